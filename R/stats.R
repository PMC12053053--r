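#' Gaussian fit to a height distribution
#'
#' Maximum-likelihood Gaussian fit to raw heights: the sample mean and the
#' sample SD (n - 1 denominator). Goodness of fit is the one-sample
#' Kolmogorov-Smirnov distance between the data and the fitted Gaussian.
#'
#' @param heights Numeric vector of heights, um. At least 8 values with
#'   positive spread.
#' @return A list with `mu`, `sigma` (um) and `goodness` (KS distance).
#' @examples
#' fit_gaussian(rnorm(100, 510, 50))
#' @export
fit_gaussian <- function(heights) {
  heights <- as.numeric(heights)
  if (length(heights) < 8) stop("need at least 8 observations")
  s <- stats::sd(heights)
  if (!is.finite(s) || s == 0) stop("degenerate fit: constant data")
  m <- mean(heights)
  D <- suppressWarnings(
    stats::ks.test(heights, "pnorm", mean = m, sd = s)$statistic)
  list(mu = m, sigma = s, goodness = unname(D))
}

#' Width of the central probability interval of a Gaussian
#'
#' The slab thickness containing a given central fraction of a Gaussian
#' height distribution: \eqn{2\sigma\,\Phi^{-1}((1+c)/2)}. For 70%
#' coverage the factor is \eqn{2 \times 1.0364}, so
#' \eqn{\sigma = 105\,\mu m} gives 217.6 um (reported as 220 um at 10 um
#' rounding granularity).
#'
#' @param sigma Gaussian SD, um (>= 0).
#' @param coverage Central coverage fraction, in (0, 1).
#' @return Slab thickness in um.
#' @examples
#' central_interval_width(105, 0.70) # 217.6
#' @export
central_interval_width <- function(sigma, coverage) {
  check_nonnegative_scalar(sigma, "sigma")
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1)
    stop("'coverage' must lie strictly inside (0, 1)")
  2 * sigma * stats::qnorm((1 + coverage) / 2)
}

#' Fraction of a Gaussian population inside a centred slab
#'
#' For fitted parameters, the analytic fraction of \eqn{N(\mu, \sigma)}
#' within the slab of the given thickness centred at \eqn{\mu}:
#' \eqn{2\Phi(t/2\sigma) - 1}. For an empirical sample pass `heights`; the
#' maximal fraction over all slab positions (sliding window) is returned.
#'
#' @param mu Gaussian mean, um (unused analytically beyond centring).
#' @param sigma Gaussian SD, um.
#' @param thickness Slab thickness, um (>= 0).
#' @param heights Optional numeric vector; if given, the empirical sliding
#'   -window maximum fraction is computed instead of the analytic one.
#' @return Fraction in `[0, 1]`.
#' @examples
#' fraction_within_slab(510, 50, 150) # 0.8664
#' @export
fraction_within_slab <- function(mu, sigma, thickness, heights = NULL) {
  if (!is.numeric(thickness) || thickness < 0)
    stop("'thickness' must be >= 0")
  if (!is.null(heights)) {
    x <- sort(as.numeric(heights))
    n <- length(x)
    best <- max(vapply(seq_len(n), function(i)
      sum(x >= x[i] & x <= x[i] + thickness), integer(1)))
    return(best / n)
  }
  if (sigma == 0) return(as.numeric(thickness > 0))
  2 * stats::pnorm(thickness / (2 * sigma)) - 1
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' is the asymptotic two-sided Kolmogorov probability at effective sample
#' size \eqn{n_1 n_2 / (n_1 + n_2)} (the convention used for cumulative
#' frequency comparisons of height distributions). Exact small-sample
#' enumeration can be requested via `exact = TRUE`.
#'
#' @param x,y Numeric samples, each with at least 5 values.
#' @param exact Logical; default `FALSE` (asymptotic p).
#' @return A list with `D` and `p`.
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50))
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) < 5 || length(y) < 5)
    stop("both samples need at least 5 observations")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p = min(1, unname(kt$p.value)))
}

#' Mean misalignment between two fitted populations
#'
#' Absolute difference of the fitted mean heights, um.
#'
#' @param statsA,statsB Lists with a `mu` field (e.g. from
#'   [fit_gaussian()]).
#' @return |mu_A - mu_B| in um.
#' @examples
#' misalignment(list(mu = 150), list(mu = 235)) # 85
#' @export
misalignment <- function(statsA, statsB) abs(statsA$mu - statsB$mu)

#' Circularity of a segmented 2D shape
#'
#' \eqn{4\pi A / P^2}; 1 for a perfect circle, < 1 otherwise.
#'
#' @param area Shape area (e.g. um^2), > 0.
#' @param perimeter Shape perimeter (same length unit), > 0.
#' @return Dimensionless circularity.
#' @examples
#' circularity(pi, 2 * pi) # 1 (unit circle)
#' circularity(1, 4)       # pi/4, unit square
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(area <= 0)) stop("'area' must be > 0")
  if (any(!is.finite(perimeter)) || any(perimeter <= 0))
    stop("'perimeter' must be > 0")
  4 * pi * area / perimeter^2
}

#' Group-wise alignment report
#'
#' Fits a Gaussian per group, derives the 70%-coverage slab thickness, and
#' computes the pairwise two-sample KS matrix. Groups with fewer than 8
#' samples are flagged and excluded from fitting and testing.
#'
#' @param samples A data.frame with columns `group` and `height_um` (an
#'   `al_heights` or any equivalent table).
#' @param coverage Coverage fraction for the slab-thickness column.
#' @return A list of class `al_report`: `stats` (data.frame with `group`,
#'   `n`, `mu`, `sigma`, `thickness_70`, `goodness`, `excluded`), `D` and
#'   `p` (named matrices over the fitted groups).
#' @export
group_report <- function(samples, coverage = 0.70) {
  stopifnot(all(c("group", "height_um") %in% names(samples)))
  groups <- unique(as.character(samples$group))
  if (!length(groups)) stop("need at least one group")
  per <- lapply(groups, function(g) {
    h <- samples$height_um[samples$group == g]
    if (length(h) < 8 || stats::sd(h) == 0)
      return(data.frame(group = g, n = length(h), mu = NA, sigma = NA,
                        thickness_70 = NA, goodness = NA, excluded = TRUE))
    ft <- fit_gaussian(h)
    data.frame(group = g, n = length(h), mu = ft$mu, sigma = ft$sigma,
               thickness_70 = central_interval_width(ft$sigma, coverage),
               goodness = ft$goodness, excluded = FALSE)
  })
  tab <- do.call(rbind, per)
  ok <- tab$group[!tab$excluded]
  D <- p <- matrix(NA_real_, length(ok), length(ok), dimnames = list(ok, ok))
  for (i in seq_along(ok)) for (j in seq_along(ok)) {
    if (i == j) { D[i, j] <- 0; p[i, j] <- 1; next }
    if (i > j) next
    hx <- samples$height_um[samples$group == ok[i]]
    hy <- samples$height_um[samples$group == ok[j]]
    kt <- ks_two_sample(hx, hy)
    D[i, j] <- D[j, i] <- kt$D
    p[i, j] <- p[j, i] <- kt$p
  }
  structure(list(stats = tab, D = D, p = p), class = "al_report")
}

#' @export
print.al_report <- function(x, ...) {
  cat("<al_report>\n")
  tab <- x$stats
  tab$mu <- round(tab$mu, 1); tab$sigma <- round(tab$sigma, 1)
  tab$thickness_70 <- round(tab$thickness_70, 1)
  tab$goodness <- round(tab$goodness, 3)
  print(tab, row.names = FALSE)
  if (nrow(x$D)) {
    cat("pairwise KS p-values:\n")
    print(round(x$p, 4))
  }
  invisible(x)
}
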