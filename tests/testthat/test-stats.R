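test_that("Gaussian fit recovers parameters within sampling bounds", {
  set.seed(1)
  x <- rnorm(285, 510, 50)
  ft <- fit_gaussian(x)
  expect_lt(abs(ft$mu - 510), 3 * 50 / sqrt(285))
  expect_lt(abs(ft$sigma - 50), 3 * 50 / sqrt(2 * 285))
  expect_lt(ft$goodness, 0.1)
  # shift equivariance
  ft2 <- fit_gaussian(x + 100)
  expect_equal(ft2$mu, ft$mu + 100)
  expect_equal(ft2$sigma, ft$sigma)
  # n-1 convention by hand
  ft3 <- fit_gaussian(c(0, 2, 0, 2, 0, 2, 0, 2))
  expect_equal(ft3$mu, 1)
  expect_equal(ft3$sigma, sd(c(0, 2, 0, 2, 0, 2, 0, 2)))
  expect_error(fit_gaussian(rep(5, 20)), "constant")
  expect_error(fit_gaussian(1:5), "at least 8")
})

test_that("fit is essentially unbiased on the levitated preset at n = 285", {
  mus <- sigmas <- numeric(40)
  for (i in 1:40) {
    h <- generate_preset("levitated-HepG2-140", seed = i)
    ft <- fit_gaussian(h$height_um)
    mus[i] <- ft$mu; sigmas[i] <- ft$sigma
  }
  expect_lt(abs(mean(mus) - 510), 0.05 * 50)
  # with k balanced blocks the grand mean absorbs 1/k of the block variance,
  # so the pooled-SD expectation is sqrt(jitter^2 + block^2 * (1 - 1/k))
  sigma_expected <- sqrt(40^2 + 30^2 * (1 - 1 / 4))
  expect_lt(abs(mean(sigmas) - sigma_expected), 0.05 * 50)
})

test_that("central interval width follows the Gaussian quantile formula", {
  expect_equal(central_interval_width(105, 0.70), 2 * 105 * qnorm(0.85))
  expect_equal(central_interval_width(105, 0.70), 217.6, tolerance = 1e-3)
  expect_equal(round(central_interval_width(105, 0.70) / 10) * 10, 220)
  expect_equal(central_interval_width(50, 0.70), 103.6, tolerance = 1e-3)
  expect_lt(central_interval_width(105, 1e-9), 1e-5)
  expect_error(central_interval_width(105, 1), "coverage")
  expect_error(central_interval_width(-1, 0.5), "sigma")
})

test_that("slab fractions are exact Gaussian probabilities and inverses", {
  expect_equal(fraction_within_slab(510, 50, 150), 2 * pnorm(1.5) - 1)
  expect_equal(fraction_within_slab(510, 50, 150), 0.8664, tolerance = 1e-4)
  expect_equal(fraction_within_slab(500, 80, 150), 0.6515, tolerance = 1e-4)
  expect_equal(fraction_within_slab(0, 50, 1e9), 1, tolerance = 1e-12)
  expect_equal(fraction_within_slab(0, 0, 10), 1)
  # inverse identity over a parameter grid
  for (s in c(10, 50, 105)) for (cv in c(0.3, 0.5, 0.7, 0.9)) {
    expect_equal(fraction_within_slab(0, s, central_interval_width(s, cv)),
                 cv, tolerance = 1e-9)
  }
  # empirical sliding window
  expect_equal(fraction_within_slab(heights = c(0, 1, 2, 10), thickness = 2),
               0.75)
})

test_that("two-sample KS agrees with brute-force ECDF enumeration", {
  expect_equal(ks_two_sample(1:10, 1:10), list(D = 0, p = 1))
  expect_equal(ks_two_sample(1:5, 6:10)$D, 1)
  brute_D <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
  }
  kolmogorov_p <- function(D, n1, n2) {
    x <- sqrt(n1 * n2 / (n1 + n2)) * D
    j <- 1:100
    min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * x^2))))
  }
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(5:15, 1)); y <- rnorm(sample(5:15, 1), mean = runif(1))
    got <- ks_two_sample(x, y)
    expect_equal(got$D, brute_D(x, y), tolerance = 1e-12)
    expect_equal(got$p, kolmogorov_p(got$D, length(x), length(y)),
                 tolerance = 1e-4)
  }
  expect_error(ks_two_sample(1:3, 1:10), "at least 5")
})

test_that("KS null rejection rate is calibrated at the 5% level", {
  set.seed(1)
  rej <- 0
  for (i in 1:1000) {
    if (ks_two_sample(rnorm(100), rnorm(100))$p < 0.05) rej <- rej + 1
  }
  half_band <- 3 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rej / 1000, 0.05 - half_band)
  expect_lt(rej / 1000, 0.05 + half_band)
})

test_that("misalignment and circularity follow their defining formulas", {
  a <- list(mu = 150); b <- list(mu = 235)
  expect_equal(misalignment(a, b), 85)
  expect_equal(misalignment(b, a), 85)
  expect_equal(misalignment(a, a), 0)
  expect_equal(circularity(pi, 2 * pi), 1)
  expect_equal(circularity(1, 4), pi / 4)
  # isoperimetric bound on an irregular polygon (L-shape)
  expect_lt(circularity(3, 8), 1)
  expect_error(circularity(0, 1), "area")
  expect_error(circularity(1, -1), "perimeter")
})

test_that("group report fits, derives slabs, and cross-compares groups", {
  lev140 <- generate_preset("levitated-HepG2-140", seed = 1)
  lev340 <- generate_preset("levitated-HepG2-340", seed = 51)
  tiny <- data.frame(group = "tiny", block = 1, diameter_um = 140,
                     height_um = c(100, 120, 140))
  rep <- group_report(rbind(lev140, lev340, tiny))
  st <- rep$stats
  expect_true(st$excluded[st$group == "tiny"])
  expect_false(any(st$excluded[st$group != "tiny"]))
  r140 <- st[st$group == "levitated-HepG2-140", ]
  expect_equal(r140$thickness_70,
               central_interval_width(r140$sigma, 0.70))
  # the two levitated populations align at similar heights
  expect_gt(rep$p["levitated-HepG2-140", "levitated-HepG2-340"], 0.05)
  expect_equal(diag(rep$D), c(0, 0), ignore_attr = TRUE)
  # single group: trivial 1x1 matrices
  rep1 <- group_report(lev140)
  expect_equal(unname(rep1$D[1, 1]), 0)
  expect_equal(unname(rep1$p[1, 1]), 1)
  # identical groups (same seed) have D exactly 0
  dup <- lev140
  dup$group <- "copy"
  rep2 <- group_report(rbind(lev140, dup))
  expect_equal(unname(rep2$D["copy", "levitated-HepG2-140"]), 0)
})
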