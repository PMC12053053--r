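# Solved fields are expensive relative to the rest of the suite; cache one
# instance of each reference configuration per test run.
.al_cache <- new.env(parent = emptyenv())

ref_particle <- function() particle_spec(75e-6, 1099)

cached_field <- function(model = c("A", "B")) {
  model <- match.arg(model)
  key <- paste0("field_", model)
  if (is.null(.al_cache[[key]])) {
    cfg <- if (model == "A") model_a_config() else model_b_config()
    .al_cache[[key]] <- solve_pressure(cfg$chamber, cfg$map)
  }
  .al_cache[[key]]
}

cached_force <- function(model = c("A", "B")) {
  model <- match.arg(model)
  key <- paste0("force_", model)
  if (is.null(.al_cache[[key]]))
    .al_cache[[key]] <- radiation_force(
      gorkov_potential(cached_field(model), ref_particle()))
  .al_cache[[key]]
}

# Coarse-but-valid resolution for tests that need extra solves.
coarse_res <- function() c(200e-6, 200e-6, 100e-6)

# Reverse an array along one axis (same shape), for parity checks.
mirror_flip <- function(arr, axis) {
  idx <- rev(seq_len(dim(arr)[axis]))
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}
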