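# shared small fixtures; built in code, sized for fast unit tests

# coarse raster keeps per-test pRF predictions cheap
small_cfg <- function(grid_n = 61L) stimulus_config(grid_n = grid_n)

# one mapping run + design, built once per test file that needs it
mapping_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      run <- make_mapping_run(small_cfg())
      cache <<- list(run = run, design = aperture_design(run$apertures),
                     hrf = hrf_params())
    }
    cache
  }
})

# uniform tensor field with principal axis +y
uniform_field <- function(dims = c(21L, 41L, 21L),
                          evals = c(1.7, 0.2, 0.2) * 1e-3) {
  nvox <- prod(dims)
  D <- matrix(0, nvox, 6)
  D[, 1] <- evals[2]
  D[, 2] <- evals[1]
  D[, 3] <- evals[3]
  structure(list(D = D, S0 = rep(1, nvox), dims = dims, voxel_mm = 1),
            class = "tensor_field")
}

center_seed_mask <- function(dims, at = NULL) {
  m <- array(FALSE, dims)
  if (is.null(at)) at <- pmax(1L, as.integer(dims / 2))
  m[at[1], at[2], at[3]] <- TRUE
  m
}
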