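# Shared fixtures, built in code at test time. Heavy objects are cached per
# session so several test files can reuse one pipeline run.

options(mbcti.log_level = "error")

.fixture_env <- new.env(parent = emptyenv())

# Small end-to-end pipeline run on the three-region phantom (48 x 48,
# SNR 100, seed 1, full 15-direction protocol).
small_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    spec <- default_phantom_spec(n = 48L, snr = 100, seed = 1L)
    .fixture_env$pipe <- run_pipeline(spec, phantom_protocol(), seed = 1L)
  }
  .fixture_env$pipe
}

# A single-slice grid with full mask.
square_grid <- function(n, spacing = c(2, 2, 4)) {
  volume_grid(c(n, n, 1L), spacing)
}

# Metre coordinates of a square grid as matrices.
coord_mats <- function(grid) {
  sp <- grid$spacing * 1e-3
  x <- (seq_len(grid$shape[1]) - (grid$shape[1] + 1) / 2) * sp[1]
  y <- (seq_len(grid$shape[2]) - (grid$shape[2] + 1) / 2) * sp[2]
  list(X = matrix(x, grid$shape[1], grid$shape[2]),
       Y = matrix(y, grid$shape[1], grid$shape[2], byrow = TRUE))
}

# Synthesize a DWI series whose signals follow a Gaussian tensor model
# (for the tensor-fit oracle tests): S/S0 = exp(-b g' D g).
tensor_series <- function(D, protocol, grid, s0 = 1000) {
  nb <- length(protocol$b_values)
  sig <- array(0, dim = c(grid$shape, nb))
  for (j in seq_len(nb)) {
    g <- protocol$directions[j, ]
    adc <- as.numeric(t(g) %*% D %*% g)
    sig[, , , j] <- s0 * exp(-protocol$b_values[j] * adc)
  }
  dwi_series(sig, protocol, grid)
}

# Collapse a possibly-degenerate 4-D volume stack to a 3-D array.
vol3 <- function(a, k) array(a[, , , k, drop = FALSE], dim = dim(a)[1:3])

region_median_rel_err <- function(est, truth, labels, label) {
  rel <- abs(est - truth) / truth
  stats::median(rel[labels == label & is.finite(rel)], na.rm = TRUE)
}
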