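#' Configuration for the stabilized convection-reaction inversion
#'
#' The phase-based inversion solves, for u = 1/sigma_H,
#'   -c lap(u) + grad(phi) . grad(u) + lap(phi) u = 2 omega mu0
#' on the masked region, discretized with three-point central differences
#' on the physical (metre) lattice. The artificial diffusion term c
#' stabilizes the convection; c = 0.025 is the default working value.
#'
#' @param omega Larmor angular frequency, rad/s (default 2 pi x 128 MHz).
#' @param mu0 magnetic permeability of free space, T m/A.
#' @param c artificial diffusion coefficient (>= 0).
#' @param boundary_mode `"local_helmholtz"` (Dirichlet boundary values from
#'   the pointwise Helmholtz estimate 2 omega mu0 / lap(phi), median
#'   filtered over a 3x3 window) or `"fixed_value"` (u = 1/boundary_sigma,
#'   for phantoms with known background conductivity).
#' @param boundary_sigma background conductivity, S/m; required in
#'   `fixed_value` mode.
#' @param sigma_bounds admissible conductivity range (S/m); values outside
#'   are clamped and counted.
#' @param slicewise solve each slice as an independent 2-D problem
#'   (default; matches a thick-slice acquisition where through-plane
#'   derivatives are unreliable). `FALSE` solves one 3-D system.
#' @param smooth_fwhm optional Gaussian pre-smoothing of the phase before
#'   differentiation, FWHM in mm (0 = off).
#' @return object of class `mrept_config`.
#' @export
mrept_config <- function(omega = 2 * pi * 128e6,
                         mu0 = 4 * pi * 1e-7,
                         c = 0.025,
                         boundary_mode = c("local_helmholtz", "fixed_value"),
                         boundary_sigma = NULL,
                         sigma_bounds = c(0.05, 5),
                         slicewise = TRUE,
                         smooth_fwhm = 0) {
  boundary_mode <- match.arg(boundary_mode)
  stopifnot(omega > 0, mu0 > 0, c >= 0,
            length(sigma_bounds) == 2L, sigma_bounds[1] > 0,
            sigma_bounds[2] > sigma_bounds[1])
  if (boundary_mode == "fixed_value" &&
      (is.null(boundary_sigma) || boundary_sigma <= 0))
    stop("fixed_value boundary mode requires a positive boundary_sigma")
  structure(list(omega = omega, mu0 = mu0, c = c,
                 boundary_mode = boundary_mode, boundary_sigma = boundary_sigma,
                 sigma_bounds = sigma_bounds, slicewise = slicewise,
                 smooth_fwhm = smooth_fwhm),
            class = "mrept_config")
}

#' Transceiver phase map
#'
#' @param phi scalar field, radians; `NaN` outside the region of support.
#' @param grid a [volume_grid].
#' @return object of class `transceiver_phase`.
#' @export
transceiver_phase <- function(phi, grid) {
  dm <- dim(phi)
  if (length(dm) == 2L) dim(phi) <- dm <- c(dm, 1L)
  if (!identical(as.integer(dm), grid$shape))
    stop("phase shape does not match grid")
  if (any(!is.finite(phi[grid$mask])))
    stop("phase must be finite inside the mask")
  structure(list(phi = phi, grid = grid), class = "transceiver_phase")
}

#' Multi-echo complex series
#'
#' @param complex_signals 4-D complex array (grid x echoes).
#' @param echo_indices 1-based echo numbers of the stored volumes.
#' @param grid a [volume_grid].
#' @return object of class `multi_echo_series`.
#' @export
multi_echo_series <- function(complex_signals, echo_indices, grid) {
  dm <- dim(complex_signals)
  stopifnot(length(dm) == 4L, dm[4] == length(echo_indices))
  if (!identical(as.integer(dm[1:3]), grid$shape))
    stop("echo stack shape does not match grid")
  echo_indices <- as.integer(echo_indices)
  if (!any(echo_indices %% 2L == 1L))
    stop("at least one odd echo is required")
  structure(list(complex_signals = complex_signals,
                 echo_indices = echo_indices, grid = grid),
            class = "multi_echo_series")
}

#' Combine multi-echo phase into the transceiver phase
#'
#' Only odd echoes are used (even echoes carry background phase from the
#' refocusing train). Per voxel the combined phase is the
#' magnitude-squared-weighted average of the odd-echo phases,
#' w_k = |S_k|^2 / sum_odd |S_m|^2, after unwrapping each echo's phase
#' pairwise to the first odd echo's branch. Phase noise is inversely
#' proportional to magnitude, which this weighting exploits. Voxels where
#' every odd-echo magnitude is zero are masked out.
#'
#' @param echoes a [multi_echo_series].
#' @return a [transceiver_phase] whose grid mask excludes dead voxels.
#' @export
combine_echo_phase <- function(echoes) {
  odd <- which(echoes$echo_indices %% 2L == 1L)
  s <- echoes$complex_signals[, , , odd, drop = FALSE]
  mag2 <- Mod(s)^2
  tot <- apply(mag2, 1:3, sum)
  ref <- Arg(s[, , , 1L])
  num <- array(0, dim = dim(tot))
  for (k in seq_along(odd)) {
    ph_k <- ref + Arg(s[, , , k] * Conj(exp(1i * ref)))  # unwrap to ref branch
    num <- num + mag2[, , , k] * ph_k
  }
  phi <- array(NaN, dim = dim(tot))
  alive <- tot > 0
  phi[alive] <- num[alive] / tot[alive]
  mask <- echoes$grid$mask & alive
  if (any(echoes$grid$mask & !alive))
    mbcti_log("warn", "%d voxel(s) with zero odd-echo magnitude masked out",
              sum(echoes$grid$mask & !alive))
  transceiver_phase(phi, volume_grid(echoes$grid$shape, echoes$grid$spacing, mask))
}

# Central-difference phase derivatives on the metre lattice. Returns
# gradients per used axis and the Laplacian restricted to those axes;
# entries are NA where a needed neighbour is missing or non-finite.
phase_derivatives <- function(phi, spacing_mm, axes = c(1L, 2L)) {
  h <- spacing_mm * 1e-3
  g <- vector("list", 3L)
  lap <- array(0, dim = dim(phi))
  for (a in axes) {
    fp <- shift_arr(phi, a, 1L)
    fm <- shift_arr(phi, a, -1L)
    g[[a]] <- (fp - fm) / (2 * h[a])
    lap <- lap + (fp - 2 * phi + fm) / h[a]^2
  }
  list(g = g, lap = lap)
}

#' Assemble the discrete stabilized inversion system
#'
#' Builds the sparse system A u = b over the interior masked voxels of one
#' slice (or the full volume in 3-D mode), with u = 1/sigma_H. Each row
#' discretizes -c lap(u) + grad(phi).grad(u) + lap(phi) u = 2 omega mu0
#' with three-point central differences; voxels of the mask's boundary
#' layer enter as Dirichlet values according to the configured boundary
#' mode and are moved to the right-hand side.
#'
#' @param phase a [transceiver_phase].
#' @param cfg an [mrept_config].
#' @param slice slice index (1-based) when `cfg$slicewise`; ignored in 3-D
#'   mode.
#' @return object of class `mrept_system`: `A` (sparse), `b`, `interior`
#'   and `boundary` (linear voxel indices into the slice/volume),
#'   `u_boundary`, `derivs`, and bookkeeping fields.
#' @export
assemble_mrept_system <- function(phase, cfg, slice = 1L) {
  if (cfg$slicewise) {
    z <- as.integer(slice)
    phi <- phase$phi[, , z, drop = FALSE]
    mask <- phase$grid$mask[, , z, drop = FALSE]
    axes <- c(1L, 2L)
  } else {
    phi <- phase$phi
    mask <- phase$grid$mask
    axes <- which(dim(phase$phi) > 1L)
  }
  .assemble_region(phi, mask, phase$grid$spacing, axes, cfg)
}

.assemble_region <- function(phi, mask, spacing_mm, axes, cfg) {
  dm <- dim(phi)
  h <- spacing_mm * 1e-3
  d <- phase_derivatives(phi, spacing_mm, axes)
  nb_in <- array(TRUE, dim = dm)
  for (a in axes)
    nb_in <- nb_in & shift_arr(mask, a, 1L, fill = FALSE) &
                     shift_arr(mask, a, -1L, fill = FALSE)
  derivs_ok <- is.finite(d$lap)
  for (a in axes) derivs_ok <- derivs_ok & is.finite(d$g[[a]])
  interior <- mask & nb_in & derivs_ok
  boundary <- mask & !interior
  if (any(mask & nb_in & !derivs_ok))
    mbcti_log("info", "%d voxel(s) excluded for non-finite phase derivatives",
              sum(mask & nb_in & !derivs_ok))
  int_idx <- which(interior)
  if (!length(int_idx)) stop("mask has no interior voxels")
  bnd_idx <- which(boundary)

  rhs0 <- 2 * cfg$omega * cfg$mu0
  u_bc <- .boundary_u(d, interior, boundary, rhs0, cfg)

  strides <- c(1L, dm[1], dm[1] * dm[2])
  rank <- integer(prod(dm)); rank[int_idx] <- seq_along(int_idx)
  n <- length(int_idx)
  diag_coef <- d$lap[int_idx] + cfg$c * sum(2 / h[axes]^2)
  ii <- seq_len(n); jj <- seq_len(n); xx <- diag_coef
  b <- rep(rhs0, n)
  for (a in axes) for (s in c(1L, -1L)) {
    coef <- -cfg$c / h[a]^2 + s * d$g[[a]][int_idx] / (2 * h[a])
    nb <- int_idx + s * strides[a]
    is_int <- rank[nb] > 0L
    ii <- c(ii, which(is_int))
    jj <- c(jj, rank[nb[is_int]])
    xx <- c(xx, coef[is_int])
    ext <- which(!is_int)        # boundary-layer neighbour -> Dirichlet
    if (length(ext)) b[ext] <- b[ext] - coef[ext] * u_bc[nb[ext]]
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  structure(list(A = A, b = b, interior = int_idx, boundary = bnd_idx,
                 u_boundary = u_bc, derivs = d, dim = dm, axes = axes,
                 rhs0 = rhs0, cfg = cfg),
            class = "mrept_system")
}

# Dirichlet values of u = 1/sigma on the boundary layer.
.boundary_u <- function(d, interior, boundary, rhs0, cfg) {
  dm <- dim(interior)
  u_bc <- array(NA_real_, dim = dm)
  if (cfg$boundary_mode == "fixed_value") {
    u_bc[boundary] <- 1 / cfg$boundary_sigma
    return(u_bc)
  }
  uh <- rhs0 / d$lap                 # pointwise Helmholtz estimate of 1/sigma
  uh[!interior | !is.finite(uh) | uh <= 0] <- NA
  uh_f <- median_filter3_inplane(uh)
  vals <- median_filter3_inplane(uh_f)   # widen by one ring for edge voxels
  bidx <- which(boundary)
  u_bc[bidx] <- vals[bidx]
  miss <- bidx[!is.finite(u_bc[bidx])]
  if (length(miss)) {
    fallback <- stats::median(uh, na.rm = TRUE)
    if (!is.finite(fallback))
      stop("cannot form Helmholtz boundary values: no usable interior estimate")
    u_bc[miss] <- fallback
  }
  u_bc
}

#' Solve an assembled inversion system for u = 1/sigma_H
#'
#' @param sys an `mrept_system` from [assemble_mrept_system].
#' @return numeric vector u over `sys$interior`, solved to relative
#'   residual <= 1e-10 (direct sparse factorization).
#' @export
solve_mrept_system <- function(sys) {
  u <- tryCatch(
    as.numeric(Matrix::solve(sys$A, sys$b)),
    error = function(e) {
      kappa <- tryCatch(Matrix::condest(sys$A)$est, error = function(e2) NA)
      stop("MREPT system singular or ill-conditioned (condition estimate ",
           format(kappa, digits = 3), "): ", conditionMessage(e))
    })
  rel <- sqrt(sum((as.numeric(sys$A %*% u) - sys$b)^2)) / sqrt(sum(sys$b^2))
  if (!is.finite(rel) || rel > 1e-10)
    stop("MREPT solve did not reach relative residual 1e-10 (got ",
         format(rel, digits = 3), ")")
  u
}

#' Reconstruct the high-frequency conductivity map
#'
#' Runs the stabilized inversion over the masked region (slice-by-slice by
#' default) and returns sigma_H = 1/u, clamped to the configured bounds.
#'
#' @param phase a [transceiver_phase].
#' @param cfg an [mrept_config].
#' @return object of class `conductivity_map`: `sigma_h` (S/m, `NaN`
#'   outside the mask), `grid`, `clamped_fraction`.
#' @export
solve_sigma_h <- function(phase, cfg = mrept_config()) {
  log_stage("mrept", list(c = cfg$c, omega = cfg$omega,
                          boundary = cfg$boundary_mode,
                          slicewise = cfg$slicewise))
  if (cfg$smooth_fwhm > 0) {
    sig_vox <- cfg$smooth_fwhm / (2 * sqrt(2 * log(2))) / phase$grid$spacing[1]
    mbcti_log("info", "phase pre-smoothing FWHM %.3g mm (sigma %.3g vox)",
              cfg$smooth_fwhm, sig_vox)
    phi_s <- gaussian_smooth_inplane(phase$phi, sig_vox, phase$grid$mask)
    phase <- transceiver_phase(phi_s, phase$grid)
  }
  dm <- phase$grid$shape
  sigma <- array(NaN, dim = dm)
  slices <- if (cfg$slicewise) seq_len(dm[3]) else 1L
  for (z in slices) {
    msk <- if (cfg$slicewise) phase$grid$mask[, , z] else phase$grid$mask
    if (!any(msk)) next
    sys <- assemble_mrept_system(phase, cfg, slice = z)
    u <- solve_mrept_system(sys)
    sl <- array(NaN, dim = sys$dim)
    sl[sys$interior] <- u
    sl[sys$boundary] <- sys$u_boundary[sys$boundary]
    if (cfg$slicewise) sigma[, , z] <- 1 / sl else sigma <- 1 / sl
  }
  inmask <- phase$grid$mask & is.finite(sigma)
  lo <- cfg$sigma_bounds[1]; hi <- cfg$sigma_bounds[2]
  clamped <- inmask & (sigma < lo | sigma > hi)
  sigma[inmask & sigma < lo] <- lo
  sigma[inmask & sigma > hi] <- hi
  frac <- sum(clamped) / max(1L, sum(inmask))
  if (frac > 0.2)
    warning(sprintf("%.1f%% of voxels clamped to sigma bounds", 100 * frac))
  structure(list(sigma_h = sigma, grid = phase$grid, clamped_fraction = frac),
            class = "conductivity_map")
}

#' Pointwise Helmholtz conductivity estimate
#'
#' The homogeneous-medium limit lap(phi) / (2 omega mu0), useful as a
#' sanity check: where grad(1/sigma) = 0 the full inversion coincides with
#' this estimate.
#'
#' @param phase a [transceiver_phase].
#' @param cfg an [mrept_config].
#' @return 3-D array of sigma estimates (NA where the Laplacian is not
#'   computable).
#' @export
helmholtz_sigma <- function(phase, cfg = mrept_config()) {
  axes <- if (cfg$slicewise) c(1L, 2L) else which(phase$grid$shape > 1L)
  d <- phase_derivatives(phase$phi, phase$grid$spacing, axes)
  out <- d$lap / (2 * cfg$omega * cfg$mu0)
  out[!phase$grid$mask] <- NA
  out
}
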