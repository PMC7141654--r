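#' Define one phantom region
#'
#' Regions are painted in order onto the grid (later regions win where
#' they overlap, with a warning), each carrying a true conductivity and
#' the compartment-model ground truth for the DWI synthesis.
#'
#' @param geometry `"background"` (whole mask), `"disk"` or `"annulus"`.
#' @param sigma true conductivity, S/m.
#' @param nu_ic,d_star_e,nu_iso,nu_0 compartment truth (fractions;
#'   d_star_e in mm^2/s). Must lie within the fit bounds.
#' @param center in-plane centre in voxel coordinates; grid centre when
#'   `NULL`.
#' @param radius disk radius, voxels.
#' @param radii annulus inner/outer radii, voxels.
#' @return list describing the region.
#' @export
phantom_region <- function(geometry = c("background", "disk", "annulus"),
                           sigma, nu_ic, d_star_e, nu_iso, nu_0 = 0.02,
                           center = NULL, radius = NULL, radii = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(sigma > 0, nu_ic >= 0, nu_ic <= 1, nu_iso >= 0, nu_iso <= 1,
            nu_0 >= 0, nu_0 <= 0.2, d_star_e >= 0.1e-3, d_star_e <= 3.0e-3)
  if (geometry == "disk" && is.null(radius)) stop("disk region needs a radius")
  if (geometry == "annulus" && (is.null(radii) || length(radii) != 2L))
    stop("annulus region needs radii = c(inner, outer)")
  list(geometry = geometry, sigma = sigma, nu_ic = nu_ic,
       d_star_e = d_star_e, nu_iso = nu_iso, nu_0 = nu_0,
       center = center, radius = radius, radii = radii)
}

#' Specify a synthetic phantom
#'
#' @param grid a [volume_grid] whose mask is the phantom support.
#' @param regions list of [phantom_region]s; the first is usually the
#'   background.
#' @param interface_smoothing Gaussian sigma in voxels applied to every
#'   primitive map (0 = hard interfaces).
#' @param snr S0-to-noise ratio of the synthetic DWI (Rician).
#' @param seed integer seed for the noise.
#' @param beta ion-concentration ratio used for the closed-form truth.
#' @param fixed a [fixed_diffusivities].
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, regions, interface_smoothing = 1,
                         snr = 100, seed = 1L, beta = 0.41,
                         fixed = fixed_diffusivities()) {
  stopifnot(length(regions) >= 1L, snr > 0, interface_smoothing >= 0)
  structure(list(grid = grid, regions = regions,
                 interface_smoothing = interface_smoothing, snr = snr,
                 seed = as.integer(seed), beta = beta, fixed = fixed),
            class = "phantom_spec")
}

#' The default three-region brain slab phantom
#'
#' A single 128 x 128 slice at 1.875 mm in-plane spacing (4 mm slice):
#' a CSF background ring (1.19 S/m), a grey-matter annulus (0.55 S/m) and
#' a white-matter core (0.41 S/m) — conductivities at the levels reported
#' for segmented brain ROIs. Compartment truths are chosen at tissue-like
#' values: WM is cell-rich (nu_ic 0.6), GM intermediate (0.4), CSF almost
#' purely isotropic free water (nu_iso 0.9).
#'
#' @param n in-plane matrix size.
#' @param interface_smoothing Gaussian sigma in voxels.
#' @param snr S0-to-noise ratio.
#' @param seed noise seed.
#' @return a [phantom_spec].
#' @export
default_phantom_spec <- function(n = 128L, interface_smoothing = 1,
                                 snr = 100, seed = 1L) {
  n <- as.integer(n)
  ctr <- (n + 1) / 2
  xi <- seq_len(n) - ctr
  r <- sqrt(outer(xi^2, xi^2, "+"))
  mask <- array(r <= 0.45 * n, dim = c(n, n, 1L))
  grid <- volume_grid(c(n, n, 1L), c(1.875, 1.875, 4), mask)
  regions <- list(
    phantom_region("background", sigma = 1.19, nu_ic = 0.05,
                   d_star_e = 2.0e-3, nu_iso = 0.90, nu_0 = 0.02),
    phantom_region("annulus", sigma = 0.55, nu_ic = 0.40,
                   d_star_e = 1.2e-3, nu_iso = 0.10, nu_0 = 0.02,
                   radii = c(0.16, 0.30) * n),
    phantom_region("disk", sigma = 0.41, nu_ic = 0.60,
                   d_star_e = 1.0e-3, nu_iso = 0.02, nu_0 = 0.02,
                   radius = 0.16 * n))
  phantom_spec(grid, regions, interface_smoothing, snr, seed)
}

#' Build ground-truth maps from a phantom specification
#'
#' Paints the piecewise-constant primitive maps (sigma, nu_ic, d*_e,
#' nu_iso, nu_0), smooths them at the interfaces, then evaluates the
#' derived truth in closed form: alpha, d_w^e, d_w^i from the compartment
#' relations, c_e and sigma_L from the decomposition identity, and an
#' isotropic low-frequency tensor truth (diagonal sigma_L). Every truth
#' map therefore satisfies the same algebraic identities the pipeline
#' must reproduce.
#'
#' @param spec a [phantom_spec].
#' @return object of class `phantom_truth`: `grid`, `labels` (region
#'   index map), primitive and derived maps, and the spec.
#' @export
build_phantom <- function(spec) {
  grid <- spec$grid
  dm <- grid$shape
  ctr <- (dm[1:2] + 1) / 2
  xi <- seq_len(dm[1]) - ctr[1]
  yi <- seq_len(dm[2]) - ctr[2]
  r2d <- sqrt(outer(xi^2, yi^2, "+"))
  labels <- array(0L, dim = dm)
  prim <- list(sigma_h = NULL, nu_ic = NULL, d_star_e = NULL,
               nu_iso = NULL, nu_0 = NULL)
  for (nm in names(prim)) prim[[nm]] <- array(NaN, dim = dm)
  for (i in seq_along(spec$regions)) {
    rg <- spec$regions[[i]]
    ctr_i <- if (is.null(rg$center)) ctr else rg$center
    rr <- sqrt(outer((seq_len(dm[1]) - ctr_i[1])^2,
                     (seq_len(dm[2]) - ctr_i[2])^2, "+"))
    sel2d <- switch(rg$geometry,
                    background = matrix(TRUE, dm[1], dm[2]),
                    disk = rr <= rg$radius,
                    annulus = rr > rg$radii[1] & rr <= rg$radii[2])
    sel <- array(rep(sel2d, dm[3]), dim = dm) & grid$mask
    if (rg$geometry != "background" && any(labels[sel] > 1L))
      warning("overlapping phantom regions; later region wins")
    labels[sel] <- i
    prim$sigma_h[sel] <- rg$sigma
    prim$nu_ic[sel] <- rg$nu_ic
    prim$d_star_e[sel] <- rg$d_star_e
    prim$nu_iso[sel] <- rg$nu_iso
    prim$nu_0[sel] <- rg$nu_0
  }
  if (any(grid$mask & labels == 0L))
    stop("regions do not tile the mask (missing background region?)")
  if (spec$interface_smoothing > 0)
    prim <- lapply(prim, gaussian_smooth_inplane,
                   sigma = spec$interface_smoothing, mask = grid$mask)
  d_ic <- spec$fixed$d_ic; d_iso <- spec$fixed$d_iso
  alpha <- (1 - prim$nu_iso) * (1 - prim$nu_ic) + prim$nu_iso
  d_w_e <- ((1 - prim$nu_iso) * (1 - prim$nu_ic)^2 * prim$d_star_e +
            prim$nu_iso * d_iso) / alpha
  d_w_i <- prim$nu_ic * d_ic
  denom_um <- alpha * d_w_e * 1e3 + (1 - alpha) * spec$beta * d_w_i * 1e3
  c_e <- prim$sigma_h / denom_um
  sigma_l <- alpha * c_e * d_w_e * 1e3
  c_l <- array(0, dim = c(dm, 6L))
  for (k in 1:3) c_l[, , , k] <- sigma_l
  c_l[!is.finite(c_l)] <- NaN
  structure(list(grid = grid, labels = labels,
                 sigma_h_true = prim$sigma_h, nu_ic_true = prim$nu_ic,
                 d_star_e_true = prim$d_star_e, nu_iso_true = prim$nu_iso,
                 nu_0_true = prim$nu_0,
                 alpha_true = alpha, d_w_e_true = d_w_e, d_w_i_true = d_w_i,
                 c_e_true = c_e, sigma_l_true = sigma_l, c_l_true = c_l,
                 spec = spec),
            class = "phantom_truth")
}

#' Forward transceiver phase from a known conductivity
#'
#' Solves the divergence-form forward problem
#' div((1/sigma) grad(phi)) = 2 omega mu0 on the mask (slice-by-slice,
#' conservative five-point flux scheme with harmonic face averaging),
#' with Dirichlet boundary values from the homogeneous closed form
#' phi = (omega mu0 sigma_bg / 2)(x^2 + y^2) on the mask's boundary
#' layer. For constant sigma the discrete solution is that quadratic
#' exactly.
#'
#' @param sigma_true 3-D array of conductivity, S/m, positive on the
#'   mask.
#' @param grid a [volume_grid].
#' @param cfg an [mrept_config] (supplies omega, mu0).
#' @param sigma_bg background conductivity used for the boundary closed
#'   form; defaults to the median of `sigma_true` on the boundary layer.
#' @return a [transceiver_phase].
#' @export
forward_transceiver_phase <- function(sigma_true, grid, cfg = mrept_config(),
                                      sigma_bg = NULL) {
  if (length(dim(sigma_true)) == 2L)
    dim(sigma_true) <- c(dim(sigma_true), 1L)
  if (any(grid$mask & !(sigma_true > 0)))
    stop("sigma_true must be positive everywhere in the mask")
  dm <- grid$shape
  co <- grid_coords_m(grid)
  phi_bc2d <- (cfg$omega * cfg$mu0 / 2) * outer(co$x^2, co$y^2, "+")
  phi <- array(NaN, dim = dm)
  for (z in seq_len(dm[3])) {
    msk <- grid$mask[, , z]
    if (!any(msk)) next
    phi[, , z] <- .forward_phase_slice(sigma_true[, , z], msk, phi_bc2d,
                                       grid$spacing[1:2] * 1e-3, cfg,
                                       sigma_bg)
  }
  transceiver_phase(phi, grid)
}

.forward_phase_slice <- function(sig, msk, phi_bc, h, cfg, sigma_bg) {
  dm <- dim(sig)
  m3 <- array(msk, dim = c(dm, 1L))
  inner <- m3
  for (a in 1:2)
    inner <- inner & shift_arr(m3, a, 1L, fill = FALSE) &
                     shift_arr(m3, a, -1L, fill = FALSE)
  interior <- which(inner)
  boundary <- which(m3 & !inner)
  if (!length(interior)) stop("mask has no interior voxels")
  if (is.null(sigma_bg)) sigma_bg <- stats::median(sig[boundary])
  phi_b <- phi_bc * (sigma_bg)           # closed form scales with sigma_bg
  strides <- c(1L, dm[1])
  rank <- integer(prod(dm)); rank[interior] <- seq_along(interior)
  n <- length(interior)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diagv <- numeric(n)
  b <- rep(-2 * cfg$omega * cfg$mu0, n)
  sigv <- as.vector(sig)
  for (a in 1:2) for (s in c(1L, -1L)) {
    nb <- interior + s * strides[a]
    kf <- 2 / (sigv[interior] + sigv[nb]) / h[a]^2   # harmonic mean of 1/sigma
    diagv <- diagv + kf
    is_int <- rank[nb] > 0L
    ii <- c(ii, which(is_int)); jj <- c(jj, rank[nb[is_int]])
    xx <- c(xx, -kf[is_int])
    ext <- which(!is_int)
    if (length(ext)) b[ext] <- b[ext] + kf[ext] * phi_b[nb[ext]]
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                            x = c(diagv, xx), dims = c(n, n))
  u <- as.numeric(Matrix::solve(A, b))
  out <- matrix(NaN, dm[1], dm[2])
  out[interior] <- u
  out[boundary] <- phi_b[boundary]
  out
}

#' Synthesize a multi-b-value DWI series from phantom truth
#'
#' Noiseless diffusion-weighted signals are S0 times the forward
#' compartment model evaluated at each voxel's true parameters
#' (isotropic: identical across gradient directions); b = 0 acquisitions
#' carry the reference amplitude S0 itself (the model, including its
#' noise-floor offset nu_0, describes the diffusion-weighted signals).
#' Rician noise is then applied: the magnitude of (S + n1, n2) with
#' n1, n2 independent zero-mean Gaussians of sd = S0/snr.
#' Bit-reproducible for a fixed seed; `snr = Inf` disables the noise.
#'
#' @param truth a `phantom_truth` from [build_phantom].
#' @param protocol a [dwi_protocol] with at least one b = 0 acquisition.
#' @param snr S0-to-noise ratio (defaults to the spec's).
#' @param seed noise seed (defaults to the spec's).
#' @param s0_scale noiseless b = 0 signal amplitude.
#' @return a [dwi_series].
#' @export
synthesize_dwi <- function(truth, protocol, snr = NULL, seed = NULL,
                           s0_scale = 1000) {
  if (is.null(snr)) snr <- truth$spec$snr
  if (is.null(seed)) seed <- truth$spec$seed
  if (snr <= 0) stop("snr must be positive")
  if (!any(protocol$b_values == 0))
    stop("protocol must include a b = 0 acquisition")
  grid <- truth$grid
  dm <- grid$shape
  nb <- length(protocol$b_values)
  fixed <- truth$spec$fixed
  sig <- array(0, dim = c(dm, nb))
  msk <- grid$mask
  nic <- truth$nu_ic_true[msk]; dse <- truth$d_star_e_true[msk]
  nis <- truth$nu_iso_true[msk]; n0 <- truth$nu_0_true[msk]
  for (j in seq_len(nb)) {
    bj <- protocol$b_values[j]
    s <- if (bj == 0) rep(1, length(nic))
         else (1 - nis) * (nic * exp(-bj * nic * fixed$d_ic) +
                           (1 - nic) * exp(-bj * (1 - nic) * dse)) +
              nis * exp(-bj * fixed$d_iso) + n0
    vol <- array(0, dim = dm)
    vol[msk] <- s0_scale * s
    sig[, , , j] <- vol
  }
  if (is.finite(snr)) {
    set.seed(seed)
    sd <- s0_scale / snr
    n1 <- array(stats::rnorm(length(sig), 0, sd), dim = dim(sig))
    n2 <- array(stats::rnorm(length(sig), 0, sd), dim = dim(sig))
    sig <- sqrt((sig + n1)^2 + n2^2)
    for (j in seq_len(nb)) {
      vol <- sig[, , , j]; vol[!msk] <- 0; sig[, , , j] <- vol
    }
  }
  dwi_series(sig, protocol, grid)
}

#' Diffusion weighting from gradient timing
#'
#' b = gamma^2 delta^2 G^2 (Delta - delta/3), converted from s/m^2 to
#' s/mm^2.
#'
#' @param delta gradient pulse duration, s.
#' @param Delta gradient pulse separation (diffusion time), s.
#' @param G gradient amplitude, T/m.
#' @param gamma gyromagnetic ratio of hydrogen, rad/(T s).
#' @return b-value, s/mm^2.
#' @export
b_value_from_gradient <- function(delta, Delta, G, gamma = 26.75e7) {
  if (any(delta <= 0) || any(Delta <= delta / 3))
    stop("gradient timing must satisfy Delta > delta/3 > 0")
  if (any(G < 0)) stop("gradient amplitude must be non-negative")
  gamma^2 * delta^2 * G^2 * (Delta - delta / 3) * 1e-6
}

#' Gradient direction sets
#'
#' `directions_orthogonal` returns the three axis-aligned unit vectors;
#' `directions_fibonacci` returns n approximately uniform unit vectors on
#' the half-sphere (spherical Fibonacci lattice), enough for full-tensor
#' fitting when n >= 6.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
directions_orthogonal <- function() diag(3)

#' @rdname directions_orthogonal
#' @export
directions_fibonacci <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  zc <- i / n                      # half-sphere: z in (0, 1)
  r <- sqrt(1 - zc^2)
  cbind(r * cos(phi), r * sin(phi), zc)
}

#' Build the phantom's acquisition protocol
#'
#' One b = 0 acquisition followed by each b-value in each gradient
#' direction. The default emulates the reference acquisition: the 15
#' b-values each applied along 15 gradient directions; pass
#' [directions_orthogonal()] for the reduced 3-direction protocol.
#'
#' @param b_values diffusion weightings, s/mm^2 (default: the 15-value
#'   reference protocol).
#' @param directions matrix of unit gradient directions.
#' @param n_b0 number of b = 0 acquisitions.
#' @return a [dwi_protocol].
#' @export
phantom_protocol <- function(b_values = reference_b_values(),
                             directions = directions_fibonacci(15L),
                             n_b0 = 1L) {
  nd <- nrow(directions)
  b <- c(rep(0, n_b0), rep(b_values, each = nd))
  dirs <- rbind(matrix(0, n_b0, 3),
                directions[rep(seq_len(nd), times = length(b_values)), ,
                           drop = FALSE])
  dwi_protocol(b, dirs)
}
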