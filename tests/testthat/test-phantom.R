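test_that("a single background region yields constant maps", {
  grid <- volume_grid(c(8, 8, 1), c(1.875, 1.875, 4))
  spec <- phantom_spec(grid, list(
    phantom_region("background", sigma = 0.7, nu_ic = 0.3,
                   d_star_e = 1.1e-3, nu_iso = 0.2, nu_0 = 0.02)),
    interface_smoothing = 1)
  tr <- build_phantom(spec)
  expect_equal(range(tr$sigma_h_true), c(0.7, 0.7))
  expect_equal(range(tr$alpha_true), rep((1 - 0.2) * (1 - 0.3) + 0.2, 2))
})

test_that("the three-region phantom carries the reference conductivity levels", {
  n <- 64L
  tr <- build_phantom(default_phantom_spec(n = n))
  ctr <- (n + 1) / 2
  # region interiors (far from the smoothed interfaces) keep exactly the
  # CSF/GM/WM conductivities: sample the WM centre, mid-GM and mid-CSF
  wm <- tr$sigma_h_true[round(ctr), round(ctr), 1]
  gm <- tr$sigma_h_true[round(ctr + 0.23 * n), round(ctr), 1]
  csf <- tr$sigma_h_true[round(ctr + 0.375 * n), round(ctr), 1]
  expect_equal(wm, 0.41, tolerance = 1e-12)
  expect_equal(gm, 0.55, tolerance = 1e-12)
  expect_equal(csf, 1.19, tolerance = 1e-12)
})

test_that("zero interface smoothing produces hard interfaces", {
  spec <- default_phantom_spec(n = 32L, interface_smoothing = 0)
  tr <- build_phantom(spec)
  vals <- unique(tr$sigma_h_true[tr$grid$mask])
  expect_setequal(round(vals, 6), c(1.19, 0.55, 0.41))
})

test_that("phantom truth maps satisfy the pipeline's algebraic identities", {
  tr <- build_phantom(default_phantom_spec(n = 32L))
  msk <- tr$grid$mask
  # sigma_L = alpha c_e d_w^e (um^2/ms) by construction
  expect_equal(tr$sigma_l_true[msk],
               (tr$alpha_true * tr$c_e_true * tr$d_w_e_true * 1e3)[msk],
               tolerance = 1e-14)
  # trace(C_L_true)/3 = sigma_L_true exactly
  trc <- (vol3(tr$c_l_true, 1) + vol3(tr$c_l_true, 2) + vol3(tr$c_l_true, 3)) / 3
  expect_equal(trc[msk], tr$sigma_l_true[msk], tolerance = 1e-15)
  expect_true(all(tr$sigma_l_true[msk] <= tr$sigma_h_true[msk] + 1e-14))
})

test_that("the forward phase solver reproduces the homogeneous closed form", {
  grid <- square_grid(24, spacing = c(1.875, 1.875, 4))
  cfg <- mrept_config()
  sigma0 <- 0.9
  ph <- forward_transceiver_phase(array(sigma0, dim = grid$shape), grid, cfg)
  co <- coord_mats(grid)
  closed <- (cfg$omega * cfg$mu0 * sigma0 / 2) * (co$X^2 + co$Y^2)
  diff <- ph$phi[, , 1] - closed
  expect_lt(max(abs(diff - mean(diff))), 1e-10 * max(abs(closed)))
})

test_that("the discrete boundary flux balances the source (divergence theorem)", {
  spec <- default_phantom_spec(n = 48L)
  tr <- build_phantom(spec)
  cfg <- mrept_config()
  ph <- forward_transceiver_phase(tr$sigma_h_true, tr$grid, cfg)
  phi <- ph$phi[, , 1]
  sig <- tr$sigma_h_true[, , 1]
  msk <- tr$grid$mask[, , 1]
  h <- tr$grid$spacing[1:2] * 1e-3
  inner <- msk
  inner[c(1, nrow(msk)), ] <- FALSE; inner[, c(1, ncol(msk))] <- FALSE
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    idx <- which(msk)
    nb <- idx + d[1] + d[2] * nrow(msk)
    inner[idx[!msk[nb]]] <- FALSE
  }
  # sum of face fluxes (1/sigma) dphi/dn over the interior's boundary,
  # computed independently of the solver's assembly
  flux <- 0
  idx <- which(inner)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- idx + d[1] + d[2] * nrow(msk)
    ext <- !inner[nb]                       # faces crossing the boundary
    hperp <- if (d[1] != 0) h[2] else h[1]
    hpar <- if (d[1] != 0) h[1] else h[2]
    kf <- 2 / (sig[idx[ext]] + sig[nb[ext]])
    flux <- flux + sum(kf * (phi[nb[ext]] - phi[idx[ext]]) / hpar * hperp)
  }
  area <- length(idx) * h[1] * h[2]
  expect_equal(flux, 2 * cfg$omega * cfg$mu0 * area, tolerance = 1e-3)
})

test_that("phase inversion of the phantom recovers the true conductivity", {
  spec <- default_phantom_spec(n = 64L)
  tr <- build_phantom(spec)
  cfg <- mrept_config()
  ph <- forward_transceiver_phase(tr$sigma_h_true, tr$grid, cfg)
  cm <- solve_sigma_h(ph, cfg)
  rel <- abs(cm$sigma_h - tr$sigma_h_true) / tr$sigma_h_true
  expect_lt(stats::median(rel[is.finite(rel)]), 0.05)
})

test_that("DWI synthesis is exact without noise and reproducible with it", {
  spec <- default_phantom_spec(n = 16L)
  tr <- build_phantom(spec)
  proto <- phantom_protocol(directions = directions_orthogonal())
  clean <- synthesize_dwi(tr, proto, snr = Inf)
  vox <- which(tr$grid$mask)[5]
  p <- list(nu_ic = tr$nu_ic_true[vox], d_star_e = tr$d_star_e_true[vox],
            nu_iso = tr$nu_iso_true[vox], nu_0 = tr$nu_0_true[vox])
  sig_v <- matrix(clean$signals, ncol = length(proto$b_values))[vox, ]
  expect_equal(sig_v[1], 1000)              # b = 0 carries S0 itself
  expect_equal(sig_v[-1] / 1000,
               mbd_forward(p, tr$spec$fixed, proto$b_values[-1]),
               tolerance = 1e-12)
  n1 <- synthesize_dwi(tr, proto, snr = 50, seed = 123)
  n2 <- synthesize_dwi(tr, proto, snr = 50, seed = 123)
  expect_identical(n1$signals, n2$signals)
  n3 <- synthesize_dwi(tr, proto, snr = 50, seed = 124)
  expect_false(identical(n1$signals, n3$signals))
  expect_error(synthesize_dwi(tr, proto, snr = 0), "positive")
})

test_that("the empirical Rician mean matches its closed form at S/sd = 5", {
  # closed form: mu = sd sqrt(pi/2) L_{1/2}(-S^2 / (2 sd^2)) with
  # L_{1/2}(x) = exp(x/2) [(1 - x) I0(-x/2) - x I1(-x/2)]
  n <- 200000L
  grid <- volume_grid(c(n, 1, 1), c(1, 1, 1))
  spec <- phantom_spec(grid, list(
    phantom_region("background", sigma = 1, nu_ic = 0.5, d_star_e = 1.2e-3,
                   nu_iso = 0.1, nu_0 = 0.02)), interface_smoothing = 0,
    snr = 20, seed = 99)
  tr <- build_phantom(spec)
  b_pick <- 1800
  proto <- dwi_protocol(c(0, b_pick), rbind(c(0, 0, 0), c(0, 0, 1)))
  S <- 1000 * mbd_forward(list(nu_ic = 0.5, d_star_e = 1.2e-3, nu_iso = 0.1,
                               nu_0 = 0.02), tr$spec$fixed, b_pick)
  sd <- 1000 / 20
  expect_gt(S / sd, 4.5); expect_lt(S / sd, 5.5)
  noisy <- synthesize_dwi(tr, proto, snr = 20, seed = 99)
  emp <- mean(noisy$signals[, , , 2])
  x <- -S^2 / (2 * sd^2)
  laguerre_half <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) -
                                 x * besselI(-x / 2, 1))
  mu <- sd * sqrt(pi / 2) * laguerre_half
  expect_equal(emp, mu, tolerance = 0.005)
})

test_that("the gradient-timing b-value formula evaluates correctly", {
  expect_equal(b_value_from_gradient(0.02, 0.04, 0), 0)
  # delta = 20 ms, Delta = 40 ms, G = 30 mT/m (direct evaluation)
  b <- b_value_from_gradient(0.02, 0.04, 0.03)
  expect_equal(b, 858.675, tolerance = 1e-4)
  # quadratic in G
  expect_equal(b_value_from_gradient(0.02, 0.04, 0.06), 4 * b,
               tolerance = 1e-12)
  expect_error(b_value_from_gradient(0.02, 0.005, 0.03), "timing")
  expect_error(b_value_from_gradient(-0.01, 0.04, 0.03), "timing")
})

test_that("overlapping regions warn and the later region wins", {
  grid <- volume_grid(c(16, 16, 1), c(1, 1, 1))
  spec <- phantom_spec(grid, list(
    phantom_region("background", sigma = 1, nu_ic = 0.2, d_star_e = 1e-3,
                   nu_iso = 0.3),
    phantom_region("disk", sigma = 0.5, nu_ic = 0.4, d_star_e = 1e-3,
                   nu_iso = 0.1, radius = 5),
    phantom_region("disk", sigma = 0.3, nu_ic = 0.5, d_star_e = 1e-3,
                   nu_iso = 0.1, radius = 3)), interface_smoothing = 0)
  expect_warning(tr <- build_phantom(spec), "overlap")
  expect_equal(tr$sigma_h_true[8, 8, 1], 0.3)
})
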