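grid1 <- volume_grid(c(1, 1, 1), c(1, 1, 1))
proto15 <- function(b = 1000) {
  dwi_protocol(c(0, rep(b, 15)), rbind(c(0, 0, 0), directions_fibonacci(15)))
}

test_that("the log-linear tensor fit recovers noiseless tensors exactly", {
  # isotropic
  Di <- diag(3) * 0.8e-3
  f <- fit_diffusion_tensor(tensor_series(Di, proto15(), grid1), 1000)
  expect_equal(f$mode, "full")
  expect_equal(as.numeric(f$components[1, 1, 1, 1:3]), rep(0.8e-3, 3),
               tolerance = 1e-10)
  expect_lt(max(abs(f$components[1, 1, 1, 4:6])), 1e-12 * 1e-3)
  # anisotropic diagonal (log-linear system is consistent -> exact)
  Da <- diag(c(0.3, 0.6, 1.8)) * 1e-3
  fa <- fit_diffusion_tensor(tensor_series(Da, proto15(), grid1), 1000)
  expect_equal(tensor_unpack(fa$components[1, 1, 1, ]), Da,
               tolerance = 1e-10)
  # rotated full tensor
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Dr <- R %*% Da %*% t(R)
  fr <- fit_diffusion_tensor(tensor_series(Dr, proto15(), grid1), 1000)
  expect_equal(tensor_unpack(fr$components[1, 1, 1, ]), Dr,
               tolerance = 1e-10)
})

test_that("an orthogonal triple triggers diagonal-only mode", {
  p3 <- dwi_protocol(c(0, rep(1000, 3)), rbind(c(0, 0, 0), diag(3)))
  Da <- diag(c(0.3, 0.6, 1.8)) * 1e-3
  f <- fit_diffusion_tensor(tensor_series(Da, p3, grid1), 1000)
  expect_equal(f$mode, "diagonal_only")
  expect_equal(as.numeric(f$components[1, 1, 1, 1:3]), diag(Da),
               tolerance = 1e-10)
  expect_true(all(is.nan(f$components[1, 1, 1, 4:6])))
  # two directions are not enough for any mode
  p2 <- dwi_protocol(c(0, 1000, 1000), rbind(c(0, 0, 0), diag(3)[1:2, ]))
  expect_error(fit_diffusion_tensor(tensor_series(Da, p2, grid1), 1000),
               "orthogonal")
})

test_that("eigendecomposition is ascending, orthonormal and right-handed", {
  e <- eigendecompose(diag(c(3, 1, 2)) * 1e-3)
  expect_equal(e$values, c(1, 2, 3) * 1e-3)
  expect_equal(abs(e$vectors), diag(3)[, c(2, 3, 1)], tolerance = 1e-12)

  th <- 0.8
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  D <- R %*% diag(c(1, 2, 3) * 1e-3) %*% t(R)   # oracle: D = R Lambda R'
  er <- eigendecompose(D)
  expect_equal(er$values, c(1, 2, 3) * 1e-3, tolerance = 1e-12)
  for (k in 1:3) {
    v <- er$vectors[, k]
    expect_equal(abs(sum(v * R[, k])), 1, tolerance = 1e-10)
  }
  expect_equal(crossprod(er$vectors), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(det(er$vectors), 1, tolerance = 1e-10)

  # degenerate isotropic case: any orthonormal basis is acceptable
  ei <- eigendecompose(diag(3) * 1e-3)
  expect_equal(ei$values, rep(1e-3, 3))
  expect_equal(crossprod(ei$vectors), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("negative eigenvalues are clipped to the floor", {
  e <- eigendecompose(diag(c(-0.5, 1, 2)) * 1e-3)
  expect_equal(e$values[1], 1e-6)
  expect_equal(e$clipped, 1)
})

test_that("eta matches its closed form", {
  expect_equal(compute_eta(1e-3, c(0.8, 1.0, 1.2) * 1e-3), 1)
  expect_equal(compute_eta(0.75e-3, c(0.8, 1.0, 1.2) * 1e-3), 0.75)
  expect_equal(compute_eta(0, c(0.8, 1.0, 1.2) * 1e-3), 0)
  expect_true(is.nan(compute_eta(1e-3, c(0, 0, 0))))
})

test_that("the extracellular tensor is the eta-scaled measured tensor", {
  comp <- array(0, c(1, 1, 1, 6))
  comp[1, 1, 1, ] <- c(0.8, 1.0, 1.2, 0, 0, 0) * 1e-3
  field <- structure(list(components = comp, b_used = 1000, mode = "full",
                          grid = grid1), class = "diffusion_tensor_field")
  ext <- extracellular_tensor(field, 0.75)
  expect_equal(as.numeric(ext$components[1, 1, 1, 1:3]),
               c(0.6, 0.75, 0.9) * 1e-3)
  # eta = 1 is the identity
  expect_equal(extracellular_tensor(field, 1)$components, comp)
  # trace(D_ext) = 3 d_w^e by construction of eta
  d_w_e <- 0.66e-3
  eta <- compute_eta(d_w_e, c(0.8, 1.0, 1.2) * 1e-3)
  ext2 <- extracellular_tensor(field, eta)
  expect_equal(sum(ext2$components[1, 1, 1, 1:3]), 3 * d_w_e,
               tolerance = 1e-12)
  # scaling preserves eigenvectors (random symmetric input)
  set.seed(9)
  M <- matrix(rnorm(9), 3); M <- (M + t(M)) * 1e-4; diag(M) <- abs(diag(M)) + 1e-3
  cf <- array(0, c(1, 1, 1, 6)); cf[1, 1, 1, ] <- tensor_pack(M)
  fld <- structure(list(components = cf, b_used = 1000, mode = "full",
                        grid = grid1), class = "diffusion_tensor_field")
  ee <- eigendecompose(tensor_unpack(extracellular_tensor(fld, 0.6)$components[1, 1, 1, ]))
  e0 <- eigendecompose(M)
  expect_equal(abs(diag(crossprod(ee$vectors, e0$vectors))), rep(1, 3),
               tolerance = 1e-9)
})

test_that("the conductivity tensor closes the algebraic chain", {
  # worked voxel: alpha = 0.6, c_e = 0.5855, D_ext mean 1.3333 um^2/ms
  alpha <- array(0.6, c(1, 1, 1))
  ce <- array(0.55 / (0.8 + 0.4 * 0.41 * 0.85), c(1, 1, 1))
  comp <- array(0, c(1, 1, 1, 6))
  comp[1, 1, 1, 1:3] <- c(1.2, 4 / 3, 22 / 15) * 1e-3   # mm^2/s
  ext <- structure(list(components = comp, grid = grid1),
                   class = "extracellular_tensor_field")
  cl <- conductivity_tensor(alpha, ce, ext)
  expect_equal(as.numeric(cl$components[1, 1, 1, 1:3]),
               c(0.4216, 0.4684, 0.5152), tolerance = 5e-4)
  # mean diagonal equals sigma_L = alpha c_e d_w^e
  expect_equal(mean(cl$components[1, 1, 1, 1:3]),
               0.6 * ce[1] * (4 / 3), tolerance = 1e-12)
  # alpha = 0 kills the tensor
  cl0 <- conductivity_tensor(array(0, c(1, 1, 1)), ce, ext)
  expect_equal(max(abs(cl0$components)), 0)
  # doubling d_w^e (via eta) doubles every component
  cl2 <- conductivity_tensor(alpha, ce,
                             structure(list(components = comp * 2,
                                            grid = grid1),
                                       class = "extracellular_tensor_field"))
  expect_equal(cl2$components, cl$components * 2)
})

test_that("C_L and D_b commute (simultaneously diagonalizable)", {
  set.seed(17)
  for (i in 1:5) {
    M <- matrix(rnorm(9), 3); M <- (M + t(M)) * 1e-4
    diag(M) <- abs(diag(M)) + 1.5e-3
    comp <- array(0, c(1, 1, 1, 6)); comp[1, 1, 1, ] <- tensor_pack(M)
    fld <- structure(list(components = comp, grid = grid1),
                     class = "diffusion_tensor_field")
    eta <- compute_eta(1e-3, fld)
    ext <- extracellular_tensor(fld, eta)
    cl <- conductivity_tensor(array(runif(1, 0.2, 1), c(1, 1, 1)),
                              array(runif(1, 0.3, 1.2), c(1, 1, 1)), ext)
    CL <- tensor_unpack(cl$components[1, 1, 1, ])
    expect_lt(max(abs(CL %*% M - M %*% CL)), 1e-10)
  }
})
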