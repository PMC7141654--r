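#' Fit the diffusion tensor at a fixed b-value
#'
#' Log-linear least squares of ln(S/S0) = -b g' D g over the acquisitions
#' whose b-value matches `b_target` (within `b_tol`). Full-tensor mode
#' needs at least 6 non-coplanar directions; an orthogonal direction
#' triple is accepted in `diagonal_only` mode, which estimates only the
#' diagonal (off-diagonals reported `NaN`).
#'
#' @param series a [dwi_series].
#' @param b_target b-value of the tensor shell, s/mm^2.
#' @param mask logical array; defaults to the grid mask.
#' @param b_tol acquisition-matching tolerance, s/mm^2.
#' @return object of class `diffusion_tensor_field`: `components` (4-D
#'   array, 6 volumes in order xx, yy, zz, xy, xz, yz; mm^2/s), `b_used`,
#'   `mode`, `grid`.
#' @export
fit_diffusion_tensor <- function(series, b_target = 1000, mask = NULL,
                                 b_tol = 5) {
  if (is.null(mask)) mask <- series$grid$mask
  sel <- which(abs(series$protocol$b_values - b_target) <= b_tol &
               series$protocol$b_values > 0)
  if (!length(sel)) stop("no acquisitions at b = ", b_target)
  g <- series$protocol$directions[sel, , drop = FALSE]
  b <- series$protocol$b_values[sel]
  n <- nrow(g)
  G6 <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
              2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  mode <- if (n >= 6L && qr(G6)$rank == 6L) "full" else {
    ortho <- n == 3L && max(abs(crossprod(t(g)) - diag(3))) < 1e-6
    if (!ortho)
      stop("need >= 6 non-coplanar directions (full) or an orthogonal ",
           "triple (diagonal_only) at b = ", b_target)
    "diagonal_only"
  }
  G <- if (mode == "full") G6 else G6[, 1:3, drop = FALSE]
  P <- solve(crossprod(G), t(G))         # (G'G)^{-1} G'
  vox <- which(mask & series$s0 > 0)
  sig <- matrix(series$signals, ncol = dim(series$signals)[4])[vox, sel,
                                                               drop = FALSE]
  y <- -log(pmax(sig / series$s0[vox], .Machine$double.eps)) / rep(b, each = length(vox))
  bad <- sig <= 0
  if (any(bad)) {
    mbcti_log("info", "%d non-positive signal value(s) at tensor shell", sum(bad))
    y[bad] <- NA
  }
  coefs <- t(apply(y, 1L, function(r) {
    ok <- is.finite(r)
    if (sum(ok) < ncol(G)) return(rep(NA_real_, ncol(G)))
    if (all(ok)) as.numeric(P %*% r)
    else as.numeric(solve(crossprod(G[ok, , drop = FALSE]),
                          crossprod(G[ok, , drop = FALSE], r[ok])))
  }))
  dm <- series$grid$shape
  comp <- array(NaN, dim = c(dm, 6L))
  for (k in seq_len(ncol(G))) {
    m <- array(NaN, dim = dm); m[vox] <- coefs[, k]
    comp[, , , k] <- m
  }
  structure(list(components = comp, b_used = b_target, mode = mode,
                 grid = series$grid),
            class = "diffusion_tensor_field")
}

#' Per-voxel eigensystem of a symmetric tensor field
#'
#' Eigenvalues are returned in ascending order and clipped below at
#' `eps_d` (noise can produce non-positive-definite fits); eigenvectors
#' are orthonormal with a deterministic sign convention (largest-magnitude
#' component of the first two eigenvectors positive, third eigenvector
#' their cross product, so the basis is right-handed with det = +1).
#'
#' @param field a `diffusion_tensor_field`, or a single length-6 component
#'   vector / 3x3 symmetric matrix.
#' @param eps_d eigenvalue floor, mm^2/s.
#' @return for a single tensor, a list with `values` (ascending),
#'   `vectors` (columns), `clipped`; for a field, a list with `values`
#'   (4-D, 3 volumes), `vectors` (5-D, 3x3 per voxel), `n_clipped`.
#' @export
eigendecompose <- function(field, eps_d = 1e-6) {
  if (is.matrix(field) && all(dim(field) == c(3L, 3L)))
    return(.eig_one(field, eps_d))
  if (is.numeric(field) && length(field) == 6L)
    return(.eig_one(tensor_unpack(field), eps_d))
  comp <- field$components
  dm <- dim(comp)[1:3]
  vals <- array(NaN, dim = c(dm, 3L))
  vecs <- array(NaN, dim = c(dm, 3L, 3L))
  n_clipped <- 0L
  vox <- which(apply(is.finite(comp), 1:3, all))
  nvox <- prod(dm)
  cm <- matrix(comp, nrow = nvox)
  for (i in vox) {
    e <- .eig_one(tensor_unpack(cm[i, ]), eps_d)
    n_clipped <- n_clipped + e$clipped
    for (k in 1:3) {
      vals[i + (k - 1L) * nvox] <- e$values[k]
      for (r in 1:3) vecs[i + (r - 1L) * nvox + (k - 1L) * 3L * nvox] <- e$vectors[r, k]
    }
  }
  if (n_clipped > 0L)
    mbcti_log("info", "%d eigenvalue(s) clipped to %.1e", n_clipped, eps_d)
  list(values = vals, vectors = vecs, n_clipped = n_clipped)
}

.eig_one <- function(m, eps_d) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ord <- order(e$values)                       # ascending
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  clipped <- sum(vals < eps_d)
  vals <- pmax(vals, eps_d)
  for (k in 1:2) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  vecs[, 3] <- c(vecs[2, 1] * vecs[3, 2] - vecs[3, 1] * vecs[2, 2],
                 vecs[3, 1] * vecs[1, 2] - vecs[1, 1] * vecs[3, 2],
                 vecs[1, 1] * vecs[2, 2] - vecs[2, 1] * vecs[1, 2])
  list(values = vals, vectors = vecs, clipped = clipped)
}

#' Scale factor from measured to extracellular diffusion tensor
#'
#' eta = 3 d_w^e / (d1 + d2 + d3): the extracellular tensor shares the
#' eigenvectors of the measured tensor and its trace is matched to
#' 3 d_w^e.
#'
#' @param d_w_e extracellular mean diffusivity, mm^2/s (scalar or map).
#' @param eig eigenvalues: a length-3 vector, the result of
#'   [eigendecompose], or a tensor trace map divided by nothing (for maps,
#'   pass the `diffusion_tensor_field` and the trace is used directly,
#'   which equals the eigenvalue sum).
#' @return eta (scalar or map); `NaN` where the trace is zero.
#' @export
compute_eta <- function(d_w_e, eig) {
  tr <- if (is.numeric(eig) && length(eig) == 3L) sum(eig)
        else if (is.list(eig) && !is.null(eig$values) && is.null(dim(eig$values)[4]))
          sum(eig$values)
        else if (is.list(eig) && !is.null(eig$values))
          .vol_sum(eig$values, 1:3)
        else if (is.list(eig) && !is.null(eig$components))
          .vol_sum(eig$components, 1:3)
        else stop("eig must be eigenvalues, an eigendecomposition, or a tensor field")
  eta <- 3 * d_w_e / tr
  eta[!is.finite(eta)] <- NaN
  if (length(eta) == 1L) as.numeric(eta) else eta
}

#' Extracellular diffusion tensor
#'
#' D_ext = eta D_b componentwise, so D_ext shares eigenvectors with D_b
#' and trace(D_ext) = 3 d_w^e by construction of eta.
#'
#' @param field a `diffusion_tensor_field`.
#' @param eta scalar or 3-D map from [compute_eta].
#' @return a `diffusion_tensor_field`-shaped list with `components`
#'   (mm^2/s), `eta`, `grid`.
#' @export
extracellular_tensor <- function(field, eta) {
  comp <- field$components
  if (length(eta) > 1L) {
    for (k in 1:6)
      comp[, , , k] <- as.vector(comp[, , , k, drop = FALSE]) * as.vector(eta)
  } else comp <- comp * eta
  structure(list(components = comp, eta = eta, b_used = field$b_used,
                 mode = field$mode, grid = field$grid),
            class = "extracellular_tensor_field")
}

#' Low-frequency conductivity tensor
#'
#' C_L = alpha c_e D_ext voxel-wise. c_e is in S ms/(m um^2) and the
#' tensor components in mm^2/s; the conversion to um^2/ms (x 1e3) is
#' handled internally so that C_L comes out in S/m. Its mean diagonal
#' (trace/3) equals sigma_L wherever the inputs are valid.
#'
#' @param alpha extracellular volume fraction map.
#' @param c_e apparent extracellular ion concentration map (or the list
#'   from [estimate_ion_concentration]).
#' @param ext an `extracellular_tensor_field`.
#' @return object of class `conductivity_tensor_field` with `components`
#'   (4-D, 6 volumes, S/m) and `grid`.
#' @export
conductivity_tensor <- function(alpha, c_e, ext) {
  if (is.list(c_e)) c_e <- c_e$c_e
  comp <- ext$components * 1e3            # mm^2/s -> um^2/ms
  scale <- alpha * c_e
  for (k in 1:6)
    comp[, , , k] <- as.vector(comp[, , , k, drop = FALSE]) * as.vector(scale)
  structure(list(components = comp, grid = ext$grid),
            class = "conductivity_tensor_field")
}
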