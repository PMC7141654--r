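# Array shift and small neighbourhood filters used by the PDE kernels and
# the phantom generator. All operate on 3-D arrays; "in-plane" means the
# first two axes (the acquisition geometry is slice-based).

# Sum selected volumes of a 4-D stack, preserving the 3-D shape (guards
# against R dropping singleton dimensions).
.vol_sum <- function(a, k) {
  dm <- dim(a)
  out <- array(0, dim = dm[1:3])
  for (j in k) out <- out + array(a[, , , j, drop = FALSE], dim = dm[1:3])
  out
}

# result[i] = a[i + by] along axis `ax`; padded with `fill`.
shift_arr <- function(a, ax, by, fill = NA) {
  dm <- dim(a)
  out <- array(fill, dim = dm)
  n <- dm[ax]
  if (abs(by) >= n) return(out)
  src <- vector("list", 3L); dst <- vector("list", 3L)
  for (k in 1:3) { src[[k]] <- seq_len(dm[k]); dst[[k]] <- seq_len(dm[k]) }
  if (by >= 0) { dst[[ax]] <- seq_len(n - by); src[[ax]] <- seq_len(n - by) + by }
  else { dst[[ax]] <- seq_len(n + by) - by; src[[ax]] <- seq_len(n + by) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Mask-aware in-plane Gaussian smoothing: the kernel is renormalized over
# the in-mask voxels so region values are not dragged toward the (empty)
# exterior. sigma in voxels; sigma = 0 is the identity.
gaussian_smooth_inplane <- function(a, sigma, mask = NULL) {
  if (sigma <= 0) return(a)
  dm <- dim(a)
  if (is.null(mask)) mask <- array(TRUE, dim = dm)
  r <- max(1L, ceiling(3 * sigma))
  off <- -r:r
  w1 <- exp(-off^2 / (2 * sigma^2))
  num <- array(0, dim = dm); den <- array(0, dim = dm)
  az <- a; az[!mask] <- 0
  mz <- array(0, dim = dm); mz[mask] <- 1
  for (dx in off) for (dy in off) {
    w <- w1[dx + r + 1L] * w1[dy + r + 1L]
    num <- num + w * shift_arr(shift_arr(az, 1L, dx, fill = 0), 2L, dy, fill = 0)
    den <- den + w * shift_arr(shift_arr(mz, 1L, dx, fill = 0), 2L, dy, fill = 0)
  }
  out <- array(NA_real_, dim = dm)
  ok <- mask & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

# 3x3 in-plane median filter over voxels where `valid` (and value finite);
# voxels with no valid neighbour keep NA.
median_filter3_inplane <- function(a, valid = NULL) {
  dm <- dim(a)
  if (is.null(valid)) valid <- is.finite(a)
  stack <- vector("list", 9L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    v <- a; v[!valid] <- NA
    stack[[k]] <- shift_arr(shift_arr(v, 1L, dx), 2L, dy)
  }
  m <- do.call(cbind, lapply(stack, as.vector))
  out <- apply(m, 1L, stats::median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  array(out, dim = dm)
}
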