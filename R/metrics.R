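#' Value-based Dice similarity of two maps
#'
#' DSC = 2 |a . b| / (||a||^2 + ||b||^2) on the raw voxel values, the
#' vector form used to compare reconstructions — not the binary
#' set-overlap Dice. It is symmetric but scale-sensitive:
#' DSC(a, 2a) = 4/5. Voxel pairs where either value is `NaN` are excluded
#' before the computation.
#'
#' @param a,b numeric vectors (or arrays) of equal length.
#' @return scalar in [0, 1]; 0 by convention when both inputs are
#'   all-zero.
#' @export
dsc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (!length(a)) stop("no finite voxel pairs")
  den <- sum(a^2) + sum(b^2)
  if (den == 0) return(0)
  2 * abs(sum(a * b)) / den
}

#' Relative L2 error against a reference map
#'
#' ||a - b|| / ||a|| with `a` the reference (e.g. the full-protocol
#' reconstruction) — the measure is asymmetric in its arguments by
#' definition. `NaN` pairs are excluded.
#'
#' @param a reference values; must have a positive norm.
#' @param b comparison values.
#' @return scalar >= 0.
#' @export
relative_l2 <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  na <- sqrt(sum(a^2))
  if (na == 0) stop("reference norm is zero")
  sqrt(sum((a - b)^2)) / na
}

#' Per-region mean and standard deviation of a map
#'
#' Reports mean, population standard deviation (divisor n) and voxel
#' count per label over the non-`NaN` voxels, mirroring ROI tables of the
#' form mean +/- SD.
#'
#' @param map numeric array.
#' @param label_map integer array of the same shape; non-negative labels,
#'   0 = background (excluded).
#' @return data.frame with columns `label`, `mean`, `sd`, `n`.
#' @export
roi_statistics <- function(map, label_map) {
  if (!identical(dim(map), dim(label_map)))
    stop("map and label map do not share one grid")
  labs <- sort(unique(as.integer(label_map[label_map > 0])))
  if (!length(labs)) stop("label map has no positive labels")
  rows <- lapply(labs, function(l) {
    v <- map[label_map == l]
    v <- v[is.finite(v)]
    if (!length(v)) stop("label ", l, " has no finite voxels")
    data.frame(label = l, mean = mean(v),
               sd = sqrt(mean((v - mean(v))^2)), n = length(v))
  })
  do.call(rbind, rows)
}

#' Region-wise comparison report of two maps
#'
#' Convenience wrapper computing [dsc] and [relative_l2] per label (plus a
#' whole-region row with label 0).
#'
#' @param ref reference map (full-protocol reconstruction).
#' @param test comparison map.
#' @param label_map integer array; `NULL` for a single overall row.
#' @return data.frame with columns `label`, `dsc`, `rel_l2`, `n`.
#' @export
comparison_report <- function(ref, test, label_map = NULL) {
  one <- function(sel, lab) {
    a <- ref[sel]; b <- test[sel]
    ok <- is.finite(a) & is.finite(b)
    data.frame(label = lab, dsc = dsc(a, b), rel_l2 = relative_l2(a, b),
               n = sum(ok))
  }
  out <- one(TRUE & array(TRUE, dim = dim(ref)), 0L)
  if (!is.null(label_map)) {
    labs <- sort(unique(as.integer(label_map[label_map > 0])))
    out <- rbind(out, do.call(rbind, lapply(labs, function(l)
      one(label_map == l, l))))
  }
  out
}
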