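#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 image and returns its payload together with the
#' `volume_grid` implied by the header spacing. Values are returned with
#' `scl_slope`/`scl_inter` already applied (RNifti semantics), so writing a
#' map back and re-reading it is idempotent. No resampling or reorientation
#' is performed; voxel-index space is used throughout the pipeline.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (3-D or 4-D numeric array), `grid`
#'   ([volume_grid] of the first three dimensions) and `header`
#'   (the NIfTI header, for provenance).
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI image: ", path,
                                           " (", conditionMessage(e), ")"))
  data <- as.array(img)
  dm <- dim(data)
  data <- array(as.vector(data), dim = dm)   # plain numeric array
  if (length(dm) < 3L) dim(data) <- dm <- c(dm, rep(1L, 3L - length(dm)))
  hdr <- RNifti::niftiHeader(img)
  ndim <- hdr$dim[1]
  sp <- abs(hdr$pixdim[2:4])
  if (any(!is.finite(sp[seq_len(min(3L, ndim))])) ||
      any(sp[seq_len(min(3L, ndim))] <= 0))
    stop("invalid NIfTI header: non-positive voxel spacing in ", path)
  sp[!is.finite(sp) | sp <= 0] <- 1     # padding for absent dimensions
  grid <- volume_grid(dm[1:3], sp[1:3])
  list(data = data, grid = grid, header = hdr)
}

#' Write a map to NIfTI
#'
#' Writes a 3-D map (or a 4-D stack, e.g. a 6-component tensor field) with
#' the grid spacing in the header. `NaN` is preserved for masked-out voxels
#' (data are written as floating point).
#'
#' @param field numeric array whose first three dimensions match `grid`.
#' @param grid a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map <- function(field, grid, path) {
  dm <- dim(field)
  if (is.null(dm)) stop("field must be an array")
  if (length(dm) < 3L) dim(field) <- dm <- c(dm, rep(1L, 3L - length(dm)))
  if (!identical(as.integer(dm[1:3]), grid$shape))
    stop("field shape does not match grid")
  # oro.nifti writes dim/pixdim verbatim (singleton slice dimensions and
  # their spacing survive the round trip); payload as float64
  nim <- oro.nifti::nifti(field * 1.0, datatype = 64, bitpix = 64)
  nim@pixdim <- c(1, grid$spacing, rep(1, 4))[seq_len(8)]
  gz <- grepl("\\.gz$", path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  oro.nifti::writeNIfTI(nim, stem, gzipped = gz)
  invisible(path)
}

# Tensor component order used for serialization everywhere in the pipeline.
TENSOR_COMPONENTS <- c("xx", "yy", "zz", "xy", "xz", "yz")

#' Pack / unpack symmetric 3x3 tensors
#'
#' Tensor fields are stored as 6-component 4-D volumes in the fixed order
#' (xx, yy, zz, xy, xz, yz) so that serialization is bit-stable across the
#' pipeline.
#'
#' @param m a symmetric 3x3 matrix.
#' @return `tensor_pack`: length-6 vector; `tensor_unpack`: 3x3 matrix.
#' @export
tensor_pack <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

#' @rdname tensor_pack
#' @param v length-6 component vector in order (xx, yy, zz, xy, xz, yz).
#' @export
tensor_unpack <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

#' Read FSL-style bval/bvec files into a DWI protocol
#'
#' b-values and gradient directions are aligned by acquisition index. The
#' bvec dialect (3 rows of n entries, FSL style, vs n rows of 3) is
#' auto-detected from the shape; the ambiguous 3x3 case is taken as FSL
#' rows. Non-unit directions at b > 0 are renormalized with a warning when
#' they deviate from unit norm by more than 1e-3; zero-norm vectors are only
#' allowed at b = 0.
#'
#' @param bval_path,bvec_path paths to whitespace-separated text files.
#' @return a [dwi_protocol].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  lines <- readLines(bvec_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
    if (any(is.na(v))) stop("non-numeric token in bvec file ", bvec_path)
    v
  })
  n <- length(bvals)
  nr <- length(rows)
  lens <- vapply(rows, length, integer(1))
  if (nr == 3L && all(lens == n)) {
    dirs <- t(do.call(rbind, rows))            # FSL: 3 rows x n columns
  } else if (all(lens == 3L) && nr == n) {
    dirs <- do.call(rbind, rows)               # n rows x 3 columns
  } else {
    stop("bvec shape (", nr, " rows) does not match ", n, " b-values")
  }
  dwi_protocol(bvals, dirs)
}

#' Construct a DWI protocol
#'
#' @param b_values non-negative b-values, s/mm^2.
#' @param directions n x 3 matrix of gradient directions (unit vectors;
#'   ignored and stored as zero where b = 0).
#' @param timing optional data.frame with columns `delta` (s), `Delta` (s),
#'   `G` (T/m) per acquisition.
#' @return object of class `dwi_protocol`.
#' @export
dwi_protocol <- function(b_values, directions, timing = NULL) {
  b_values <- as.numeric(b_values)
  if (any(!is.finite(b_values)) || any(b_values < 0))
    stop("b-values must be finite and non-negative")
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L || nrow(directions) != length(b_values))
    stop("directions must be an n x 3 matrix matching b_values in length")
  nrm <- sqrt(rowSums(directions^2))
  b0 <- b_values == 0
  if (any(!b0 & nrm == 0))
    stop("zero-norm gradient direction at non-zero b-value")
  off <- !b0 & abs(nrm - 1) > 1e-6
  if (any(off)) {
    bad <- which(off & abs(nrm - 1) > 1e-3)
    if (length(bad))
      warning(sprintf("%d non-unit gradient direction(s) renormalized", length(bad)))
    directions[off, ] <- directions[off, ] / nrm[off]
  }
  directions[b0, ] <- 0
  if (!is.null(timing)) {
    stopifnot(all(c("delta", "Delta", "G") %in% names(timing)),
              nrow(timing) == length(b_values))
    if (any(timing$Delta <= timing$delta / 3) || any(timing$delta <= 0))
      stop("gradient timing must satisfy Delta > delta/3 > 0")
  }
  structure(list(b_values = b_values, directions = directions, timing = timing),
            class = "dwi_protocol")
}

#' Write a protocol as FSL bval/bvec text files
#'
#' @param protocol a [dwi_protocol].
#' @param bval_path,bvec_path output paths.
#' @export
write_bval_bvec <- function(protocol, bval_path, bvec_path) {
  writeLines(paste(format(protocol$b_values, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  tx <- t(protocol$directions)
  writeLines(apply(tx, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' Multi-b-value DWI series
#'
#' @param signals 4-D non-negative array (grid x acquisitions).
#' @param protocol a [dwi_protocol] with one entry per acquisition.
#' @param grid a [volume_grid].
#' @param s0 optional 3-D array of b = 0 signal; computed as the mean over
#'   the protocol's b = 0 acquisitions when omitted.
#' @return object of class `dwi_series`.
#' @export
dwi_series <- function(signals, protocol, grid, s0 = NULL) {
  dm <- dim(signals)
  stopifnot(length(dm) == 4L)
  if (!identical(as.integer(dm[1:3]), grid$shape))
    stop("signal shape does not match grid")
  if (dm[4] != length(protocol$b_values))
    stop("number of volumes does not match protocol length")
  if (is.null(s0)) {
    i0 <- which(protocol$b_values == 0)
    if (!length(i0)) stop("protocol has no b = 0 acquisition and no s0 supplied")
    s0 <- apply(signals[, , , i0, drop = FALSE], 1:3, mean)
  }
  structure(list(signals = signals, protocol = protocol, grid = grid, s0 = s0),
            class = "dwi_series")
}

#' The 15 diffusion weightings of the reference acquisition protocol
#'
#' @return numeric vector of b-values, s/mm^2.
#' @export
reference_b_values <- function() {
  c(50, 150, 300, 500, 700, 1000, 1400, 1800, 2200, 2600,
    3000, 3600, 4000, 4500, 5000)
}
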