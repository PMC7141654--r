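#' Default pipeline configuration
#'
#' Flat key-value configuration shared by all stages. Values can be
#' overridden by a YAML config file ([read_config]) and, in the command-line
#' interface, by flags (flags win over the file).
#'
#' @return named list of configuration values:
#' \describe{
#'   \item{omega_hz}{Larmor frequency, Hz (128e6 at 3 T).}
#'   \item{mu0}{magnetic permeability of free space, T m/A.}
#'   \item{c_diffusion}{artificial diffusion coefficient of the stabilized
#'     inversion, dimensionless in the metre-lattice discretization.}
#'   \item{beta}{assumed intracellular/extracellular ion-concentration ratio.}
#'   \item{d_ic}{intracellular (restricted) diffusivity, mm^2/s.}
#'   \item{d_iso}{free-water (CSF) diffusivity, mm^2/s.}
#'   \item{tensor_b_value}{b-value at which the diffusion tensor is fitted.}
#'   \item{nls_multistarts}{number of deterministic starts for the
#'     compartment fits.}
#'   \item{snr}{phantom S0-to-noise ratio.}
#' }
#' @export
default_config <- function() {
  list(
    omega_hz       = 128e6,
    mu0            = 4 * pi * 1e-7,
    c_diffusion    = 0.025,
    beta           = 0.41,
    d_ic           = 1.7e-3,
    d_iso          = 3.0e-3,
    tensor_b_value = 1000,
    nls_multistarts = 5,
    snr            = 100
  )
}

#' Read a flat YAML configuration file
#'
#' Unknown keys are rejected so that typos in a run configuration fail
#' loudly rather than silently falling back to defaults.
#'
#' @param path YAML file with a flat mapping.
#' @return full configuration list (file values over defaults).
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(vals)] <- vals
  cfg
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the logging threshold
#'
#' @param level one of "debug", "info", "warn", "error".
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  options(mbcti.log_level = level)
  invisible(level)
}

mbcti_log <- function(level, fmt, ...) {
  threshold <- .log_levels[[getOption("mbcti.log_level", "info")]]
  if (.log_levels[[level]] >= threshold)
    message(sprintf("[mbcti %s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

# Each stage logs its parameter set and the md5 checksums of file inputs at
# start, so reconstructions run with different protocols (e.g. 15 vs 7
# b-values) stay traceable.
log_stage <- function(stage, params = list(), inputs = character()) {
  ptxt <- if (length(params))
    paste(names(params), vapply(params, function(v)
      paste(format(v, digits = 6), collapse = ","), character(1)),
      sep = "=", collapse = " ")
  else "(defaults)"
  mbcti_log("info", "stage %s: %s", stage, ptxt)
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    for (i in seq_along(sums))
      mbcti_log("info", "input %s md5=%s", names(sums)[i], sums[i])
  }
  invisible(NULL)
}
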