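#' Fixed compartment diffusivities
#'
#' The intracellular (restricted) and free-water diffusivities are fixed a
#' priori, following common multi-compartment practice: d_ic = 1.7e-3 and
#' d_iso = 3.0e-3 mm^2/s.
#'
#' @param d_ic intracellular diffusivity, mm^2/s.
#' @param d_iso free-water (CSF) diffusivity, mm^2/s.
#' @return object of class `fixed_diffusivities`.
#' @export
fixed_diffusivities <- function(d_ic = 1.7e-3, d_iso = 3.0e-3) {
  stopifnot(d_ic > 0, d_iso > d_ic)
  structure(list(d_ic = d_ic, d_iso = d_iso), class = "fixed_diffusivities")
}

#' Options for the per-voxel nonlinear least-squares fits
#'
#' The multi-exponential objective has local minima, so each voxel is
#' fitted from a deterministic multi-start grid and the best residual wins
#' (ties broken by smallest offset nu_0). Bounds: volume fractions in
#' [0, 1], offset nu_0 in [0, 0.2] (a noise floor), extracellular
#' diffusivity parameter in [0.1, 3.0]e-3 mm^2/s.
#'
#' @param max_iter maximum optimizer iterations per start.
#' @param ptol absolute parameter tolerance.
#' @param nu0_max upper bound of the offset fraction.
#' @param d_star_bounds bounds of d*_e, mm^2/s.
#' @return list of options.
#' @export
fit_options <- function(max_iter = 500L, ptol = 1e-8, nu0_max = 0.2,
                        d_star_bounds = c(0.1e-3, 3.0e-3)) {
  list(max_iter = as.integer(max_iter), ptol = ptol, nu0_max = nu0_max,
       d_star_bounds = d_star_bounds)
}

#' Direction-aggregated per-voxel signal table
#'
#' The compartment models are isotropic, so acquisitions are collapsed per
#' unique b-value by the geometric mean of the normalized signals S/S0 over
#' directions (the geometric mean of exp(-b g' D g) over directions equals
#' exp(-b mean ADC), so for a tensor substrate the aggregate decays with the
#' orientation-averaged diffusivity). Ratios are clipped to (0, 1.5];
#' non-positive signals are dropped with a log count. The b = 0
#' acquisitions serve only as the normalization reference S0 (their own
#' ratio is identically 1 and carries no information), so the table
#' contains the positive b-values.
#'
#' @param series a [dwi_series].
#' @param mask logical array; defaults to the series grid mask.
#' @return list with `b_values` (sorted unique), `signals` (matrix, masked
#'   voxels x b-values), `voxels` (linear indices into the grid).
#' @export
aggregate_directions <- function(series, mask = NULL) {
  if (is.null(mask)) mask <- series$grid$mask
  vox <- which(mask & series$s0 > 0)
  if (any(mask & !(series$s0 > 0)))
    mbcti_log("warn", "%d voxel(s) dropped: s0 <= 0", sum(mask & !(series$s0 > 0)))
  b <- series$protocol$b_values
  ub <- sort(unique(b[b > 0]))
  nvol <- dim(series$signals)[4]
  sig <- matrix(series$signals, ncol = nvol)[vox, , drop = FALSE]
  s0 <- series$s0[vox]
  out <- matrix(NA_real_, nrow = length(vox), ncol = length(ub))
  dropped <- 0L
  for (k in seq_along(ub)) {
    cols <- which(b == ub[k])
    r <- sig[, cols, drop = FALSE] / s0
    bad <- r <= 0
    dropped <- dropped + sum(bad)
    lr <- log(r); lr[bad] <- NA
    gm <- exp(rowMeans(lr, na.rm = TRUE))
    gm[!is.finite(gm)] <- NA
    out[, k] <- pmin(gm, 1.5)
  }
  if (dropped > 0L)
    mbcti_log("info", "%d non-positive signal value(s) dropped", dropped)
  list(b_values = ub, signals = out, voxels = vox)
}

#' Forward multi-compartment signal model
#'
#' Normalized signal of the four-parameter constrained model:
#' S/S0 = (1 - nu_iso) [ nu_ic exp(-b nu_ic d_ic)
#'        + (1 - nu_ic) exp(-b (1 - nu_ic) d*_e) ]
#'        + nu_iso exp(-b d_iso) + nu_0.
#' The intracellular decay uses the composite rate nu_ic d_ic and the
#' extracellular one (1 - nu_ic) d*_e, which is what makes the model
#' identifiable from b-value decays alone (no orientation information).
#'
#' @param par named list or vector with `nu_ic`, `d_star_e` (mm^2/s),
#'   `nu_iso`, `nu_0`.
#' @param fixed a [fixed_diffusivities].
#' @param b_values b-values, s/mm^2.
#' @return normalized signals, same length as `b_values`.
#' @export
mbd_forward <- function(par, fixed = fixed_diffusivities(), b_values) {
  p <- .as_mbd_par(par)
  stopifnot(all(b_values >= 0))
  as.numeric(
    (1 - p["nu_iso"]) *
      (p["nu_ic"] * exp(-b_values * p["nu_ic"] * fixed$d_ic) +
       (1 - p["nu_ic"]) * exp(-b_values * (1 - p["nu_ic"]) * p["d_star_e"])) +
      p["nu_iso"] * exp(-b_values * fixed$d_iso) + p["nu_0"])
}

.as_mbd_par <- function(par) {
  if (is.list(par)) par <- unlist(par)
  if (is.null(names(par)) || !all(c("nu_ic", "d_star_e", "nu_iso", "nu_0") %in% names(par)))
    names(par) <- c("nu_ic", "d_star_e", "nu_iso", "nu_0")
  par[c("nu_ic", "d_star_e", "nu_iso", "nu_0")]
}

# Deterministic multi-start grid: nu_ic sweeps its range, nu_iso alternates
# low/high, d*_e and nu_0 start at typical tissue values.
.mbd_starts <- function(n = 5L, opts = fit_options()) {
  nu_ic <- seq(0.1, 0.9, length.out = n)
  nu_iso <- rep(c(0.05, 0.5), length.out = n)
  cbind(nu_ic = nu_ic, d_star_e = 1.0e-3, nu_iso = nu_iso, nu_0 = 0.02)
}

#' Fit the four-parameter compartment model at one voxel
#'
#' Bounded Levenberg-Marquardt least squares from a deterministic
#' multi-start grid; the start with the smallest residual wins, ties broken
#' by the smallest offset nu_0.
#'
#' @param b_values distinct b-values, s/mm^2 (at least 5).
#' @param signals normalized signals S/S0 in (0, 1.5], same length.
#' @param fixed a [fixed_diffusivities].
#' @param opts a [fit_options] list.
#' @param n_starts number of multi-starts.
#' @return list with `nu_ic`, `d_star_e`, `nu_iso`, `nu_0`,
#'   `residual_norm`, `converged`.
#' @export
fit_mbd_model <- function(b_values, signals, fixed = fixed_diffusivities(),
                          opts = fit_options(), n_starts = 5L) {
  keep <- is.finite(signals) & is.finite(b_values)
  b_values <- b_values[keep]; signals <- signals[keep]
  if (length(unique(b_values)) < 5L)
    stop("fit_mbd_model requires at least 5 distinct b-values")
  if (any(signals <= 0) || any(signals > 1.5))
    stop("normalized signals must lie in (0, 1.5]")
  if (stats::sd(signals) == 0)
    return(list(nu_ic = 0, d_star_e = opts$d_star_bounds[1], nu_iso = 0,
                nu_0 = 0, residual_norm = sqrt(sum((signals - 1)^2)),
                converged = FALSE))
  lower <- c(0, opts$d_star_bounds[1], 0, 0)
  upper <- c(1, opts$d_star_bounds[2], 1, opts$nu0_max)
  resid <- function(p) {
    (1 - p[3]) * (p[1] * exp(-b_values * p[1] * fixed$d_ic) +
                  (1 - p[1]) * exp(-b_values * (1 - p[1]) * p[2])) +
      p[3] * exp(-b_values * fixed$d_iso) + p[4] - signals
  }
  starts <- .mbd_starts(n_starts, opts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = as.numeric(starts[i, ]), lower = lower, upper = upper, fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = opts$max_iter,
                                           ptol = opts$ptol, ftol = 1e-15)),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$deviance < best$deviance - 1e-15 ||
        (abs(f$deviance - best$deviance) <= 1e-15 && f$par[4] < best$par[4]))
      best <- f
  }
  if (is.null(best)) stop("all optimizer starts failed")
  list(nu_ic = best$par[1], d_star_e = best$par[2], nu_iso = best$par[3],
       nu_0 = best$par[4], residual_norm = sqrt(best$deviance),
       converged = best$info %in% c(1, 2, 3, 4) && best$niter < opts$max_iter)
}

#' Derive microstructure quantities from a compartment fit
#'
#' alpha = (1 - nu_iso)(1 - nu_ic) + nu_iso is the extracellular-plus-CSF
#' volume fraction;
#' d_w^e = [(1 - nu_iso)(1 - nu_ic)^2 d*_e + nu_iso d_iso] / alpha is the
#' extracellular mean diffusivity; d_w^i = nu_ic d_ic the intracellular
#' one. All diffusivities in mm^2/s.
#'
#' @param fit result of [fit_mbd_model] (list with the four parameters).
#' @param fixed a [fixed_diffusivities].
#' @return list with `alpha`, `d_w_e`, `d_w_i` (and `flagged` when alpha
#'   is 0 and d_w^e undefined).
#' @export
derive_microstructure <- function(fit, fixed = fixed_diffusivities()) {
  nu_ic <- fit$nu_ic; nu_iso <- fit$nu_iso
  alpha <- (1 - nu_iso) * (1 - nu_ic) + nu_iso
  if (alpha == 0)
    return(list(alpha = 0, d_w_e = NaN, d_w_i = nu_ic * fixed$d_ic,
                flagged = TRUE))
  d_w_e <- ((1 - nu_iso) * (1 - nu_ic)^2 * fit$d_star_e +
            nu_iso * fixed$d_iso) / alpha
  list(alpha = alpha, d_w_e = d_w_e, d_w_i = nu_ic * fixed$d_ic,
       flagged = FALSE)
}

#' Forward three-pool signal model
#'
#' Baseline multi-exponential model:
#' S/S0 = nu_ecm exp(-b d_ecm^w) + nu_ecw exp(-b d_ecw^w)
#'        + nu_i exp(-b d_i^w) + nu_0, with the free-water pool diffusivity
#' d_ecw^w fixed at 3.0e-3 mm^2/s.
#'
#' @param par named vector/list with `nu_ecm`, `nu_ecw`, `nu_i`, `d_ecm_w`,
#'   `d_i_w`, `nu_0`.
#' @param b_values b-values, s/mm^2.
#' @param d_ecw_w fixed free-water diffusivity, mm^2/s.
#' @return normalized signals.
#' @export
three_pool_forward <- function(par, b_values, d_ecw_w = 3.0e-3) {
  p <- unlist(par)[c("nu_ecm", "nu_ecw", "nu_i", "d_ecm_w", "d_i_w", "nu_0")]
  as.numeric(
    p["nu_ecm"] * exp(-b_values * p["d_ecm_w"]) +
      p["nu_ecw"] * exp(-b_values * d_ecw_w) +
      p["nu_i"] * exp(-b_values * p["d_i_w"]) + p["nu_0"])
}

#' Derived extracellular quantities of the three-pool model
#'
#' alpha = (nu_ecm + nu_ecw) / (nu_ecm + nu_ecw + nu_i);
#' d_w^e = (nu_ecm d_ecm^w + nu_ecw d_ecw^w) / (nu_ecm + nu_ecw);
#' the fitted d_i^w is carried as the intracellular diffusivity.
#'
#' @param par named list/vector with `nu_ecm`, `nu_ecw`, `nu_i`,
#'   `d_ecm_w`, `d_i_w`.
#' @param d_ecw_w fixed free-water diffusivity, mm^2/s.
#' @return list with `alpha`, `d_w_e`, `d_w_i` (`NaN` where a fraction
#'   sum vanishes).
#' @export
three_pool_derived <- function(par, d_ecw_w = 3.0e-3) {
  p <- as.list(par)
  ec <- p$nu_ecm + p$nu_ecw
  list(alpha = if (ec + p$nu_i > 0) ec / (ec + p$nu_i) else NaN,
       d_w_e = if (ec > 0) (p$nu_ecm * p$d_ecm_w + p$nu_ecw * d_ecw_w) / ec
               else NaN,
       d_w_i = p$d_i_w)
}

.three_pool_starts <- function() {
  rbind(c(0.3, 0.3, 0.3), c(0.5, 0.2, 0.2), c(0.2, 0.5, 0.2),
        c(0.2, 0.2, 0.5), c(0.4, 0.1, 0.4))
}

#' Fit the three-pool baseline model at one voxel
#'
#' Six free parameters (three pool fractions, two diffusivities, offset),
#' fitted like [fit_mbd_model] from a deterministic multi-start grid. The
#' derived extracellular quantities are
#' alpha = (nu_ecm + nu_ecw) / (nu_ecm + nu_ecw + nu_i) and
#' d_w^e = (nu_ecm d_ecm^w + nu_ecw d_ecw^w) / (nu_ecm + nu_ecw); the
#' fitted d_i^w is carried as the intracellular diffusivity.
#'
#' @inheritParams fit_mbd_model
#' @param d_ecw_w fixed free-water diffusivity, mm^2/s.
#' @return list with the six parameters plus derived `alpha`, `d_w_e`,
#'   `d_w_i`, `residual_norm`, `converged`.
#' @export
fit_three_pool <- function(b_values, signals, opts = fit_options(),
                           d_ecw_w = 3.0e-3) {
  keep <- is.finite(signals) & is.finite(b_values)
  b_values <- b_values[keep]; signals <- signals[keep]
  if (length(unique(b_values)) < 7L)
    stop("fit_three_pool requires at least 7 distinct b-values")
  lower <- c(0, 0, 0, opts$d_star_bounds[1], 0.01e-3, 0)
  upper <- c(1, 1, 1, opts$d_star_bounds[2], 3.0e-3, opts$nu0_max)
  resid <- function(p) {
    p[1] * exp(-b_values * p[4]) + p[2] * exp(-b_values * d_ecw_w) +
      p[3] * exp(-b_values * p[5]) + p[6] - signals
  }
  starts <- .three_pool_starts()
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(starts[i, ], 1.0e-3, 0.5e-3, 0.02)
    f <- tryCatch(minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper, fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = opts$max_iter,
                                           ptol = opts$ptol, ftol = 1e-15)),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$deviance < best$deviance - 1e-15 ||
        (abs(f$deviance - best$deviance) <= 1e-15 && f$par[6] < best$par[6]))
      best <- f
  }
  if (is.null(best)) stop("all optimizer starts failed")
  p <- stats::setNames(as.list(best$par),
                       c("nu_ecm", "nu_ecw", "nu_i", "d_ecm_w", "d_i_w",
                         "nu_0"))
  c(p, three_pool_derived(p, d_ecw_w),
    list(residual_norm = sqrt(best$deviance),
         converged = best$info %in% c(1, 2, 3, 4) &&
                     best$niter < opts$max_iter))
}

#' Fit a compartment model over all masked voxels
#'
#' Voxels are independent; execution order does not affect results.
#'
#' @param series a [dwi_series].
#' @param model `"mbd"` (four-parameter constrained model) or
#'   `"threepool"` (baseline).
#' @param mask logical array; defaults to the grid mask.
#' @param b_subset optional b-values to keep (b = 0 volumes are always
#'   kept for normalization and the b = 0 table point).
#' @param fixed a [fixed_diffusivities].
#' @param opts a [fit_options] list.
#' @return list of 3-D maps: model parameters, `alpha`, `d_w_e`, `d_w_i`,
#'   `residual`, `converged` (`NaN`/`NA` outside the fitted voxels).
#' @export
fit_compartment_maps <- function(series, model = c("mbd", "threepool"),
                                 mask = NULL, b_subset = NULL,
                                 fixed = fixed_diffusivities(),
                                 opts = fit_options()) {
  model <- match.arg(model)
  log_stage("fit-compartments",
            list(model = model,
                 b_subset = if (is.null(b_subset)) "all" else b_subset))
  agg <- aggregate_directions(series, mask)
  b <- agg$b_values
  keep <- if (is.null(b_subset)) rep(TRUE, length(b)) else (b %in% b_subset)
  b <- b[keep]
  sig <- agg$signals[, keep, drop = FALSE]
  dm <- series$grid$shape
  mk_map <- function() array(NaN, dim = dm)
  par_names <- if (model == "mbd") c("nu_ic", "d_star_e", "nu_iso", "nu_0")
               else c("nu_ecm", "nu_ecw", "nu_i", "d_ecm_w", "d_i_w", "nu_0")
  maps <- stats::setNames(replicate(length(par_names) + 5L, mk_map(),
                                    simplify = FALSE),
                          c(par_names, "alpha", "d_w_e", "d_w_i",
                            "residual", "converged"))
  for (v in seq_along(agg$voxels)) {
    s <- sig[v, ]
    if (any(!is.finite(s))) next
    fit <- if (model == "mbd") {
      ft <- fit_mbd_model(b, s, fixed, opts)
      c(ft, derive_microstructure(ft, fixed))
    } else {
      fit_three_pool(b, s, opts)
    }
    i <- agg$voxels[v]
    for (nm in par_names) maps[[nm]][i] <- fit[[nm]]
    maps$alpha[i] <- fit$alpha
    maps$d_w_e[i] <- fit$d_w_e
    maps$d_w_i[i] <- fit$d_w_i
    maps$residual[i] <- fit$residual_norm
    maps$converged[i] <- as.numeric(isTRUE(fit$converged))
  }
  maps$model <- model
  maps
}
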