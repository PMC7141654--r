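#' Run the full reconstruction pipeline on a synthetic phantom
#'
#' Chains every stage: phantom truth, forward transceiver phase, the
#' stabilized conductivity inversion, DWI synthesis, per-voxel compartment
#' fitting, the concentration/conductivity decomposition, and the tensor
#' stage. Intended both as the end-to-end verification path and as the
#' engine behind the command-line `pipeline` subcommand.
#'
#' @param spec a [phantom_spec] (default: the three-region brain slab).
#' @param protocol a [dwi_protocol] (default: one b = 0 plus the 15
#'   reference b-values in 3 orthogonal directions).
#' @param config configuration list from [default_config]/[read_config].
#' @param model compartment model to fit.
#' @param seed overrides the spec's noise seed when given.
#' @return list with `truth`, `phase`, `sigma_h`, `series`, `maps`,
#'   `c_e`, `sigma_l`, `d_b`, `eta`, `d_ext`, `c_l`.
#' @export
run_pipeline <- function(spec = default_phantom_spec(),
                         protocol = phantom_protocol(),
                         config = default_config(),
                         model = c("mbd", "threepool"),
                         seed = NULL) {
  model <- match.arg(model)
  log_stage("pipeline", list(model = model, snr = spec$snr,
                             seed = if (is.null(seed)) spec$seed else seed))
  truth <- build_phantom(spec)
  mcfg <- mrept_config(omega = 2 * pi * config$omega_hz, mu0 = config$mu0,
                       c = config$c_diffusion)
  phase <- forward_transceiver_phase(truth$sigma_h_true, truth$grid, mcfg)
  sigma_h <- solve_sigma_h(phase, mcfg)
  series <- synthesize_dwi(truth, protocol, snr = spec$snr, seed = seed)
  fixed <- fixed_diffusivities(config$d_ic, config$d_iso)
  maps <- fit_compartment_maps(series, model = model, fixed = fixed)
  c_e <- estimate_ion_concentration(sigma_h, maps, beta = config$beta)
  sigma_l <- compute_sigma_l(sigma_h, maps, beta = config$beta)
  d_b <- fit_diffusion_tensor(series, b_target = config$tensor_b_value)
  eta <- compute_eta(maps$d_w_e, d_b)
  d_ext <- extracellular_tensor(d_b, eta)
  c_l <- conductivity_tensor(maps$alpha, c_e, d_ext)
  list(truth = truth, phase = phase, sigma_h = sigma_h, series = series,
       maps = maps, c_e = c_e, sigma_l = sigma_l, d_b = d_b, eta = eta,
       d_ext = d_ext, c_l = c_l)
}

#' Protocol sub-sampling stability experiment
#'
#' Refits the compartment model(s) with a reduced set of b-values and
#' reports the relative L2 error of alpha, d_w^e, d_w^i and sigma_L
#' against the full-protocol reconstruction (the reference), per model.
#' Mirrors the comparison of full and sub-sampled acquisitions used to
#' argue the constrained model's stability over the three-pool baseline.
#'
#' @param series a [dwi_series] (the full acquisition).
#' @param sigma_h a `conductivity_map` on the same grid.
#' @param b_subset b-values of the reduced protocol (default: the 7-value
#'   subset 300, 500, 700, 1000, 1400, 1800, 3600).
#' @param models character vector of models to compare.
#' @param beta ion-concentration ratio for sigma_L.
#' @param mask optional logical array restricting the fitted voxels.
#' @param fixed,opts fitting configuration.
#' @return data.frame with columns `model`, `quantity`, `rel_l2`,
#'   plus attribute `maps` holding the per-model reconstructions.
#' @export
subsampling_experiment <- function(series, sigma_h,
                                   b_subset = c(300, 500, 700, 1000, 1400,
                                                1800, 3600),
                                   models = c("mbd", "threepool"),
                                   beta = 0.41, mask = NULL,
                                   fixed = fixed_diffusivities(),
                                   opts = fit_options()) {
  out <- list(); store <- list()
  for (model in models) {
    full <- fit_compartment_maps(series, model = model, mask = mask,
                                 fixed = fixed, opts = opts)
    sub <- fit_compartment_maps(series, model = model, mask = mask,
                                b_subset = b_subset, fixed = fixed,
                                opts = opts)
    sl_full <- compute_sigma_l(sigma_h, full, beta)$sigma_l
    sl_sub <- compute_sigma_l(sigma_h, sub, beta)$sigma_l
    q <- list(alpha = list(full$alpha, sub$alpha),
              d_w_e = list(full$d_w_e, sub$d_w_e),
              d_w_i = list(full$d_w_i, sub$d_w_i),
              sigma_l = list(sl_full, sl_sub))
    for (nm in names(q))
      out[[length(out) + 1L]] <- data.frame(
        model = model, quantity = nm,
        rel_l2 = relative_l2(q[[nm]][[1]], q[[nm]][[2]]))
    store[[model]] <- list(full = full, sub = sub)
  }
  res <- do.call(rbind, out)
  attr(res, "maps") <- store
  res
}
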