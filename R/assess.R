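# High-level driver: run any of the seven estimators on a group of
# subjects under one run configuration, and standardize the results onto
# the shared sliding-window time grid.

#' Run a dFC estimation method on a group of subjects
#'
#' Dispatches to the chosen estimator with the hyperparameters of `config`.
#' State-free methods (SW, TF) are applied per subject; state-based methods
#' (CAP, SWC, CHMM, DHMM, WL) are fit once at the group level and applied
#' to every subject. All randomness derives from `config$seed`.
#'
#' @param ts_list List of preprocessed (z-standardized) [parcellated_ts()].
#' @param method One of [DFC_METHODS].
#' @param config A [run_config()].
#' @return List with `dfc` (list of [dfc_matrix()], one per subject) and,
#'   for state-based methods, `fit` (the `dfc_fit`).
#' @export
assess_dfc <- function(ts_list, method, config = run_config()) {
  if (!method %in% DFC_METHODS) {
    stop_fmt("unknown method name '%s'. Valid methods: %s", method,
             paste(DFC_METHODS, collapse = ", "))
  }
  window <- make_tapered_window(config_window_tr(config),
                                config$taper_sigma_tr, config$step_tr)
  seed <- config$seed
  switch(
    method,
    SW = list(dfc = lapply(ts_list, sliding_window_dfc, window = window)),
    TF = list(dfc = lapply(ts_list, wavelet_coherence_dfc,
                           n_scales = config$n_scales,
                           coi_mask = config$coi_mask)),
    CAP = {
      fit <- cap_fit(ts_list, K = config$n_states,
                     k_subject = config$n_subject_clusters, seed = seed)
      list(dfc = fit$dfc, fit = fit)
    },
    SWC = {
      fit <- swc_fit(ts_list, K = config$n_states,
                     k_subject = config$n_subject_clusters,
                     window = window, seed = seed)
      list(dfc = fit$dfc, fit = fit)
    },
    CHMM = {
      fit <- chmm_fit(ts_list, K = config$n_states, seed = seed)
      list(dfc = fit$dfc, fit = fit)
    },
    DHMM = {
      fit <- dhmm_fit(ts_list, K = config$n_states,
                      obs_to_state_ratio = config$obs_to_state_ratio,
                      k_subject = config$n_subject_clusters,
                      window = window, seed = seed)
      list(dfc = fit$dfc, fit = fit)
    },
    WL = {
      fit <- wl_fit(ts_list, K = config$n_states, seed = seed)
      list(dfc = fit$dfc, fit = fit)
    })
}

#' Run several methods and assemble the standardized dFC array
#'
#' Runs each requested method via [assess_dfc()], downsamples per-TR
#' results onto the sliding-window grid with [temporal_downsample()], and
#' assembles everything into one [dfc_array()] (shape S x M x 38 x R x R
#' for the default grid on 1200 TRs).
#'
#' @inheritParams assess_dfc
#' @param methods Character vector of method ids (default: all in
#'   `config$methods`).
#' @return A [dfc_array()] with the producing `config` embedded.
#' @export
assess_all_dfc <- function(ts_list, config = run_config(),
                           methods = config$methods) {
  window <- make_tapered_window(config_window_tr(config),
                                config$taper_sigma_tr, config$step_tr)
  grid <- sliding_window_grid(nrow(ts_list[[1]]$values), window)
  out <- list()
  for (m in methods) {
    res <- assess_dfc(ts_list, m, config)
    for (d in res$dfc) {
      if (length(d$time_stamps) != length(grid) ||
          !isTRUE(all.equal(d$time_stamps, grid, tolerance = 1e-9))) {
        d <- temporal_downsample(d, grid)
      }
      out[[length(out) + 1L]] <- d
    }
  }
  assemble_dfc_array(out, config = config)
}
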