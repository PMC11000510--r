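# Run configuration: method list, per-method hyperparameters, TR, seed.
# Every output artifact embeds the configuration that produced it.

#' Build a run configuration
#'
#' Collects the hyperparameters of all seven dFC methods with their default
#' values: a tapered sliding window of 44 s nominal length (60 TRs at
#' TR = 0.72 s) smoothed by a Gaussian of sigma = 3 TRs, a step of 30 TRs
#' (50% overlap), 101 wavelet scales with cone-of-influence masking, 12 FC
#' states for all state-based methods, 20 subject-level clusters for the
#' two-stage k-means, and an observation-to-state ratio of 16/24 for the
#' discrete HMM.
#'
#' @param methods Character vector of method ids (subset of [DFC_METHODS]).
#' @param window_len_s Nominal sliding-window length in seconds (44).
#' @param step_tr Window step in TRs (30).
#' @param taper_sigma_tr Gaussian taper sigma in TRs (3).
#' @param n_scales Number of wavelet scales (101).
#' @param coi_mask Mask wavelet-coherence values inside the cone of
#'   influence (TRUE).
#' @param n_states Number of FC states K for state-based methods (12).
#' @param n_subject_clusters Subject-level k-means clusters (20).
#' @param obs_to_state_ratio Discrete-HMM observations-per-state ratio
#'   (16/24); the number of observation symbols is
#'   `round(n_states * obs_to_state_ratio)`.
#' @param tr_seconds Repetition time in seconds (0.72).
#' @param seed Integer seed recorded in every output artifact.
#' @return A list of class `run_config`.
#' @export
run_config <- function(methods = DFC_METHODS,
                       window_len_s = 44,
                       step_tr = 30,
                       taper_sigma_tr = 3,
                       n_scales = 101,
                       coi_mask = TRUE,
                       n_states = 12,
                       n_subject_clusters = 20,
                       obs_to_state_ratio = 16 / 24,
                       tr_seconds = 0.72,
                       seed = 1L) {
  unknown <- setdiff(methods, DFC_METHODS)
  if (length(unknown)) {
    stop_fmt("unknown method name(s): %s. Valid methods: %s",
             paste(unknown, collapse = ", "),
             paste(DFC_METHODS, collapse = ", "))
  }
  for (nm in c("step_tr", "n_scales", "n_states", "n_subject_clusters")) {
    if (!is_count(get(nm))) stop_fmt("%s must be a positive integer", nm)
  }
  if (!(obs_to_state_ratio > 0)) stop_fmt("obs_to_state_ratio must be positive")
  if (!(window_len_s > 0) || !(tr_seconds > 0)) {
    stop_fmt("window_len_s and tr_seconds must be positive")
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_fmt("seed must be a single integer")
  }
  structure(
    list(methods = methods, window_len_s = window_len_s, step_tr = step_tr,
         taper_sigma_tr = taper_sigma_tr, n_scales = n_scales,
         coi_mask = isTRUE(coi_mask), n_states = n_states,
         n_subject_clusters = n_subject_clusters,
         obs_to_state_ratio = obs_to_state_ratio, tr_seconds = tr_seconds,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# Window length in TRs implied by the configuration (44 s / 0.72 s ~ 60).
config_window_tr <- function(config) {
  max(2L, as.integer(round(config$window_len_s / config$tr_seconds)))
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(run_config)))
  do.call(run_config, vals[keep])
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
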