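# On-disk container for dFC arrays: a single serialized (RDS) file holding
# the 5-way value array, all label axes, and the run configuration that
# produced it. Roundtrips are bit-lossless.

CONTAINER_FORMAT <- "multidfc-dfc-array"
CONTAINER_VERSION <- 1L

#' Write a dFC array container
#'
#' Stores the array values, its label axes (subject ids, method names, time
#' stamps, ROI and RSN labels), and the producing [run_config()] (including
#' the seed) in a single RDS file. [read_dfc_array()] reproduces the array
#' bit-identically.
#'
#' @param arr A [dfc_array()].
#' @param path Output file path.
#' @param config Optional [run_config()] overriding the one embedded in
#'   `arr`.
#' @export
write_dfc_array <- function(arr, path, config = NULL) {
  stopifnot(inherits(arr, "dfc_array"))
  payload <- list(format = CONTAINER_FORMAT, version = CONTAINER_VERSION,
                  values = arr$values, subject_ids = arr$subject_ids,
                  method_ids = arr$method_ids, time_stamps = arr$time_stamps,
                  roi_labels = arr$roi_labels, rsn_labels = arr$rsn_labels,
                  config = config %||% arr$config)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a dFC array container
#'
#' @param path Path written by [write_dfc_array()]. A corrupted or foreign
#'   file raises a container error rather than returning partial data.
#' @return The [dfc_array()] (symmetry revalidated on load).
#' @export
read_dfc_array <- function(path) {
  if (!file.exists(path)) stop_fmt("container not found: %s", path)
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop_fmt("container error: cannot read %s (%s)", path, conditionMessage(e))
  })
  if (!is.list(payload) || !identical(payload$format, CONTAINER_FORMAT)) {
    stop_fmt("container error: %s is not a dFC array container", path)
  }
  need <- c("values", "subject_ids", "method_ids", "time_stamps",
            "roi_labels", "rsn_labels")
  miss <- need[!vapply(need, function(nm) !is.null(payload[[nm]]), logical(1))]
  if (length(miss)) {
    stop_fmt("container error: missing dataset(s) %s", paste(miss, collapse = ", "))
  }
  dfc_array(payload$values, payload$subject_ids, payload$method_ids,
            payload$time_stamps, payload$roi_labels, payload$rsn_labels,
            config = payload$config)
}
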