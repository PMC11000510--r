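# Atlas table: ROI identifiers, resting-state network membership, hemisphere.
# The atlas row order defines the column order of every time-series matrix.

#' Construct and validate an atlas table
#'
#' An atlas table describes the parcellation: one row per ROI with a unique
#' identifier, a resting-state network (RSN) label (the sentinel `"None"`
#' marks ROIs that belong to no network and are dropped by
#' [exclude_unassigned_rois()]), and a hemisphere code (`"L"` or `"R"`).
#' The row order defines the ROI (column) order of all time-series matrices;
#' data files are never silently reordered to match.
#'
#' @param roi_id Character vector of unique ROI identifiers.
#' @param rsn_label Character vector of RSN names, `"None"` for unassigned.
#' @param hemisphere Character vector, each `"L"` or `"R"`.
#' @return A `data.frame` of class `atlas_table`.
#' @export
atlas_table <- function(roi_id, rsn_label, hemisphere) {
  roi_id <- as.character(roi_id)
  rsn_label <- as.character(rsn_label)
  hemisphere <- as.character(hemisphere)
  n <- length(roi_id)
  if (length(rsn_label) != n || length(hemisphere) != n) {
    stop_fmt("atlas columns must have equal length")
  }
  if (n < 1) stop_fmt("atlas must contain at least one ROI")
  if (anyDuplicated(roi_id)) {
    dup <- unique(roi_id[duplicated(roi_id)])
    stop_fmt("duplicate roi_id in atlas: %s", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(rsn_label)) || anyNA(rsn_label)) {
    stop_fmt("every atlas row needs a nonempty rsn_label (use \"None\" for unassigned ROIs)")
  }
  bad <- setdiff(unique(hemisphere), c("L", "R"))
  if (length(bad)) {
    stop_fmt("unknown hemisphere token(s): %s (expected L or R)",
             paste(bad, collapse = ", "))
  }
  out <- data.frame(roi_id = roi_id, rsn_label = rsn_label,
                    hemisphere = hemisphere, stringsAsFactors = FALSE)
  class(out) <- c("atlas_table", "data.frame")
  out
}

#' Read an atlas table from a delimited text file
#'
#' Expects a header line with columns `roi_id`, `rsn_label`, `hemisphere`
#' (tab- or comma-separated, chosen by file extension: `.csv` means comma).
#'
#' @param path Path to the atlas file.
#' @return An [atlas_table()].
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop_fmt("atlas file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("roi_id", "rsn_label", "hemisphere")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_fmt("atlas file missing column(s): %s", paste(missing, collapse = ", "))
  }
  atlas_table(df$roi_id, df$rsn_label, df$hemisphere)
}

#' Write an atlas table to a TSV file
#'
#' @param atlas An [atlas_table()].
#' @param path Output path.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas_table"))
  utils::write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
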