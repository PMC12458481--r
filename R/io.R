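#' Write / read a session recording as plain-text files
#'
#' Datasets are laid out one file per matrix: `raw_f.csv` and
#' `neuropil_f.csv` (ROI x frame, no headers), `frame_times.csv`, and
#' `cell_type.csv`. Suite2p-style paired trace matrices saved this way can be
#' read back directly.
#'
#' @param rec a `session_recording`.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_session_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(rec$raw_f, file.path(dir, "raw_f.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(rec$neuropil_f, file.path(dir, "neuropil_f.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(frame_time_s = rec$frame_times),
                   file.path(dir, "frame_times.csv"), row.names = FALSE)
  utils::write.csv(data.frame(roi = seq_along(rec$cell_type),
                              cell_type = rec$cell_type),
                   file.path(dir, "cell_type.csv"), row.names = FALSE)
  invisible(file.path(dir, c("raw_f.csv", "neuropil_f.csv",
                             "frame_times.csv", "cell_type.csv")))
}

#' @rdname write_session_recording
#' @export
read_session_recording <- function(dir) {
  raw_f <- as.matrix(utils::read.table(file.path(dir, "raw_f.csv"), sep = ","))
  neuropil_f <- as.matrix(utils::read.table(file.path(dir, "neuropil_f.csv"),
                                            sep = ","))
  ft <- utils::read.csv(file.path(dir, "frame_times.csv"))$frame_time_s
  ct <- utils::read.csv(file.path(dir, "cell_type.csv"))$cell_type
  dimnames(raw_f) <- dimnames(neuropil_f) <- NULL
  structure(list(frame_rate = 1 / stats::median(diff(ft)), frame_times = ft,
                 raw_f = raw_f, neuropil_f = neuropil_f,
                 cell_type = as.character(ct)),
            class = "session_recording")
}

#' Write planted ground truth as JSON
#'
#' The per-ROI archetype, realized context gain, planted divergence window
#' and context-carrier ROIs (the acceptance oracle), without the bulky
#' noiseless signal matrix.
#'
#' @param truth a `ground_truth`.
#' @param path output .json path.
#' @export
write_ground_truth <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_ground_truth needs the jsonlite package")
  keep <- truth[c("cluster_id", "context_gain", "divergence_window",
                  "context_rois", "context_signs", "amplitude")]
  jsonlite::write_json(keep, path, auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}
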