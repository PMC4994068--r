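#' Spike-train and detection CSV interchange
#'
#' Spike trains are stored as `unit,time_s,amplitude`; detections and
#' trajectories as `frame,x_cm,y_cm[,fly_id]`.
#'
#' @param path File path.
#' @return The corresponding tibble.
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("unit", "time_s", "amplitude") %in% names(df)))
  tibble::as_tibble(df[c("unit", "time_s", "amplitude")])
}

#' @rdname read_spikes_csv
#' @param train A spike-train tibble.
#' @export
write_spikes_csv <- function(train, path) {
  utils::write.csv(train[c("unit", "time_s", "amplitude")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname read_spikes_csv
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame", "x_cm", "y_cm") %in% names(df)))
  keep <- intersect(c("frame", "x_cm", "y_cm", "fly_id"), names(df))
  tibble::as_tibble(df[keep])
}

#' @rdname read_spikes_csv
#' @param detections A detection or trajectory tibble.
#' @export
write_detections_csv <- function(detections, path) {
  keep <- intersect(c("fly_id", "frame", "x_cm", "y_cm"), names(detections))
  utils::write.csv(detections[keep], path, row.names = FALSE)
  invisible(path)
}
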