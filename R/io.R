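#' Export / import a recording with hypnogram and events
#'
#' Writes `signals.edf` (EDF, one channel per role, 16-bit), the
#' hypnogram as `hypnogram.csv` (columns `epoch_index`, `zt_seconds`,
#' `state`) and the event table as `events.csv` (columns `onset_s`,
#' `duration_s`, `type`, `channel`, plus any extra attributes).
#' `import_recording()` reverses the export; labels round-trip exactly and
#' signals to within one EDF quantization step.
#'
#' @param rec a `psg_recording`.
#' @param hyp a [hypnogram()].
#' @param events event data frame (may be empty or `NULL`).
#' @param dir output directory (created if missing).
#' @param require_roles channel roles that must be present on import.
#' @return `export_recording` returns `dir` invisibly; `import_recording`
#'   returns a list with `recording`, `hypnogram`, `events`.
#' @export
export_recording <- function(rec, hyp, events, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edf(rec, file.path(dir, "signals.edf"))
  write_hypnogram_csv(hyp, file.path(dir, "hypnogram.csv"))
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                         type = character(0), channel = character(0))
  }
  utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname export_recording
#' @export
import_recording <- function(dir, require_roles = c("EEG", "EMG")) {
  edf <- file.path(dir, "signals.edf")
  if (!file.exists(edf)) stop("no signals.edf in ", dir)
  rec <- read_edf(edf)
  missing <- setdiff(require_roles, rec$roles)
  if (length(missing))
    stop("required channel role(s) absent from EDF: ",
         paste(missing, collapse = ", "))
  hyp <- read_hypnogram_csv(file.path(dir, "hypnogram.csv"))
  ev_path <- file.path(dir, "events.csv")
  events <- if (file.exists(ev_path))
    utils::read.csv(ev_path, stringsAsFactors = FALSE) else NULL
  list(recording = rec, hypnogram = hyp, events = events)
}
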