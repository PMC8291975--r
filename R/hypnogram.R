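#' Construct a hypnogram
#'
#' A hypnogram is the epoch-by-epoch vigilance-state sequence of a
#' polysomnographic recording, scored in fixed-length epochs (4 s by
#' convention in mouse work). Valid states are `Wake`, `NREMS`, `REMS` and
#' `MA` (microarousal).
#'
#' @param states character vector of epoch labels.
#' @param epoch_s epoch length in seconds (default 4).
#' @param zt0 Zeitgeber-time offset in seconds of the first epoch
#'   (ZT0 = lights on).
#' @return a data frame of class `hypnogram` with columns `epoch`
#'   (1-based index), `zt_s` (epoch start, seconds) and `state`.
#' @export
hypnogram <- function(states, epoch_s = 4, zt0 = 0) {
  states <- as.character(states)
  bad <- setdiff(unique(states), c("Wake", "NREMS", "REMS", "MA"))
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  h <- data.frame(
    epoch = seq_along(states),
    zt_s = zt0 + (seq_along(states) - 1) * epoch_s,
    state = states,
    stringsAsFactors = FALSE
  )
  attr(h, "epoch_s") <- epoch_s
  attr(h, "zt0") <- zt0
  class(h) <- c("hypnogram", "data.frame")
  h
}

#' @export
print.hypnogram <- function(x, ...) {
  es <- attr(x, "epoch_s")
  cat("<hypnogram> ", nrow(x), " epochs of ", es, " s (",
      nrow(x) * es, " s total)\n", sep = "")
  tab <- table(factor(x$state, levels = c("Wake", "NREMS", "REMS", "MA")))
  print(tab)
  invisible(x)
}

epoch_s_of <- function(hyp) attr(hyp, "epoch_s") %||% 4

hyp_duration_s <- function(hyp) nrow(hyp) * epoch_s_of(hyp)

# Per-sample state labels at an arbitrary sampling rate.
state_at_samples <- function(hyp, fs, n) {
  es <- epoch_s_of(hyp)
  idx <- pmin(nrow(hyp), floor((seq_len(n) - 1) / (fs * es)) + 1L)
  hyp$state[idx]
}

# Epoch index containing time t (seconds from recording start).
epoch_of_time <- function(hyp, t) {
  pmin(nrow(hyp), pmax(1L, floor(t / epoch_s_of(hyp)) + 1L))
}

#' Maximal same-state runs (bouts) of a hypnogram
#'
#' @param hyp a [hypnogram()].
#' @param merge_ma if `TRUE`, `MA` epochs are merged into surrounding
#'   NREMS for bout delineation (microarousals do not terminate a NREMS
#'   bout); if `FALSE`, bouts are literal label runs.
#' @return data frame with `state`, `start_epoch`, `n_epochs`,
#'   `start_s`, `duration_s`.
#' @export
hyp_bouts <- function(hyp, merge_ma = FALSE) {
  es <- epoch_s_of(hyp)
  st <- hyp$state
  if (merge_ma) st[st == "MA"] <- "NREMS"
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    state = r$values,
    start_epoch = starts,
    n_epochs = r$lengths,
    start_s = (starts - 1L) * es,
    duration_s = r$lengths * es,
    stringsAsFactors = FALSE
  )
}

#' Write / read a hypnogram as CSV
#'
#' Columns are `epoch_index`, `zt_seconds`, `state`.
#'
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @return `read_hypnogram_csv` returns a [hypnogram()].
#' @export
write_hypnogram_csv <- function(hyp, path) {
  utils::write.csv(
    data.frame(epoch_index = hyp$epoch, zt_seconds = hyp$zt_s,
               state = hyp$state),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "zt_seconds", "state")
  if (!all(need %in% names(d))) stop("hypnogram CSV must have columns ",
                                     paste(need, collapse = ", "))
  es <- if (nrow(d) > 1) d$zt_seconds[2] - d$zt_seconds[1] else 4
  hypnogram(d$state, epoch_s = es, zt0 = d$zt_seconds[1])
}
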