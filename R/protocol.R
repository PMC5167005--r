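# Stimulus protocol generation and I/O.

#' Generate a pseudo-randomised stimulus protocol
#'
#' Produces the study protocol: after an initial rest baseline, the three
#' conditions are presented in a pseudo-random order with the constraint that
#' no more than two consecutive events share a condition. Each condition
#' occurs exactly `n_per_condition` times; every event lasts `stim_s` seconds
#' and is followed by an interstimulus interval of `isi_s` seconds. With the
#' defaults (15 events/condition, 5 s stimuli, 15 s ISI, 300 s baseline) the
#' session lasts 1200 s (20 min).
#'
#' The order is drawn by bounded rejection sampling; the draw is fully
#' determined by `seed`.
#'
#' @param n_per_condition Events per condition (default 15).
#' @param stim_s Stimulus duration in seconds (default 5).
#' @param isi_s Interstimulus interval in seconds (default 15).
#' @param baseline_s Initial rest period in seconds (default 300).
#' @param seed Integer seed.
#' @param conditions Condition labels (default `PAPain`, `PA30`, `Brush`).
#' @param max_attempts Resampling bound before giving up.
#' @return A `stim_protocol`: data frame with columns `condition`, `onset_s`,
#'   `duration_s` and attributes `baseline_s`, `isi_s`, `total_s`.
#' @examples
#' p <- generate_protocol(seed = 7)
#' attr(p, "total_s")       # 1200
#' table(p$condition)       # 15 each
#' @export
generate_protocol <- function(n_per_condition = 15, stim_s = 5, isi_s = 15,
                              baseline_s = 300, seed = 1,
                              conditions = CONDITIONS, max_attempts = 1000) {
  stopifnot(n_per_condition >= 1, stim_s > 0, isi_s >= 0, baseline_s >= 0)
  pool <- rep(conditions, each = n_per_condition)
  seq_cond <- with_seed(seed, {
    cand <- NULL
    for (attempt in seq_len(max_attempts)) {
      draw <- sample(pool)
      if (max_run_length(draw) <= 2) { cand <- draw; break }
    }
    if (is.null(cand))
      stop(sprintf(
        "could not satisfy the run-length constraint after %d attempts",
        max_attempts))
    cand
  })
  n_events <- length(seq_cond)
  onsets <- baseline_s + (seq_len(n_events) - 1) * (stim_s + isi_s)
  events <- data.frame(condition = seq_cond, onset_s = onsets,
                       duration_s = stim_s)
  structure(events,
            baseline_s = baseline_s, isi_s = isi_s,
            total_s = baseline_s + n_events * (stim_s + isi_s),
            conditions = conditions,
            class = c("stim_protocol", "data.frame"))
}

#' Longest run of identical consecutive values
#' @keywords internal
#' @noRd
max_run_length <- function(x) max(rle(as.character(x))$lengths)

#' Write / read a stimulus protocol as TSV
#'
#' Columns `condition`, `onset_s`, `duration_s`; baseline and ISI structure
#' are recovered from the event grid on read.
#' @param protocol A `stim_protocol`.
#' @param path File path.
#' @export
write_protocol <- function(protocol, path) {
  utils::write.table(as.data.frame(protocol), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  ev <- utils::read.delim(path)
  stopifnot(all(c("condition", "onset_s", "duration_s") %in% names(ev)))
  isi <- if (nrow(ev) > 1) diff(ev$onset_s)[1] - ev$duration_s[1] else 15
  structure(ev,
            baseline_s = ev$onset_s[1], isi_s = isi,
            total_s = ev$onset_s[nrow(ev)] + ev$duration_s[nrow(ev)] + isi,
            conditions = ordered_conditions(ev$condition),
            class = c("stim_protocol", "data.frame"))
}
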