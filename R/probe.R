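# Probe geometry and channel bookkeeping.

#' Build the default measurement probe
#'
#' Constructs the study probe: 8 sources and 8 detectors forming 18
#' multidistance channels over two regions of interest. Channels 1-6 cover the
#' bilateral supplementary motor area (SMA), channels 7-18 the bilateral
#' primary somatosensory cortex (S1). Channels 2 and 10 are short-separation
#' channels (~11 mm source-detector distance) sensitive mainly to the scalp;
#' all other channels have separations between 25 and 45 mm. The
#' short-separation regression map pairs every long channel with the short
#' channel of its ROI: channels 1, 3-6 with channel 2, and channels 7-9, 11-18
#' with channel 10.
#'
#' Individual long-channel separations are configuration, not measurement:
#' no downstream computation depends on their exact values (the pathlength
#' factor depends on wavelength and age only; the separation enters the
#' Beer-Lambert conversion per channel).
#'
#' @return A `probe_layout`: list with `optodes` (data frame: `id`, `kind`,
#'   `position_1020`), `channels` (data frame: `id`, `source_id`,
#'   `detector_id`, `separation_mm`, `roi`, `is_short`) and `ssr_map`
#'   (named integer vector, long channel id -> short channel id).
#' @examples
#' probe <- build_default_probe()
#' nrow(probe$channels)          # 18
#' probe$ssr_map[["5"]]          # 2
#' probe$ssr_map[["17"]]         # 10
#' @export
build_default_probe <- function() {
  optodes <- rbind(
    data.frame(id = 1:8, kind = "source", position_1020 = NA_character_),
    data.frame(id = 1:8, kind = "detector", position_1020 = NA_character_)
  )
  channels <- data.frame(
    id = 1:18,
    source_id   = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 5, 6, 6, 6, 7, 7, 8, 8),
    detector_id = c(1, 2, 1, 2, 2, 3, 4, 5, 4, 5, 6, 5, 6, 7, 6, 7, 7, 8),
    separation_mm = c(30, 11, 35, 30, 40, 30,
                      30, 35, 28, 11, 32, 38, 30, 45, 27, 33, 25, 42),
    roi = c(rep("SMA", 6), rep("S1", 12)),
    is_short = seq_len(18) %in% c(2L, 10L)
  )
  ssr_map <- c(
    stats::setNames(rep(2L, 5), c(1, 3, 4, 5, 6)),
    stats::setNames(rep(10L, 11), c(7, 8, 9, 11:18))
  )
  structure(list(optodes = optodes, channels = channels, ssr_map = ssr_map),
            class = "probe_layout")
}

#' Validate a probe layout
#'
#' Checks every structural invariant of a probe layout and returns the
#' violations as data, not errors: an empty character vector means the layout
#' is valid.
#'
#' Invariants checked: exactly 18 channels with unique ids; unique optode ids
#' within kind; short flags exactly on channels 2 and 10; short separations
#' ~11 mm, long separations within 25-45 mm; the SSR map keys are exactly the
#' long channels, each mapping to the short channel of its own ROI.
#'
#' @param layout A `probe_layout`.
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_probe <- function(layout) {
  v <- character(0)
  ch <- layout$channels
  if (nrow(ch) != 18)
    v <- c(v, sprintf("channel count != 18 (got %d)", nrow(ch)))
  if (anyDuplicated(ch$id))
    v <- c(v, "duplicate channel ids")
  for (k in c("source", "detector")) {
    ids <- layout$optodes$id[layout$optodes$kind == k]
    if (anyDuplicated(ids)) v <- c(v, sprintf("duplicate %s ids", k))
  }
  expected_short <- ch$id %in% c(2L, 10L)
  bad_flag <- ch$id[xor(ch$is_short, expected_short)]
  for (id in bad_flag)
    v <- c(v, sprintf("channel %d: is_short flag inconsistent with ids {2, 10}", id))
  for (i in seq_len(nrow(ch))) {
    s <- ch$separation_mm[i]
    if (s < 10 || s > 46)
      v <- c(v, sprintf("channel %d: separation %.1f mm outside [10, 46]", ch$id[i], s))
    if (ch$is_short[i] && abs(s - 11) > 1.5)
      v <- c(v, sprintf("channel %d: short-channel separation %.1f mm not ~11 mm", ch$id[i], s))
    if (!ch$is_short[i] && (s < 25 || s > 45))
      v <- c(v, sprintf("channel %d: long-channel separation %.1f mm outside [25, 45]", ch$id[i], s))
  }
  short_ids <- ch$id[ch$is_short]
  long_ids <- ch$id[!ch$is_short]
  keys <- as.integer(names(layout$ssr_map))
  targets <- as.integer(layout$ssr_map)
  for (k in keys[keys %in% short_ids])
    v <- c(v, sprintf("ssr_map: short channel %d used as a key", k))
  for (tg in unique(targets[!targets %in% short_ids]))
    v <- c(v, sprintf("ssr_map: short channel used as SSR target is not short (channel %d)", tg))
  missing_keys <- setdiff(long_ids, keys)
  for (k in missing_keys)
    v <- c(v, sprintf("ssr_map: long channel %d has no short-channel assignment", k))
  if (anyDuplicated(keys))
    v <- c(v, "ssr_map: duplicated keys")
  # ROI consistency: each long channel must regress against its own ROI's short channel
  roi_of <- stats::setNames(ch$roi, ch$id)
  for (i in seq_along(keys)) {
    k <- keys[i]; tg <- targets[i]
    if (k %in% ch$id && tg %in% ch$id && !is.na(roi_of[as.character(k)]) &&
        roi_of[as.character(k)] != roi_of[as.character(tg)])
      v <- c(v, sprintf("ssr_map: channel %d mapped to short channel %d of a different ROI", k, tg))
  }
  v
}

#' Long-channel ids of a layout
#' @param layout A `probe_layout`.
#' @return Integer vector of non-short channel ids.
#' @export
long_channels <- function(layout) {
  layout$channels$id[!layout$channels$is_short]
}

#' Write / read a probe layout as a YAML config file
#'
#' The on-disk form is human-editable; `read_probe()` validates on read and
#' errors if any invariant is violated.
#'
#' @param layout A `probe_layout`.
#' @param path File path.
#' @return `read_probe()` returns a validated `probe_layout`.
#' @export
write_probe <- function(layout, path) {
  obj <- list(
    optodes = layout$optodes,
    channels = layout$channels,
    ssr_map = as.list(stats::setNames(as.integer(layout$ssr_map),
                                      names(layout$ssr_map)))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_probe
#' @export
read_probe <- function(path) {
  obj <- yaml::read_yaml(path)
  layout <- structure(list(
    optodes = as.data.frame(obj$optodes),
    channels = as.data.frame(obj$channels),
    ssr_map = unlist(obj$ssr_map)
  ), class = "probe_layout")
  viol <- validate_probe(layout)
  if (length(viol) > 0)
    stop("invalid probe layout in ", path, ":\n  ", paste(viol, collapse = "\n  "))
  layout
}
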