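# Study-level orchestration: simulate cohorts, run the full analysis,
# read/write the on-disk study layout.

#' Simulate one subject end to end
#'
#' Derives per-subject seeds from the subject seed, draws the subject's
#' pseudo-randomised protocol, the optical-density recording and the 1 Hz
#' heart-rate series.
#'
#' @param subject_seed Integer seed for this subject.
#' @param layout A `probe_layout`.
#' @param params A `sim_params` (its `seed` field is replaced).
#' @param protocol Optional fixed protocol; by default each subject gets an
#'   independently randomised stimulus order.
#' @return List with `protocol`, `od`, `truth`, `hr`, `age_years`, `seed`.
#' @export
simulate_subject <- function(subject_seed, layout = build_default_probe(),
                             params = default_sim_params(),
                             protocol = NULL) {
  seeds <- derive_seeds(subject_seed, 3)
  if (is.null(protocol)) protocol <- generate_protocol(seed = seeds[1])
  params$seed <- seeds[2]
  rec <- simulate_recording(layout, protocol, params)
  hr <- simulate_heart_rate(protocol, params, seed = seeds[3])
  list(protocol = protocol, od = rec$od, truth = rec$truth, hr = hr,
       age_years = params$subject_age_years, seed = subject_seed)
}

#' Tidy per-subject response-scalar table
#'
#' Flattens a block-average scalar array into the long format consumed by
#' [run_group_analysis()].
#'
#' @param scalars Array `[channel, condition, chromophore]` from
#'   [block_average()].
#' @param layout A `probe_layout`.
#' @param subject Subject label.
#' @param long_only Keep only long (non-short) channels (default TRUE).
#' @return Data frame: `subject`, `channel`, `condition`, `chromophore`,
#'   `scalar`.
#' @export
study_scalar_table <- function(scalars, layout, subject, long_only = TRUE) {
  d <- dim(scalars)
  df <- expand.grid(channel = layout$channels$id,
                    condition = dimnames(scalars)[[2]],
                    chromophore = dimnames(scalars)[[3]],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$scalar <- as.numeric(scalars)
  if (long_only) df <- df[df$channel %in% long_channels(layout), ]
  cbind(subject = subject, df)
}

#' Simulate and analyse a full cohort in memory
#'
#' The package's main entry point for simulation studies: simulates
#' `n_subjects` recordings, preprocesses each through the full signal chain,
#' and runs the group statistics (both tracks), the habituation screen and
#' the heart-rate comparison.
#'
#' @param n_subjects Cohort size (default 20, the study's sample size).
#' @param seed Study seed; per-subject seeds are derived from it.
#' @param params A `sim_params` shared by all subjects.
#' @param layout A `probe_layout`.
#' @param tracks Analysis tracks to run (default both).
#' @param keep_subjects Keep per-subject tensors/traces in the result
#'   (memory-heavy; default keeps traces only).
#' @return List with `scalars`, `responders`, `group` (per track),
#'   `habituation`, `trend_summary`, `hr`, `grand_avg_scalars`,
#'   `traces_by_subject`, `layout`, `seed`.
#' @export
run_study <- function(n_subjects = 20, seed = 1,
                      params = default_sim_params(),
                      layout = build_default_probe(),
                      tracks = c("All", "Responders"),
                      keep_subjects = FALSE) {
  subject_seeds <- derive_seeds(seed, n_subjects)
  scalars <- responders <- habituation <- hr_summaries <- list()
  traces <- vector("list", n_subjects)
  subjects <- vector("list", if (keep_subjects) n_subjects else 0)
  for (s in seq_len(n_subjects)) {
    id <- sprintf("S%02d", s)
    subj <- simulate_subject(subject_seeds[s], layout, params)
    tensor <- preprocess_subject(subj$od, layout, subj$protocol,
                                 age_years = subj$age_years)
    ba <- block_average(tensor)
    traces[[s]] <- ba$traces
    scalars[[s]] <- study_scalar_table(ba$scalars, layout, id)
    rs <- classify_responders(tensor, layout)
    responders[[s]] <- cbind(subject = id, rs)
    habituation[[s]] <- habituation_screen(tensor, layout, subject = id)
    hw <- extract_hr_windows(subj$hr, subj$protocol)
    hr_summaries[[s]] <- aggregate_hr(hw, subject = id)
    if (keep_subjects) subjects[[s]] <- list(subject = subj, tensor = tensor)
  }
  scalars <- do.call(rbind, scalars)
  responders <- do.call(rbind, responders)
  habituation <- do.call(rbind, habituation)
  hr_summaries <- do.call(rbind, hr_summaries)

  group <- lapply(tracks, function(tr)
    run_group_analysis(scalars, responders, track = tr, layout = layout))
  names(group) <- tracks

  ga_scalars <- grand_scalars(scalars)

  list(scalars = scalars, responders = responders, group = group,
       habituation = habituation,
       trend_summary = summarize_trends(habituation),
       hr_summaries = hr_summaries,
       hr = if (n_subjects >= 5) compare_hr(hr_summaries) else NULL,
       grand_avg_scalars = ga_scalars,
       traces_by_subject = traces,
       subjects = if (keep_subjects) subjects else NULL,
       layout = layout, seed = seed, n_subjects = n_subjects)
}

#' Grand-average response scalars
#'
#' Median across subjects of the per-subject response scalars, per channel,
#' condition and chromophore.
#'
#' @param scalars Tidy scalar table (stacked [study_scalar_table()] rows).
#' @return Data frame: `channel`, `condition`, `chromophore`,
#'   `grand_median`, `n`.
#' @export
grand_scalars <- function(scalars) {
  agg <- stats::aggregate(scalar ~ channel + condition + chromophore,
                          data = scalars, FUN = stats::median)
  names(agg)[names(agg) == "scalar"] <- "grand_median"
  cnt <- stats::aggregate(scalar ~ channel + condition + chromophore,
                          data = scalars, FUN = length)
  agg$n <- cnt$scalar
  agg
}

#' Write a simulated study to disk
#'
#' One directory per subject containing the optical-density recording
#' (`recording.tsv`: `time_s`, then `ch{n}_{wavelength}` columns), the
#' protocol (`protocol.tsv`), the heart-rate series (`heartrate.tsv`) and
#' the parameters (`params.yaml`); plus a study-level `manifest.json`
#' recording the seed, cohort size, parameter echo and package version.
#' Reruns with the same seed produce identical files.
#'
#' @param dir Output directory (created if missing).
#' @param n_subjects Cohort size.
#' @param seed Study seed.
#' @param params A `sim_params`.
#' @param layout A `probe_layout` (also written, as `probe.yaml`).
#' @return The manifest, invisibly.
#' @export
simulate_study <- function(dir, n_subjects = 20, seed = 1,
                           params = default_sim_params(),
                           layout = build_default_probe()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subject_seeds <- derive_seeds(seed, max(n_subjects, 1))
  write_probe(layout, file.path(dir, "probe.yaml"))
  for (s in seq_len(n_subjects)) {
    id <- sprintf("S%02d", s)
    sd <- file.path(dir, id)
    dir.create(sd, showWarnings = FALSE)
    subj <- simulate_subject(subject_seeds[s], layout, params)
    write_recording(subj$od, layout, file.path(sd, "recording.tsv"))
    write_protocol(subj$protocol, file.path(sd, "protocol.tsv"))
    utils::write.table(subj$hr, file.path(sd, "heartrate.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(subject = id, seed = subject_seeds[s],
                          age_years = subj$age_years),
                     file.path(sd, "params.yaml"))
  }
  manifest <- list(package = "nirspine",
                   version = as.character(utils::packageVersion("nirspine")),
                   seed = seed, n_subjects = n_subjects,
                   params = params_echo(params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

params_echo <- function(params) {
  lapply(unclass(params), function(x) {
    if (is.matrix(x)) as.data.frame(x) else x
  })
}

#' Write / read a two-wavelength recording as TSV
#'
#' Columns: `time_s`, then `ch{n}_{wavelength}` OD values for every channel
#' and wavelength.
#' @param od A `channel_ts` of kind `"optical_density"`.
#' @param layout A `probe_layout`.
#' @param path File path.
#' @export
write_recording <- function(od, layout, path) {
  d <- dim(od$values)
  cols <- list(time_s = round((seq_len(d[2]) - 1) / od$fs, 4))
  for (i in seq_len(d[1])) for (w in seq_len(d[3])) {
    nm <- sprintf("ch%d_%s", layout$channels$id[i], dimnames(od$values)[[3]][w])
    cols[[nm]] <- od$values[i, , w]
  }
  utils::write.table(as.data.frame(cols), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param fs Sampling rate of the stored recording.
#' @export
read_recording <- function(path, layout, fs = FS_DEFAULT) {
  df <- utils::read.delim(path)
  nch <- nrow(layout$channels)
  ns <- nrow(df)
  vals <- array(NA_real_, c(nch, ns, 2),
                dimnames = list(NULL, NULL, as.character(WAVELENGTHS_NM)))
  for (i in seq_len(nch)) for (w in 1:2) {
    nm <- sprintf("ch%d_%d", layout$channels$id[i], WAVELENGTHS_NM[w])
    if (!nm %in% names(df)) stop("missing column ", nm, " in ", path)
    vals[i, , w] <- df[[nm]]
  }
  channel_ts(vals, fs = fs, kind = "optical_density")
}

#' Analyse an on-disk study
#'
#' Reads every subject directory written by [simulate_study()], runs the
#' full pipeline and writes the report bundle as TSV files (group statistics
#' per track, responder table, habituation screen, heart-rate comparison,
#' grand-average scalars) plus an analysis manifest.
#'
#' @param study_dir Directory produced by [simulate_study()].
#' @param out_dir Output directory for the reports.
#' @param q_threshold FDR threshold.
#' @return Invisibly, the in-memory result bundle.
#' @export
analyze_study <- function(study_dir, out_dir, q_threshold = 0.05) {
  layout <- read_probe(file.path(study_dir, "probe.yaml"))
  subj_dirs <- sort(list.dirs(study_dir, recursive = FALSE))
  missing <- character(0)
  for (sd in subj_dirs)
    for (f in c("recording.tsv", "protocol.tsv", "heartrate.tsv"))
      if (!file.exists(file.path(sd, f)))
        missing <- c(missing, file.path(sd, f))
  if (length(missing) > 0)
    stop("missing inputs:\n  ", paste(missing, collapse = "\n  "))
  scalars <- responders <- habituation <- hr_summaries <- list()
  for (sd in subj_dirs) {
    id <- basename(sd)
    pmeta <- yaml::read_yaml(file.path(sd, "params.yaml"))
    protocol <- read_protocol(file.path(sd, "protocol.tsv"))
    od <- read_recording(file.path(sd, "recording.tsv"), layout)
    hr <- utils::read.delim(file.path(sd, "heartrate.tsv"))
    tensor <- preprocess_subject(od, layout, protocol,
                                 age_years = pmeta$age_years %||% 33.5)
    ba <- block_average(tensor)
    scalars[[id]] <- study_scalar_table(ba$scalars, layout, id)
    responders[[id]] <- cbind(subject = id,
                              classify_responders(tensor, layout))
    habituation[[id]] <- habituation_screen(tensor, layout, subject = id)
    hr_summaries[[id]] <- aggregate_hr(extract_hr_windows(hr, protocol),
                                       subject = id)
  }
  scalars <- do.call(rbind, scalars)
  responders <- do.call(rbind, responders)
  habituation <- do.call(rbind, habituation)
  hr_summaries <- do.call(rbind, hr_summaries)
  group <- lapply(c("All", "Responders"), function(tr)
    run_group_analysis(scalars, responders, track = tr, layout = layout,
                       q_threshold = q_threshold))
  names(group) <- c("All", "Responders")
  hr_cmp <- if (length(subj_dirs) >= 5) compare_hr(hr_summaries) else NULL

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  for (tr in names(group)) {
    wt(group[[tr]]$friedman, sprintf("friedman_%s.tsv", tolower(tr)))
    wt(group[[tr]]$vs_zero, sprintf("vs_zero_%s.tsv", tolower(tr)))
    wt(group[[tr]]$posthoc, sprintf("posthoc_%s.tsv", tolower(tr)))
  }
  wt(responders, "responders.tsv")
  wt(habituation, "habituation.tsv")
  wt(hr_summaries, "heartrate_summaries.tsv")
  wt(hr_group_table(hr_summaries), "heartrate_group.tsv")
  if (!is.null(hr_cmp)) wt(hr_cmp$wilcoxon, "heartrate_wilcoxon.tsv")
  wt(grand_scalars(scalars), "grand_scalars.tsv")
  jsonlite::write_json(
    list(package = "nirspine",
         version = as.character(utils::packageVersion("nirspine")),
         study_dir = study_dir, n_subjects = length(subj_dirs),
         q_threshold = q_threshold),
    file.path(out_dir, "analysis_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(list(scalars = scalars, responders = responders, group = group,
                 habituation = habituation, hr_summaries = hr_summaries,
                 hr = hr_cmp))
}
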