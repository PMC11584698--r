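# Plain-text persistence: recordings as TSV with a JSON sidecar, event and
# cardiac-event tables as TSV, ground truth and reports as JSON.

#' Write a session to a directory
#'
#' Writes `recording.tsv` (one column per channel), `recording.json`
#' (sampling rate, channel names), `events.tsv` (onset_s, side, task) and,
#' when present, `truth.json` with the generator's ground truth.
#'
#' @param session list with `recording`, `cues` and optionally `truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- session$recording
  stopifnot(inherits(rec, "physio_recording"))
  write.table(rec$data, file.path(dir, "recording.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sampling_rate = rec$fs, channels = rec$channels),
                       file.path(dir, "recording.json"), auto_unbox = TRUE)
  write.table(session$cues, file.path(dir, "events.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(session$truth))
    jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory.
#' @return list with `recording`, `cues` and (if stored) `truth`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  data <- as.matrix(read.table(file.path(dir, "recording.tsv"), sep = "\t",
                               header = TRUE, check.names = FALSE))
  colnames(data) <- meta$channels
  cues <- read.table(file.path(dir, "events.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  list(recording = physio_recording(data, meta$sampling_rate), cues = cues,
       truth = truth)
}

#' Write detected cardiac events as TSV
#'
#' @param events a `cardiac_events` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cardiac_events <- function(events, path) {
  df <- data.frame(r_time_s = events$r_times,
                   t_offset_s = c(events$t_offsets, NA))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a timewise test result as TSV
#'
#' Columns: time_s, stat, p, significant.
#'
#' @param test a `timewise_test`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timewise_tsv <- function(test, path) {
  df <- data.frame(time_s = test$times, stat = test$observed, p = test$p,
                   significant = test$significant)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# strip heavyweight members down to a JSON-friendly summary
.summarize_timewise <- function(tw) {
  list(n_significant = sum(tw$significant), p_star = tw$p_star,
       p_range = if (any(tw$significant))
         range(tw$p[tw$significant]) else NULL,
       sig_range_s = .sig_range(tw), delta_dep = tw$delta_dep,
       n_perm = tw$n_perm, q = tw$q, n_subjects = tw$n_subjects)
}

#' Write a pipeline report bundle
#'
#' Writes `report.json` (every statistic, window and seed) plus one TSV per
#' timewise contrast.
#'
#' @param report a `phase_report` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "phase_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(
    config = unclass(report$config), n_subjects = report$n_subjects,
    version = report$version,
    ecg = list(left_vs_right = .summarize_timewise(report$ecg$left_vs_right),
               mean_ibis = report$ecg$mean_ibis),
    emg = if (!is.null(report$emg)) lapply(report$emg, .summarize_timewise),
    neural = lapply(report$neural, function(rk)
      lapply(rk, .summarize_timewise)),
    control = report$control,
    circular = lapply(report$circular, function(rk) lapply(rk, function(x)
      list(window = x$window, window_fallback = x$window_fallback,
           percentile = x$percentile, rbar = x$group$group$rbar,
           Z = x$group$group$Z, p = x$group$group$p,
           mean_direction_rad = x$group$group$mean_direction,
           monte_carlo_p = x$monte_carlo_p, n_selected = x$n_selected))),
    overlap = report$overlap)
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (key in names(report$neural))
    for (ss in names(report$neural[[key]]))
      write_timewise_tsv(report$neural[[key]][[ss]],
                         file.path(dir, sprintf("neural_%s_%s.tsv", key, ss)))
  if (!is.null(report$emg))
    for (nm in names(report$emg))
      write_timewise_tsv(report$emg[[nm]],
                         file.path(dir, sprintf("emg_%s.tsv", nm)))
  invisible(dir)
}
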