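#' Run the full analysis pipeline
#'
#' Wires every stage together: load (or simulate) raw events, reconstruct
#' sessions, mask by phase, compute measures, and write a deterministic
#' report bundle — sessions TSV, per-mouse measures TSV, sociability pair
#' CSV plus histogram data, QC exclusion list, and a JSON run manifest
#' recording parameters and seeds so a rerun reproduces identical files.
#'
#' @param data Either a directory/file vector of raw logs, or an event
#'   tibble.
#' @param out_dir Output directory (created if needed).
#' @param top An `ecohab_topology`.
#' @param phases Optional phase tibble from [read_phase_config()].
#' @param analysis_phase Phase name (or an interval) used for occupancy,
#'   activity and sociability; defaults to the full session span.
#' @param threshold Sessionizer threshold in seconds.
#' @param stim_phase,baseline_phase,social_comp,nonsocial_comp Optional
#'   odor-approach configuration: phase names (or intervals) for the
#'   stimulus bin and baseline bin and the two stimulus compartments;
#'   approach scores and QC exclusions are produced when all are given.
#' @param dialect Raw-file [eh_dialect()].
#' @param mask_mode Masking mode for duration-bearing measures; `"clip"`
#'   (default) or `"start_based"`, the original field scripts' behavior.
#' @return Invisibly, a list with the computed tables and the paths
#'   written.
#' @export
run_pipeline <- function(data, out_dir, top = standard_topology(),
                         phases = NULL, analysis_phase = NULL, threshold = 2,
                         stim_phase = NULL, baseline_phase = NULL,
                         social_comp = NULL, nonsocial_comp = NULL,
                         dialect = eh_dialect(),
                         mask_mode = c("clip", "start_based")) {
  mask_mode <- match.arg(mask_mode)
  events <- if (is.data.frame(data)) data else read_events(data, dialect)
  if (nrow(events) == 0L) abort("pipeline: no events loaded.")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  sessions <- reconstruct_sessions(events, top, threshold)
  if (nrow(sessions) == 0L) abort("pipeline: no sessions reconstructed.")

  resolve <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) {
      if (is.null(phases)) {
        abort(sprintf("pipeline: %s names a phase but no phase config given.",
                      what))
      }
      phase_interval(phases, x)
    } else {
      eh_as_interval(x)
    }
  }
  iv <- resolve(analysis_phase, "analysis_phase")
  if (is.null(iv)) iv <- eh_interval(min(sessions$start), max(sessions$end))

  masked <- mask_sessions(sessions, iv, mode = mask_mode)
  occ <- occupancy(sessions, iv)
  act <- activity(sessions, iv)
  measures <- dplyr::left_join(
    act,
    tidyr::pivot_wider(occ, id_cols = "mouse", names_from = "compartment",
                       values_from = "time_frac", names_prefix = "occ_c"),
    by = "mouse"
  )

  soc <- NULL
  if (length(unique(sessions$mouse)) >= 2L) {
    soc <- sociability_matrix(sessions, iv)
  }
  appr <- qc <- NULL
  stim_iv <- resolve(stim_phase, "stim_phase")
  base_iv <- resolve(baseline_phase, "baseline_phase")
  if (!is.null(stim_iv) && !is.null(base_iv) && !is.null(social_comp) &&
      !is.null(nonsocial_comp)) {
    appr <- approach_to_social_odor(sessions, stim_iv, base_iv,
                                    social_comp, nonsocial_comp)
    qc <- qc_exclusions(sessions, iv, stim_iv,
                        c(social_comp, nonsocial_comp))
  }

  ts_fmt <- function(d) {
    s <- eh_format_timestamp(d$start, dialect)
    e <- eh_format_timestamp(d$end, dialect)
    dplyr::mutate(d, start = paste(s$date, s$time), end = paste(e$date, e$time))
  }
  paths <- list(sessions = file.path(out_dir, "sessions.tsv"),
                measures = file.path(out_dir, "measures.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  readr::write_tsv(ts_fmt(masked), paths$sessions)
  readr::write_tsv(measures, paths$measures)
  if (!is.null(soc)) {
    paths$sociability <- file.path(out_dir, "sociability_pairs.csv")
    readr::write_csv(tidy(soc), paths$sociability)
    paths$histogram <- file.path(out_dir, "sociability_scores.csv")
    readr::write_csv(tibble::tibble(sociability = tidy(soc)$sociability),
                     paths$histogram)
  }
  if (!is.null(appr)) {
    paths$approach <- file.path(out_dir, "approach.tsv")
    readr::write_tsv(appr, paths$approach)
  }
  if (!is.null(qc)) {
    paths$qc <- file.path(out_dir, "qc_exclusions.tsv")
    readr::write_tsv(qc, paths$qc)
  }
  manifest <- list(
    package = "ecohab",
    version = as.character(utils::packageVersion("ecohab")),
    threshold = threshold, mask_mode = mask_mode,
    interval = format(iv, "%Y-%m-%d %H:%M:%OS3", tz = "UTC"),
    n_events = nrow(events), n_sessions = nrow(sessions),
    n_mice = length(unique(sessions$mouse)),
    outputs = purrr::map_chr(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(events = events, sessions = sessions, occupancy = occ,
                 activity = act, sociability = soc, approach = appr,
                 qc = qc, paths = paths))
}

#' Export sessions as TSV
#'
#' Writes a session tibble with timestamps rendered in the raw-file
#' dialect, columns `mouse`, `compartment`, `start`, `end`, `duration_s`,
#' `consecutive`.
#'
#' @param sessions A session tibble.
#' @param path Output file.
#' @inheritParams parse_raw_events
#' @return Invisibly, `path`.
#' @export
write_sessions <- function(sessions, path, dialect = eh_dialect()) {
  s <- eh_format_timestamp(sessions$start, dialect)
  e <- eh_format_timestamp(sessions$end, dialect)
  readr::write_tsv(tibble::tibble(
    mouse = sessions$mouse, compartment = sessions$compartment,
    start = paste(s$date, s$time), end = paste(e$date, e$time),
    duration_s = round(as.numeric(sessions$end) - as.numeric(sessions$start), 3),
    consecutive = sessions$consecutive
  ), path)
  invisible(path)
}
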