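# Per-patient, time-ordered pathogenic VAF tables: the backing data for
# longitudinal dashboards of progression, remission and recurrence.

#' Order a patient's samples into draw indices
#'
#' When every member sample carries a draw date, draws are ordered by date
#' (ties broken by sample id); otherwise — the reports are anonymous and a
#' date may simply not exist — samples are ordered lexicographically by id,
#' with a warning if only some members were dated. Indices run 1..n.
#'
#' @param member_sample_ids Character vector of one patient's sample ids.
#' @param draw_dates Named character vector (or `NULL`) mapping sample id to
#'   ISO draw date.
#' @return Tibble `sample_id`, `draw_date`, `draw_index`.
#' @export
order_draws <- function(member_sample_ids, draw_dates = NULL) {
  ids <- unique(member_sample_ids)
  dates <- if (is.null(draw_dates)) {
    rep(NA_character_, length(ids))
  } else {
    as.character(draw_dates[ids])
  }
  if (all(!is.na(dates)) && length(ids) > 0L) {
    ord <- order(as.Date(dates), ids)
  } else {
    if (any(!is.na(dates)) && any(is.na(dates))) {
      warning("mixed dated/undated samples; ordering draws by sample id",
              call. = FALSE)
    }
    ord <- order(ids)
  }
  tibble::tibble(
    sample_id = ids[ord],
    draw_date = dates[ord],
    draw_index = seq_along(ids)
  )
}

#' Assemble the longitudinal pathogenic-VAF timeline
#'
#' For each patient, each pathogenic mutation is tracked across that
#' patient's draws. The default view keeps PATHOGENIC-tier, non-germline
#' series, with sub-1% (low-AF-flagged) detections excluded from series
#' selection; a series enters the view if any draw passes these filters.
#' Within a selected series, a draw where the mutation was not detected gets
#' an explicit `allele_frequency = 0` row — so remission and recurrence are
#' visible in the long-format table rather than appearing as missing rows.
#' The complete unfiltered annotation table, with patient and draw columns
#' attached, is returned alongside.
#'
#' @param groups Tibble `patient_id`, `sample_id` from [match_patients()].
#'   Samples not present (e.g. excluded from matching) are skipped.
#' @param annotated_reports Named list of `annotated_report` objects.
#' @param include_germline Keep germline-flagged series (default `FALSE`).
#' @param apply_low_af_filter Drop series whose detections are all below the
#'   low-AF threshold (default `TRUE`).
#' @return List with `timeline` (default filtered view; tibble `patient_id`,
#'   `sample_id`, `draw_index`, `draw_date`, `gene`, `aa_change`,
#'   `allele_frequency`, `tier`, `fathmm_score`, `germline_flag`,
#'   `low_af_flag`) and `full` (every annotated row with patient/draw
#'   columns).
#' @export
build_timeline <- function(groups, annotated_reports,
                           include_germline = FALSE,
                           apply_low_af_filter = TRUE) {
  draw_dates <- vapply(annotated_reports, function(a) {
    if (is.null(a$draw_date)) NA_character_ else as.character(a$draw_date)
  }, character(1))
  names(draw_dates) <- vapply(annotated_reports, `[[`, character(1),
                              "sample_id")

  per_patient <- lapply(split(groups$sample_id, groups$patient_id),
                        function(ids) {
    order_draws(intersect(ids, names(annotated_reports)), draw_dates)
  })

  full <- dplyr::bind_rows(lapply(names(per_patient), function(pid) {
    draws <- per_patient[[pid]]
    dplyr::bind_rows(lapply(seq_len(nrow(draws)), function(i) {
      v <- annotated_reports[[draws$sample_id[i]]]$variants
      dplyr::mutate(v, patient_id = pid,
                    draw_index = draws$draw_index[i],
                    draw_date = draws$draw_date[i],
                    .before = 1L)
    }))
  }))
  if (nrow(full) == 0L) {
    empty <- tibble::tibble(
      patient_id = character(0), sample_id = character(0),
      draw_index = integer(0), draw_date = character(0),
      gene = character(0), aa_change = character(0),
      allele_frequency = numeric(0), tier = character(0),
      fathmm_score = numeric(0), germline_flag = logical(0),
      low_af_flag = logical(0)
    )
    return(list(timeline = empty, full = empty))
  }

  # Which (patient, gene, aa_change) pathogenic series enter the default view.
  eligible <- full$tier == "PATHOGENIC"
  if (!include_germline) eligible <- eligible & !full$germline_flag
  if (apply_low_af_filter) eligible <- eligible & !full$low_af_flag
  series <- dplyr::distinct(
    full[eligible, c("patient_id", "gene", "aa_change")]
  )

  # One row per (series x draw of that patient); undetected draws get AF 0.
  scaffold <- dplyr::bind_rows(lapply(names(per_patient), function(pid) {
    s <- series[series$patient_id == pid, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    tidyr::crossing(s, per_patient[[pid]])
  }))
  if (nrow(scaffold) == 0L) {
    timeline <- full[0, c("patient_id", "sample_id", "draw_index", "draw_date",
                          "gene", "aa_change", "allele_frequency", "tier",
                          "fathmm_score", "germline_flag", "low_af_flag")]
  } else {
    observed <- full[, c("patient_id", "sample_id", "gene", "aa_change",
                         "allele_frequency", "tier", "fathmm_score",
                         "germline_flag", "low_af_flag")]
    timeline <- dplyr::left_join(
      scaffold, observed,
      by = c("patient_id", "sample_id", "gene", "aa_change")
    )
    timeline$allele_frequency[is.na(timeline$allele_frequency)] <- 0
    timeline <- dplyr::arrange(
      timeline[, c("patient_id", "sample_id", "draw_index", "draw_date",
                   "gene", "aa_change", "allele_frequency", "tier",
                   "fathmm_score", "germline_flag", "low_af_flag")],
      .data$patient_id, .data$gene, .data$aa_change, .data$draw_index
    )
  }

  full <- dplyr::arrange(
    full[, c("patient_id", "sample_id", "draw_index", "draw_date", "gene",
             "aa_change", "aa_change_raw", "nt_change", "allele_frequency",
             "depth", "matched", "classification", "fathmm_score", "tier",
             "germline_flag", "low_af_flag")],
    .data$patient_id, .data$draw_index, .data$gene, .data$aa_change
  )
  list(timeline = timeline, full = full)
}

#' Write all pipeline outputs to a directory
#'
#' Emits the backing tables a dashboard (or a reviewer) consumes, one CSV
#' each: `annotated.csv`, `qc.csv`, `pairs.csv` (similarity scores rounded
#' to 4 decimals), `ambiguous.csv`, `groups.csv`, `timeline.csv`,
#' `timeline_full.csv`. Output is byte-identical across reruns on identical
#' input and configuration.
#'
#' @param results A list as returned by [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
export_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)

  annotated <- dplyr::bind_rows(lapply(results$annotated,
                                       function(a) a$variants))
  qc <- dplyr::bind_rows(lapply(results$annotated, function(a) a$qc))
  pairs <- dplyr::mutate(results$pairs, score = round(.data$score, 4))
  ambiguous <- dplyr::mutate(results$ambiguous, score = round(.data$score, 4))

  files <- c(
    annotated = "annotated.csv", qc = "qc.csv", pairs = "pairs.csv",
    ambiguous = "ambiguous.csv", groups = "groups.csv",
    timeline = "timeline.csv", timeline_full = "timeline_full.csv"
  )
  tables <- list(annotated, qc, pairs, ambiguous, results$groups,
                 results$timeline, results$timeline_full)
  paths <- file.path(dir, files)
  for (i in seq_along(paths)) {
    readr::write_csv(tables[[i]], paths[i], progress = FALSE)
  }
  invisible(stats::setNames(paths, names(files)))
}

#' Run the whole pipeline on a cohort
#'
#' Annotation ([annotate_cohort()]), patient matching ([match_patients()])
#' and timeline assembly ([build_timeline()]) in one call. The result is a
#' pure function of the inputs and configurations; sample input order does
#' not affect it (patient ids are canonicalized by smallest member id).
#'
#' @param cohort An `lb_cohort` from [load_cohort()].
#' @param reference An `lb_reference` from [load_reference()].
#' @param annotate_cfg An [annotate_config()].
#' @param match_cfg A [match_config()].
#' @param include_germline,apply_low_af_filter Passed to [build_timeline()].
#' @return List with `annotated`, `qc`, `groups`, `pairs`, `ambiguous`,
#'   `timeline`, `timeline_full`.
#' @export
run_pipeline <- function(cohort, reference,
                         annotate_cfg = annotate_config(),
                         match_cfg = match_config(),
                         include_germline = FALSE,
                         apply_low_af_filter = TRUE) {
  annotated <- annotate_cohort(cohort, reference, annotate_cfg)
  matching <- match_patients(annotated, match_cfg)
  tl <- build_timeline(matching$groups, annotated,
                       include_germline = include_germline,
                       apply_low_af_filter = apply_low_af_filter)
  list(
    annotated = annotated,
    qc = dplyr::bind_rows(lapply(annotated, function(a) a$qc)),
    groups = matching$groups,
    pairs = matching$pairs,
    ambiguous = matching$ambiguous,
    timeline = tl$timeline,
    timeline_full = tl$full
  )
}
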