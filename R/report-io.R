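# Reading and normalizing per-sample variant report tables (TSV/CSV exports
# from the upstream amplicon-panel workflow) into canonical records.

#' Default column mapping for variant report tables
#'
#' Canonical fields and the header names they resolve to in the input file.
#' `gene` and `aa` are the upstream export's "GENE" and "AA" columns; the
#' allele-frequency column name varies between exports and is configurable.
#' `nt` and `depth` are optional.
#'
#' @param gene,aa,af,nt,depth Actual header names in the input file.
#' @return Named list usable as the `column_map` argument of [parse_report()].
#' @export
report_column_map <- function(gene = "GENE", aa = "AA", af = "AF",
                              nt = "NT", depth = "DEPTH") {
  list(gene = gene, aa = aa, af = af, nt = nt, depth = depth)
}

#' Parse one variant report into canonical records
#'
#' Reads a TSV or CSV variant report (header row required; TSV assumed unless
#' the file ends in `.csv`), normalizes the protein-change column via
#' [normalize_aa_change()], puts allele frequencies on the percent scale, and
#' deduplicates repeated calls of the same variant. Rows whose protein change
#' cannot be parsed are retained with `aa_change = ""` (they still carry AF
#' signal) but are excluded downstream from reference joining and from
#' similarity vectors. Rows with a non-numeric allele frequency are dropped
#' with a warning naming the row.
#'
#' Duplicate calls of the same `(gene, aa_change)` within one report (amplicon
#' panels may call a variant once per amplicon) are collapsed to the row with
#' the highest read depth, or the first occurrence when depth is absent.
#'
#' @param path Path to the report file.
#' @param sample_id Sample label; defaults to the file name without extension.
#' @param column_map Mapping from canonical to actual column names, from
#'   [report_column_map()].
#' @param af_scale Either `"percent"` (default; values already in 0–100) or
#'   `"fraction"` (values in 0–1, multiplied by 100 on read).
#' @param draw_date Optional ISO date string for the blood draw.
#' @return A `sample_report`: a list with `sample_id`, `draw_date`,
#'   `source_path` and `records`, a tibble with columns `sample_id`, `gene`,
#'   `aa_change_raw`, `aa_change`, `nt_change`, `allele_frequency`, `depth`.
#' @export
parse_report <- function(path, sample_id = NULL,
                         column_map = report_column_map(),
                         af_scale = c("percent", "fraction"),
                         draw_date = NA_character_) {
  af_scale <- match.arg(af_scale)
  if (!file.exists(path)) {
    stop("report file not found: ", path, call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }

  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)

  for (field in c("gene", "aa", "af")) {
    if (!column_map[[field]] %in% names(raw)) {
      stop("required column ", sQuote(column_map[[field]]),
           " (", field, ") missing from ", path, call. = FALSE)
    }
  }
  if (nrow(raw) == 0L) {
    stop("empty report: ", path, call. = FALSE)
  }

  af_chr <- raw[[column_map$af]]
  af <- suppressWarnings(as.numeric(af_chr))
  bad_af <- is.na(af) & !is.na(af_chr)
  if (any(bad_af)) {
    warning(sum(bad_af), " row(s) with non-numeric allele frequency dropped in ",
            basename(path), call. = FALSE)
  }
  if (af_scale == "fraction") af <- af * 100

  depth <- if (column_map$depth %in% names(raw)) {
    suppressWarnings(as.integer(raw[[column_map$depth]]))
  } else {
    rep(NA_integer_, nrow(raw))
  }
  nt <- if (column_map$nt %in% names(raw)) {
    as.character(raw[[column_map$nt]])
  } else {
    rep(NA_character_, nrow(raw))
  }

  records <- tibble::tibble(
    sample_id = sample_id,
    gene = toupper(trimws(raw[[column_map$gene]])),
    aa_change_raw = as.character(raw[[column_map$aa]]),
    aa_change = normalize_aa_change(raw[[column_map$aa]]),
    nt_change = nt,
    allele_frequency = af,
    depth = depth
  )
  records <- records[!bad_af & !is.na(records$allele_frequency), , drop = FALSE]
  if (any(records$allele_frequency < 0 | records$allele_frequency > 100)) {
    stop("allele frequency outside [0, 100] in ", path,
         " (wrong af_scale?)", call. = FALSE)
  }
  records <- dedupe_records(records)

  structure(
    list(sample_id = sample_id, draw_date = draw_date,
         source_path = path, records = records),
    class = "sample_report"
  )
}

# Keep the highest-depth row per (gene, aa_change); first occurrence when
# depth is missing. Rows with empty aa_change are deduplicated on the raw
# string so distinct unparseable entries survive.
dedupe_records <- function(records) {
  key <- ifelse(records$aa_change == "",
                paste(records$gene, records$aa_change_raw, sep = "\r"),
                paste(records$gene, records$aa_change, sep = "\r"))
  ord <- order(match(key, unique(key)),
               -replace(records$depth, is.na(records$depth), -1L))
  records <- records[ord, , drop = FALSE]
  records[!duplicated(key[ord]), , drop = FALSE]
}

#' @export
print.sample_report <- function(x, ...) {
  cat("<sample_report> ", x$sample_id, ": ", nrow(x$records), " variant(s)",
      if (!is.na(x$draw_date)) paste0(", drawn ", x$draw_date), "\n", sep = "")
  invisible(x)
}

#' Write a sample report back to TSV in the canonical dialect
#'
#' Emits the columns GENE, AA, NT, AF, DEPTH so that re-parsing with the
#' default [report_column_map()] round-trips the records.
#'
#' @param report A `sample_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- tibble::tibble(
    GENE = report$records$gene,
    AA = ifelse(report$records$aa_change == "",
                report$records$aa_change_raw, report$records$aa_change),
    NT = report$records$nt_change,
    AF = report$records$allele_frequency,
    DEPTH = report$records$depth
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Build an empty cohort store
#'
#' A cohort is a named list of `sample_report` objects keyed by `sample_id`,
#' used to detect duplicate loads of the same sample.
#'
#' @return An empty `lb_cohort`.
#' @export
new_cohort <- function() {
  structure(list(), class = "lb_cohort")
}

#' Is a sample already loaded in the cohort?
#'
#' @param cohort An `lb_cohort`.
#' @param sample_id Sample label to test.
#' @return `TRUE` iff a report with this id is already present.
#' @export
is_duplicate_sample <- function(cohort, sample_id) {
  sample_id %in% names(cohort)
}

#' Add a parsed report to a cohort, skipping duplicates
#'
#' A report whose `sample_id` is already present is skipped with a warning —
#' never silently merged or overwritten.
#'
#' @param cohort An `lb_cohort`.
#' @param report A `sample_report`.
#' @return The updated cohort.
#' @export
add_report <- function(cohort, report) {
  stopifnot(inherits(cohort, "lb_cohort"), inherits(report, "sample_report"))
  if (is_duplicate_sample(cohort, report$sample_id)) {
    warning("sample ", sQuote(report$sample_id),
            " already loaded; duplicate skipped", call. = FALSE)
    return(cohort)
  }
  cohort[[report$sample_id]] <- report
  cohort
}

#' Load a directory of report files into a cohort
#'
#' @param paths Character vector of report file paths, or a single directory
#'   (all `.tsv`/`.csv` files inside are loaded in sorted order).
#' @param metadata Optional tibble/data frame with columns `sample_id` and
#'   `draw_date` attaching draw dates to samples.
#' @param ... Passed to [parse_report()] (`column_map`, `af_scale`).
#' @return An `lb_cohort`.
#' @export
load_cohort <- function(paths, metadata = NULL, ...) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.(tsv|csv)$",
                             full.names = TRUE, ignore.case = TRUE))
  }
  cohort <- new_cohort()
  for (p in paths) {
    rep <- parse_report(p, ...)
    if (!is.null(metadata)) {
      hit <- match(rep$sample_id, metadata$sample_id)
      if (!is.na(hit)) rep$draw_date <- as.character(metadata$draw_date[hit])
    }
    cohort <- add_report(cohort, rep)
  }
  cohort
}
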