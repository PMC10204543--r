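# COSMIC-style reference of known mutations: load, deduplicate, index and
# look up by (gene, one-letter protein change).

#' Load a reference table of known mutations
#'
#' Reads a CSV with columns `gene`, `aa_change`, `classification`
#' (`PATHOGENIC`/`NEUTRAL`, any case) and `fathmm_score` in \[0, 1\], the
#' filtered form of a COSMIC export. Gene symbols are uppercased and protein
#' changes normalized to one-letter form so lookups are case- and
#' nomenclature-insensitive. Rows with a score outside \[0, 1\] or an unknown
#' classification are rejected with a warning. Duplicate `(gene, aa_change)`
#' keys are resolved conservatively for clinical review: keep the entry with
#' the highest FATHMM score, breaking exact ties in favour of `PATHOGENIC`.
#'
#' @param path Path to the reference CSV.
#' @return An `lb_reference`: a tibble of unique entries with an attached
#'   lookup index.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)

  required <- c("gene", "aa_change", "classification", "fathmm_score")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("reference is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_raw <- nrow(raw)

  entries <- tibble::tibble(
    gene = toupper(trimws(raw$gene)),
    aa_change = normalize_aa_change(raw$aa_change),
    classification = toupper(trimws(raw$classification)),
    fathmm_score = suppressWarnings(as.numeric(raw$fathmm_score))
  )

  ok <- !is.na(entries$fathmm_score) &
    entries$fathmm_score >= 0 & entries$fathmm_score <= 1 &
    entries$classification %in% c("PATHOGENIC", "NEUTRAL") &
    entries$gene != "" & entries$aa_change != ""
  if (any(!ok)) {
    warning(sum(!ok), " reference row(s) rejected (bad score, class or key)",
            call. = FALSE)
  }
  entries <- entries[ok, , drop = FALSE]

  # Dedup: highest score wins; PATHOGENIC beats NEUTRAL on an exact score tie.
  entries <- entries[order(entries$gene, entries$aa_change,
                           -entries$fathmm_score,
                           entries$classification != "PATHOGENIC"), ,
                     drop = FALSE]
  key <- reference_key(entries$gene, entries$aa_change)
  entries <- entries[!duplicated(key), , drop = FALSE]

  message("reference: ", nrow(entries), " unique entries kept of ",
          n_raw, " rows")
  structure(entries, class = c("lb_reference", class(entries)))
}

reference_key <- function(gene, aa_change) {
  paste(toupper(gene), aa_change, sep = "\r")
}

#' Look up known mutations by gene and protein change
#'
#' Exact-key match on `(gene, aa_change)` after the same normalization applied
#' at load time. A miss is a row of `NA`s, not an error.
#'
#' @param reference An `lb_reference` from [load_reference()].
#' @param gene Character vector of gene symbols (any case).
#' @param aa_change Character vector of protein changes (one- or three-letter).
#' @return A tibble with one row per query: `matched` (logical),
#'   `classification` and `fathmm_score` (`NA` on miss).
#' @export
ref_lookup <- function(reference, gene, aa_change) {
  stopifnot(inherits(reference, "lb_reference"))
  q <- reference_key(gene, normalize_aa_change(aa_change))
  hit <- match(q, reference_key(reference$gene, reference$aa_change))
  tibble::tibble(
    matched = !is.na(hit),
    classification = reference$classification[hit],
    fathmm_score = reference$fathmm_score[hit]
  )
}

#' Write a reference table to CSV in the loadable dialect
#'
#' @param reference An `lb_reference` or a tibble with the four reference
#'   columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  readr::write_csv(
    tibble::as_tibble(reference)[, c("gene", "aa_change", "classification",
                                     "fathmm_score")],
    path, progress = FALSE
  )
  invisible(path)
}
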