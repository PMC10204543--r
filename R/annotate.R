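# Reference joining, pathogenicity tiering, report-level QC and variant-level
# germline / low-AF flags.

#' Annotation configuration
#'
#' Cutoffs and bands used by [annotate_report()] and friends.
#'
#' @param pathogenic_cutoff Minimum FATHMM score for the PATHOGENIC tier
#'   (default 0.8, inclusive: a score of exactly 0.8 is pathogenic).
#' @param lower_cutoff Matched variants scoring strictly below this go to the
#'   LOWER tier (default 0.5).
#' @param germline_het Numeric length-2 allele-frequency interval (percent)
#'   flagged as heterozygous germline (default `c(40, 60)`, around 50%).
#' @param germline_hom_min Allele frequencies at or above this percent are
#'   flagged as homozygous germline (default 90, around 100%).
#' @param low_af_threshold Allele frequencies strictly below this percent are
#'   flagged low-AF (default 1).
#' @param min_rows Reports with fewer gene + mutation rows than this are
#'   QC-flagged (default 32).
#' @param max_ratio Reports whose mutation-to-gene ratio exceeds this are
#'   QC-flagged (default 0.25).
#' @param ratio_mode How the QC ratio is computed: `"pathogenic_per_gene"`
#'   (default; PATHOGENIC-tier rows per distinct gene in the report) or
#'   `"rows_per_panel_gene"` (total rows per panel gene; see `panel_size`).
#' @param panel_size Number of genes on the panel, used only by the
#'   `"rows_per_panel_gene"` ratio mode (default 56).
#' @return A list of class `annotate_config`.
#' @export
annotate_config <- function(pathogenic_cutoff = 0.8,
                            lower_cutoff = 0.5,
                            germline_het = c(40, 60),
                            germline_hom_min = 90,
                            low_af_threshold = 1,
                            min_rows = 32,
                            max_ratio = 0.25,
                            ratio_mode = c("pathogenic_per_gene",
                                           "rows_per_panel_gene"),
                            panel_size = 56) {
  ratio_mode <- match.arg(ratio_mode)
  if (!(pathogenic_cutoff > lower_cutoff)) {
    stop("pathogenic_cutoff must exceed lower_cutoff", call. = FALSE)
  }
  if (length(germline_het) != 2L || germline_het[1] > germline_het[2]) {
    stop("germline_het must be an ordered interval", call. = FALSE)
  }
  if (low_af_threshold <= 0) stop("low_af_threshold must be > 0", call. = FALSE)
  structure(
    list(pathogenic_cutoff = pathogenic_cutoff, lower_cutoff = lower_cutoff,
         germline_het = germline_het, germline_hom_min = germline_hom_min,
         low_af_threshold = low_af_threshold, min_rows = min_rows,
         max_ratio = max_ratio, ratio_mode = ratio_mode,
         panel_size = panel_size),
    class = "annotate_config"
  )
}

#' Assign the pathogenicity tier of a variant
#'
#' The rule: a variant matched in the reference, classified `PATHOGENIC` and
#' scoring at or above `pathogenic_cutoff` is tier `PATHOGENIC`; a matched
#' variant scoring strictly below `lower_cutoff` is `LOWER` (very low
#' pathogenicity); everything else — including variants absent from the
#' reference, for which there is no evidence either way — is `NEUTRAL`.
#'
#' @param matched Logical vector: found in the reference?
#' @param classification Character vector, `"PATHOGENIC"`/`"NEUTRAL"`/`NA`.
#' @param fathmm_score Numeric vector in \[0, 1\] or `NA`.
#' @param config An [annotate_config()].
#' @return Character vector of tiers: `"PATHOGENIC"`, `"NEUTRAL"` or
#'   `"LOWER"`.
#' @export
assign_tier <- function(matched, classification, fathmm_score,
                        config = annotate_config()) {
  tier <- rep("NEUTRAL", length(matched))
  m <- matched & !is.na(fathmm_score)
  tier[m & fathmm_score < config$lower_cutoff] <- "LOWER"
  tier[m & !is.na(classification) & classification == "PATHOGENIC" &
         fathmm_score >= config$pathogenic_cutoff] <- "PATHOGENIC"
  tier
}

#' Flag germline-range allele frequencies
#'
#' In plasma, an inherited (germline) variant is present in essentially all
#' cell-free DNA, so its allele frequency sits near 50% (heterozygous) or
#' 100% (homozygous). Frequencies inside the heterozygous band or at/above
#' the homozygous bound are flagged.
#'
#' @param allele_frequency Numeric vector, percent.
#' @param config An [annotate_config()].
#' @return Logical vector.
#' @export
flag_germline <- function(allele_frequency, config = annotate_config()) {
  (allele_frequency >= config$germline_het[1] &
     allele_frequency <= config$germline_het[2]) |
    allele_frequency >= config$germline_hom_min
}

#' Flag sub-threshold allele frequencies
#'
#' Strictly below the threshold (default 1%): exactly 1% is not flagged.
#'
#' @param allele_frequency Numeric vector, percent.
#' @param threshold Percent threshold, default 1.
#' @return Logical vector.
#' @export
flag_low_af <- function(allele_frequency, threshold = 1) {
  allele_frequency < threshold
}

#' Report-level quality control
#'
#' Two independent checks on an annotated report: too few gene + mutation
#' rows (`n_rows < min_rows`), and a mutation-to-gene ratio above `max_ratio`.
#' Under the default ratio mode the ratio is the count of PATHOGENIC-tier rows
#' per distinct gene in the report; the alternative mode divides the total
#' row count by the panel size.
#'
#' @param variants Annotated variant tibble (needs `gene` and `tier`).
#' @param sample_id Sample label for the result row.
#' @param config An [annotate_config()].
#' @return One-row tibble: `sample_id`, `n_rows`, `n_distinct_genes`,
#'   `ratio`, `low_row_count_flag`, `high_ratio_flag`.
#' @export
qc_report <- function(variants, sample_id, config = annotate_config()) {
  n_rows <- nrow(variants)
  n_genes <- length(unique(variants$gene))
  ratio <- switch(config$ratio_mode,
    pathogenic_per_gene = if (n_genes == 0L) {
      warning("report has no genes; QC ratio set to 0", call. = FALSE)
      0
    } else {
      sum(variants$tier == "PATHOGENIC") / n_genes
    },
    rows_per_panel_gene = n_rows / config$panel_size
  )
  tibble::tibble(
    sample_id = sample_id,
    n_rows = n_rows,
    n_distinct_genes = n_genes,
    ratio = ratio,
    low_row_count_flag = n_rows < config$min_rows,
    high_ratio_flag = ratio > config$max_ratio
  )
}

#' Annotate a report against the reference
#'
#' Joins every record on `(gene, aa_change)`, assigns tiers via
#' [assign_tier()], sets germline and low-AF flags, and attaches the
#' report-level [qc_report()] result. Record order is preserved; rows with an
#' empty (unparseable) `aa_change` are never matched. Annotation is a pure
#' function of `(report, reference, config)`.
#'
#' @param report A `sample_report` from [parse_report()].
#' @param reference An `lb_reference` from [load_reference()].
#' @param config An [annotate_config()].
#' @return An `annotated_report`: list with `sample_id`, `draw_date`,
#'   `variants` (records plus `matched`, `classification`, `fathmm_score`,
#'   `tier`, `germline_flag`, `low_af_flag`) and `qc`.
#' @export
annotate_report <- function(report, reference, config = annotate_config()) {
  stopifnot(inherits(report, "sample_report"))
  rec <- report$records

  hit <- ref_lookup(reference, rec$gene, rec$aa_change)
  hit$matched[rec$aa_change == ""] <- FALSE
  hit$classification[rec$aa_change == ""] <- NA_character_
  hit$fathmm_score[rec$aa_change == ""] <- NA_real_

  variants <- dplyr::bind_cols(rec, hit)
  variants$tier <- assign_tier(variants$matched, variants$classification,
                               variants$fathmm_score, config)
  variants$germline_flag <- flag_germline(variants$allele_frequency, config)
  variants$low_af_flag <- flag_low_af(variants$allele_frequency,
                                      config$low_af_threshold)

  structure(
    list(sample_id = report$sample_id, draw_date = report$draw_date,
         variants = variants,
         qc = qc_report(variants, report$sample_id, config)),
    class = "annotated_report"
  )
}

#' Annotate every report in a cohort
#'
#' @param cohort An `lb_cohort` from [load_cohort()].
#' @param reference An `lb_reference`.
#' @param config An [annotate_config()].
#' @return Named list of `annotated_report` objects, keyed by sample id.
#' @export
annotate_cohort <- function(cohort, reference, config = annotate_config()) {
  stopifnot(inherits(cohort, "lb_cohort"))
  lapply(cohort, annotate_report, reference = reference, config = config)
}

#' @export
print.annotated_report <- function(x, ...) {
  cat("<annotated_report> ", x$sample_id, ": ", nrow(x$variants), " variant(s), ",
      sum(x$variants$tier == "PATHOGENIC"), " pathogenic\n", sep = "")
  invisible(x)
}
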