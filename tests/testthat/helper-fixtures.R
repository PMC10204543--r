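# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from stored data files.

# Write a TSV report file and return its path.
write_report_file <- function(rows, path = tempfile(fileext = ".tsv"),
                              col_names = c(gene = "GENE", aa = "AA",
                                            af = "AF", depth = "DEPTH")) {
  df <- data.frame(
    GENE = rows$gene,
    AA = rows$aa,
    AF = rows$af,
    stringsAsFactors = FALSE
  )
  if (!is.null(rows$depth)) df$DEPTH <- rows$depth
  names(df) <- col_names[seq_along(df)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Write a reference CSV and load it.
make_reference <- function(gene, aa_change, classification, fathmm_score) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(gene = gene, aa_change = aa_change,
               classification = classification, fathmm_score = fathmm_score,
               stringsAsFactors = FALSE),
    path, row.names = FALSE
  )
  suppressMessages(load_reference(path))
}

empty_reference <- function() {
  make_reference(character(0), character(0), character(0), numeric(0))
}

# Build an annotated_report directly (bypassing file I/O) from parallel
# vectors; tier defaults derived from the given classification/score.
make_annotated <- function(sample_id, gene, aa_change, af,
                           tier = NULL, draw_date = NA_character_) {
  n <- length(gene)
  variants <- tibble::tibble(
    sample_id = sample_id,
    gene = gene,
    aa_change_raw = aa_change,
    aa_change = aa_change,
    nt_change = NA_character_,
    allele_frequency = af,
    depth = NA_integer_,
    matched = !is.null(tier) & (if (is.null(tier)) FALSE else tier != "NEUTRAL"),
    classification = NA_character_,
    fathmm_score = NA_real_,
    tier = if (is.null(tier)) rep("NEUTRAL", n) else tier,
    germline_flag = flag_germline(af),
    low_af_flag = flag_low_af(af)
  )
  structure(
    list(sample_id = sample_id, draw_date = draw_date, variants = variants,
         qc = qc_report(variants, sample_id)),
    class = "annotated_report"
  )
}

# Independent cosine oracle: explicit two-loop dot product and norms over the
# union of keys. Deliberately naive.
cosine_brute_force <- function(v1, v2) {
  keys <- union(names(v1), names(v2))
  dot <- 0; s1 <- 0; s2 <- 0
  for (k in keys) {
    a <- if (k %in% names(v1)) v1[[k]] else 0
    b <- if (k %in% names(v2)) v2[[k]] else 0
    dot <- dot + a * b
    s1 <- s1 + a^2
    s2 <- s2 + b^2
  }
  dot / (sqrt(s1) * sqrt(s2))
}

# Random sparse nonnegative vector over a synthetic key space. Distinct
# prefixes give disjoint key pools, so forcing overlap by renaming never
# creates duplicate keys within one vector.
random_sparse_vector <- function(n_keys = 400, n_nonzero = 15, prefix = "K") {
  keys <- sample(paste0(prefix, seq_len(n_keys)), n_nonzero)
  stats::setNames(stats::runif(n_nonzero, 0.1, 100), keys)
}

# Independent connected-components oracle: repeated breadth-first expansion
# over an edge list.
components_brute_force <- function(ids, edges_a, edges_b) {
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(edges_a)) {
      ca <- comp[[edges_a[i]]]; cb <- comp[[edges_b[i]]]
      if (ca != cb) {
        comp[comp == max(ca, cb)] <- min(ca, cb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

# Adjusted Rand Index between the recovered grouping and the truth labels.
recovery_ari <- function(groups, truth) {
  merged <- merge(as.data.frame(groups), as.data.frame(truth),
                  by = "sample_id")
  mclust::adjustedRandIndex(merged$patient_id.x, merged$patient_id.y)
}

# Count MATCH-band pairs whose members belong to different true patients.
count_cross_patient_matches <- function(pairs, truth) {
  tr <- stats::setNames(truth$patient_id, truth$sample_id)
  m <- pairs[pairs$band == "MATCH", , drop = FALSE]
  as.numeric(sum(tr[m$sample_a] != tr[m$sample_b]))
}
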