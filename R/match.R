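# Patient identity matching for anonymous reports: allele-frequency vectors
# over non-pathogenic variants, k-means pre-clustering, cosine similarity
# banding at 0.98 / [0.95, 0.98), and a rescue pass across clusters.

#' Matching configuration
#'
#' @param k_clusters Number of k-means pre-clusters (default 2). Pre-clustering
#'   only reduces the number of pairwise comparisons; the rescue pass restores
#'   cross-cluster matches.
#' @param match_threshold Cosine score at or above which a pair is a MATCH
#'   (default 0.98, inclusive).
#' @param ambiguous_low Lower edge of the AMBIGUOUS band
#'   (default 0.95; band is `[ambiguous_low, match_threshold)`).
#' @param key_mode Vector dimensions: `"gene_mutation"` (default; one
#'   dimension per gene + protein change, so shared genes with different
#'   polymorphisms do not collide) or `"gene"` (one dimension per gene, AFs
#'   summed).
#' @param rescue_passes Rounds of cross-cluster rescue scoring (default 1;
#'   each round stops early once no new MATCH appears).
#' @param random_seed Seed for the k-means initialization (default 42).
#' @return A list of class `match_config`.
#' @export
match_config <- function(k_clusters = 2,
                         match_threshold = 0.98,
                         ambiguous_low = 0.95,
                         key_mode = c("gene_mutation", "gene"),
                         rescue_passes = 1,
                         random_seed = 42) {
  key_mode <- match.arg(key_mode)
  if (!(ambiguous_low >= 0 && ambiguous_low < match_threshold &&
          match_threshold <= 1)) {
    stop("need 0 <= ambiguous_low < match_threshold <= 1", call. = FALSE)
  }
  if (k_clusters < 1) stop("k_clusters must be >= 1", call. = FALSE)
  structure(
    list(k_clusters = k_clusters, match_threshold = match_threshold,
         ambiguous_low = ambiguous_low, key_mode = key_mode,
         rescue_passes = rescue_passes, random_seed = random_seed),
    class = "match_config"
  )
}

#' Build a sample's allele-frequency identity vector
#'
#' The identity signal of a sample is its non-pathogenic content — germline
#' variants, polymorphisms and synonymous changes from normal cell-free DNA —
#' so exactly the rows that are *not* tier PATHOGENIC and have a parseable
#' protein change contribute. Magnitudes are allele frequencies in percent.
#' Under `key_mode = "gene"` the AFs of a gene's multiple variants are summed.
#'
#' @param annotated An `annotated_report`.
#' @param key_mode `"gene_mutation"` or `"gene"`.
#' @return Named numeric vector (possibly length 0) of dimension keys to
#'   magnitudes.
#' @export
vectorize_report <- function(annotated, key_mode = c("gene_mutation", "gene")) {
  key_mode <- match.arg(key_mode)
  stopifnot(inherits(annotated, "annotated_report"))
  v <- annotated$variants
  v <- v[v$tier != "PATHOGENIC" & v$aa_change != "", , drop = FALSE]
  if (nrow(v) == 0L) return(stats::setNames(numeric(0), character(0)))
  key <- switch(key_mode,
    gene_mutation = paste(v$gene, v$aa_change, sep = "|"),
    gene = v$gene
  )
  out <- tapply(v$allele_frequency, key, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Cosine similarity of two sparse allele-frequency vectors
#'
#' The dot product over the union of dimension keys (a key absent from one
#' vector contributes 0) divided by the product of the Euclidean norms.
#' Identical-direction vectors score 1, disjoint-support vectors 0; with
#' nonnegative magnitudes the score lies in \[0, 1\]. The score is symmetric
#' and invariant to positive rescaling of either vector. An empty or
#' zero-norm vector has no direction: the result is `NA` with a warning,
#' never a silent 0.
#'
#' @param v1,v2 Named numeric vectors as from [vectorize_report()].
#' @return A single score in \[0, 1\], or `NA_real_` if either vector is
#'   empty or has zero norm.
#' @export
cosine_similarity <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (length(v1) == 0L || length(v2) == 0L || n1 == 0 || n2 == 0) {
    warning("cosine similarity undefined for empty or zero-norm vector",
            call. = FALSE)
    return(NA_real_)
  }
  shared <- intersect(names(v1), names(v2))
  if (length(shared) == 0L) return(0)
  sum(v1[shared] * v2[shared]) / (n1 * n2)
}

score_band <- function(score, config) {
  dplyr::case_when(
    score >= config$match_threshold ~ "MATCH",
    score >= config$ambiguous_low ~ "AMBIGUOUS",
    TRUE ~ "NO_MATCH"
  )
}

# Dense matrix over the union of keys, rows = samples. Column and row order
# fixed by sorting so results are independent of input order.
vectors_to_matrix <- function(vectors) {
  keys <- sort(unique(unlist(lapply(vectors, names))))
  ids <- sort(names(vectors))
  m <- matrix(0, nrow = length(ids), ncol = length(keys),
              dimnames = list(ids, keys))
  for (id in ids) m[id, names(vectors[[id]])] <- vectors[[id]]
  m
}

#' Partition samples into k clusters before pairwise scoring
#'
#' Lloyd's k-means over the dense matrix spanned by the union of dimension
#' keys (missing keys are 0). Initial centers are chosen by a seeded
#' farthest-point sweep (a k-means++-style start with deterministic
#' tie-breaks), so the partition is reproducible under a fixed seed. With
#' fewer samples than `k` all samples go to one cluster with a warning.
#'
#' @param vectors Named list of nonempty identity vectors.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return Named integer vector: cluster id (1..k) per sample.
#' @export
kmeans_partition <- function(vectors, k = 2, seed = 42) {
  ids <- sort(names(vectors))
  if (k <= 1L || length(vectors) <= k) {
    if (k > 1L && length(vectors) <= k) {
      warning("fewer samples than clusters; using a single cluster",
              call. = FALSE)
    }
    return(stats::setNames(rep(1L, length(ids)), ids))
  }
  m <- vectors_to_matrix(vectors)

  # Farthest-point initialization: seeded random first center, then each next
  # center maximizes the distance to its nearest chosen center (first index
  # wins ties).
  centers_idx <- integer(k)
  withr::local_seed(seed)
  centers_idx[1] <- sample.int(nrow(m), 1L)
  mind <- rowSums((m - matrix(m[centers_idx[1], ], nrow(m), ncol(m),
                              byrow = TRUE))^2)
  if (k > 1L) {
    for (j in 2:k) {
      centers_idx[j] <- which.max(mind)
      d <- rowSums((m - matrix(m[centers_idx[j], ], nrow(m), ncol(m),
                               byrow = TRUE))^2)
      mind <- pmin(mind, d)
    }
  }

  fit <- stats::kmeans(m, centers = m[centers_idx, , drop = FALSE],
                       algorithm = "Lloyd", iter.max = 100L)
  stats::setNames(as.integer(fit$cluster), rownames(m))
}

score_pairs <- function(vectors, a, b, config) {
  if (length(a) == 0L) {
    return(tibble::tibble(sample_a = character(0), sample_b = character(0),
                          score = numeric(0), band = character(0)))
  }
  tibble::tibble(
    sample_a = a,
    sample_b = b,
    score = vapply(seq_along(a), function(i) {
      cosine_similarity(vectors[[a[i]]], vectors[[b[i]]])
    }, numeric(1))
  ) |>
    dplyr::mutate(band = score_band(.data$score, config))
}

all_pairs_of <- function(ids) {
  ids <- sort(ids)
  if (length(ids) < 2L) {
    return(list(a = character(0), b = character(0)))
  }
  idx <- utils::combn(length(ids), 2L)
  list(a = ids[idx[1, ]], b = ids[idx[2, ]])
}

#' Score all sample pairs within each cluster
#'
#' Every unordered pair inside a cluster is scored with
#' [cosine_similarity()] and banded: `MATCH` at or above the match threshold,
#' `AMBIGUOUS` in `[ambiguous_low, match_threshold)`, else `NO_MATCH`. No
#' cross-cluster pairs are scored at this stage.
#'
#' @param vectors Named list of identity vectors.
#' @param assignment Named cluster vector from [kmeans_partition()].
#' @param config A [match_config()].
#' @return Tibble of `sample_a`, `sample_b`, `score`, `band` (with
#'   `sample_a < sample_b`).
#' @export
score_within_clusters <- function(vectors, assignment,
                                  config = match_config()) {
  pairs <- lapply(sort(unique(assignment)), function(cl) {
    p <- all_pairs_of(names(assignment)[assignment == cl])
    score_pairs(vectors, p$a, p$b, config)
  })
  dplyr::bind_rows(pairs)
}

#' Rescue samples left unmatched by within-cluster scoring
#'
#' Samples with no MATCH-band pair are pulled out of their clusters and
#' rerun against every sample they have not yet been scored with — across
#' cluster boundaries — so a report whose partner landed in the other
#' k-means cluster still finds it. This is a deterministic, exhaustive
#' replacement for reshuffling unmatched samples between clusters. Repeats
#' for up to `rescue_passes` rounds, stopping early once a round produces no
#' new MATCH or nothing new to score.
#'
#' @param pairs Tibble from [score_within_clusters()].
#' @param vectors Named list of identity vectors.
#' @param config A [match_config()].
#' @return Tibble of additional scored pairs (possibly empty).
#' @export
rescue_unmatched <- function(pairs, vectors, config = match_config()) {
  extra <- pairs[0, ]
  if (config$rescue_passes < 1) return(extra)
  ids <- sort(names(vectors))
  for (pass in seq_len(config$rescue_passes)) {
    seen <- dplyr::bind_rows(pairs, extra)
    matched_ids <- unique(c(seen$sample_a[seen$band == "MATCH"],
                            seen$sample_b[seen$band == "MATCH"]))
    lonely <- setdiff(ids, matched_ids)
    if (length(lonely) == 0L) break
    # every (lonely, any-other) pair, normalized to sample_a < sample_b
    cand_a <- rep(lonely, each = length(ids))
    cand_b <- rep(ids, times = length(lonely))
    keep <- cand_a != cand_b
    a <- pmin(cand_a[keep], cand_b[keep])
    b <- pmax(cand_a[keep], cand_b[keep])
    cand_key <- paste(a, b, sep = "\r")
    dup <- duplicated(cand_key)
    seen_key <- paste(seen$sample_a, seen$sample_b, sep = "\r")
    fresh <- !dup & !(cand_key %in% seen_key)
    if (!any(fresh)) break
    new_pairs <- score_pairs(vectors, a[fresh], b[fresh], config)
    extra <- dplyr::bind_rows(extra, new_pairs)
    if (!any(new_pairs$band == "MATCH")) break
  }
  extra
}

#' Group samples into patients over MATCH edges
#'
#' Connected components of the graph whose edges are the MATCH-band pairs:
#' if A matches B and B matches C, all three are one patient. AMBIGUOUS pairs
#' are reported separately for manual review and never used for grouping.
#' Samples with no MATCH edge become singleton groups. Patient ids are
#' assigned deterministically: groups sorted by their smallest member sample
#' id and labelled `PT001`, `PT002`, ...
#'
#' @param pairs Tibble of all scored pairs (within-cluster plus rescue).
#' @param sample_ids All sample ids that entered scoring (so unmatched
#'   samples still receive singleton groups).
#' @return List with `groups` (tibble `patient_id`, `sample_id`), and
#'   `ambiguous` (the AMBIGUOUS-band pairs).
#' @export
group_patients <- function(pairs, sample_ids) {
  sample_ids <- sort(unique(sample_ids))
  edges <- pairs[pairs$band == "MATCH", c("sample_a", "sample_b")]

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sample_ids, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(g)$membership

  members <- split(names(comp), comp)
  members <- members[order(vapply(members, min, character(1)))]
  groups <- dplyr::bind_rows(lapply(seq_along(members), function(i) {
    tibble::tibble(patient_id = sprintf("PT%03d", i),
                   sample_id = sort(members[[i]]))
  }))

  list(groups = groups,
       ambiguous = pairs[pairs$band == "AMBIGUOUS", , drop = FALSE])
}

#' Match a cohort of annotated reports into patients
#'
#' The full identity-matching stage: vectorize each annotated report
#' ([vectorize_report()]), drop samples with an empty identity vector (with a
#' warning — they cannot be scored), pre-cluster with [kmeans_partition()],
#' score within clusters, run the rescue pass, and group over MATCH edges.
#'
#' @param annotated_reports Named list of `annotated_report` objects.
#' @param config A [match_config()].
#' @return List with `groups`, `pairs` (all scored pairs), `ambiguous`,
#'   `assignment` (the pre-clustering) and `vectors`.
#' @export
match_patients <- function(annotated_reports, config = match_config()) {
  vectors <- lapply(annotated_reports, vectorize_report,
                    key_mode = config$key_mode)
  names(vectors) <- vapply(annotated_reports, `[[`, character(1), "sample_id")
  empty <- vapply(vectors, function(v) length(v) == 0L || sum(v^2) == 0,
                  logical(1))
  if (any(empty)) {
    warning("excluded from matching (empty identity vector): ",
            paste(names(vectors)[empty], collapse = ", "), call. = FALSE)
    vectors <- vectors[!empty]
  }
  if (length(vectors) == 0L) {
    empty_pairs <- tibble::tibble(sample_a = character(0),
                                  sample_b = character(0),
                                  score = numeric(0), band = character(0))
    return(list(groups = tibble::tibble(patient_id = character(0),
                                        sample_id = character(0)),
                pairs = empty_pairs, ambiguous = empty_pairs,
                assignment = integer(0), vectors = vectors))
  }

  assignment <- kmeans_partition(vectors, k = config$k_clusters,
                                 seed = config$random_seed)
  pairs <- score_within_clusters(vectors, assignment, config)
  pairs <- dplyr::bind_rows(pairs, rescue_unmatched(pairs, vectors, config))
  grouping <- group_patients(pairs, names(vectors))

  list(groups = grouping$groups, pairs = pairs,
       ambiguous = grouping$ambiguous, assignment = assignment,
       vectors = vectors)
}
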