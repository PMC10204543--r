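test_that("cosine similarity hits its closed-form values", {
  v1 <- c(g1 = 3, g2 = 4)
  v2 <- c(g1 = 4, g2 = 3)
  expect_equal(cosine_similarity(v1, v2), 24 / 25)

  expect_equal(cosine_similarity(v1, v1), 1)
  expect_equal(cosine_similarity(v1, v1 * 2.5), 1)    # scale invariance
  expect_equal(cosine_similarity(v1, c(g3 = 7, g4 = 1)), 0)  # disjoint

  expect_warning(s <- cosine_similarity(numeric(0), v1), "undefined")
  expect_true(is.na(s))
  expect_warning(s0 <- cosine_similarity(c(g1 = 0), v1), "undefined")
  expect_true(is.na(s0))
})

test_that("cosine similarity matches a brute-force oracle on random vectors", {
  set.seed(123)
  worst <- 0
  for (i in 1:300) {
    v1 <- random_sparse_vector(prefix = "A")
    v2 <- random_sparse_vector(prefix = "B")
    # force some key overlap half the time
    if (i %% 2 == 0) names(v2)[1:5] <- names(v1)[1:5]
    d <- abs(cosine_similarity(v1, v2) - cosine_brute_force(v1, v2))
    worst <- max(worst, d)
    # symmetry
    expect_equal(cosine_similarity(v1, v2), cosine_similarity(v2, v1))
  }
  expect_lt(worst, 1e-12)
})

test_that("vectorization keeps exactly the non-pathogenic joinable rows", {
  ann <- make_annotated(
    "S1",
    gene = c("EGFR", "BRAF", "TP53", "TP53", "ALK"),
    aa_change = c("p.Q787Q", "p.V600E", "p.P72R", "p.R213R", ""),
    af = c(49.8, 12, 30, 20, 40),
    tier = c("NEUTRAL", "PATHOGENIC", "NEUTRAL", "LOWER", "NEUTRAL")
  )
  v <- vectorize_report(ann)
  expect_setequal(names(v), c("EGFR|p.Q787Q", "TP53|p.P72R", "TP53|p.R213R"))
  expect_equal(unname(v["EGFR|p.Q787Q"]), 49.8)

  # gene mode sums a gene's variants
  vg <- vectorize_report(ann, key_mode = "gene")
  expect_equal(unname(vg["TP53"]), 50)

  all_path <- make_annotated("S2", "BRAF", "p.V600E", 12,
                             tier = "PATHOGENIC")
  expect_length(vectorize_report(all_path), 0)
})

test_that("k-means pre-clustering separates vector families deterministically", {
  set.seed(5)
  fam_a <- lapply(1:5, function(i) {
    stats::setNames(stats::runif(8, 40, 60), paste0("A", 1:8))
  })
  fam_b <- lapply(1:5, function(i) {
    stats::setNames(stats::runif(8, 40, 60), paste0("B", 1:8))
  })
  vectors <- c(fam_a, fam_b)
  names(vectors) <- sprintf("S%02d", 1:10)

  asg <- kmeans_partition(vectors, k = 2, seed = 42)
  expect_length(unique(asg[1:5]), 1L)
  expect_length(unique(asg[6:10]), 1L)
  expect_false(asg[[1]] == asg[[10]])

  expect_identical(kmeans_partition(vectors, k = 2, seed = 42), asg)

  expect_identical(unique(unname(kmeans_partition(vectors, k = 1))), 1L)
  expect_warning(one <- kmeans_partition(vectors[1:2], k = 5), "single")
  expect_identical(unique(unname(one)), 1L)
})

test_that("within-cluster scoring produces all pairs with correct bands", {
  vectors <- list(
    S1 = c(a = 50, b = 50),
    S2 = c(a = 51, b = 49),
    S3 = c(c = 50, d = 48),
    S4 = c(x = 10, y = 90)
  )
  asg <- stats::setNames(c(1L, 1L, 1L, 2L), names(vectors))
  pairs <- score_within_clusters(vectors, asg, match_config())
  expect_equal(nrow(pairs), 3L)   # 3 choose 2 in cluster 1, none in cluster 2
  s12 <- pairs$score[pairs$sample_a == "S1" & pairs$sample_b == "S2"]
  expect_identical(pairs$band[pairs$sample_a == "S1" & pairs$sample_b == "S2"],
                   "MATCH")
  expect_gte(s12, 0.98)
  expect_identical(pairs$band[pairs$sample_a == "S1" & pairs$sample_b == "S3"],
                   "NO_MATCH")

  cfg <- match_config()
  expect_identical(plasmatrace:::score_band(0.985, cfg), "MATCH")
  expect_identical(plasmatrace:::score_band(0.98, cfg), "MATCH")
  expect_identical(plasmatrace:::score_band(0.96, cfg), "AMBIGUOUS")
  expect_identical(plasmatrace:::score_band(0.95, cfg), "AMBIGUOUS")
  expect_identical(plasmatrace:::score_band(0.9499, cfg), "NO_MATCH")
})

test_that("rescue pass recovers same-patient samples split across clusters", {
  # S1/S2 are near-identical but forced into different clusters.
  vectors <- list(
    S1 = c(a = 50, b = 50, c = 97),
    S2 = c(a = 50.5, b = 49.5, c = 96.5),
    S3 = c(p = 45, q = 55),
    S4 = c(u = 60, v = 40)
  )
  asg <- stats::setNames(c(1L, 2L, 1L, 2L), names(vectors))
  within <- score_within_clusters(vectors, asg, match_config())
  expect_false(any(within$band == "MATCH"))

  extra <- rescue_unmatched(within, vectors, match_config())
  m <- extra[extra$band == "MATCH", ]
  expect_equal(nrow(m), 1L)
  expect_identical(sort(c(m$sample_a, m$sample_b)), c("S1", "S2"))

  # rescue_passes = 0 adds nothing
  expect_equal(nrow(rescue_unmatched(within, vectors,
                                     match_config(rescue_passes = 0))), 0L)

  # nothing to rescue when everyone is matched
  all_matched <- tibble::tibble(sample_a = c("S1", "S3"),
                                sample_b = c("S2", "S4"),
                                score = c(0.99, 0.99),
                                band = c("MATCH", "MATCH"))
  expect_equal(nrow(rescue_unmatched(all_matched, vectors, match_config())),
               0L)
})

test_that("grouping is transitive closure over MATCH edges only", {
  pairs <- tibble::tibble(
    sample_a = c("A", "B", "D"),
    sample_b = c("B", "C", "E"),
    score = c(0.99, 0.985, 0.97),
    band = c("MATCH", "MATCH", "AMBIGUOUS")
  )
  out <- group_patients(pairs, c("A", "B", "C", "D", "E", "F"))
  by_patient <- split(out$groups$sample_id, out$groups$patient_id)
  sizes <- sort(vapply(by_patient, length, integer(1)))
  expect_equal(unname(sizes), c(1L, 1L, 1L, 3L))
  abc <- by_patient[[which(vapply(by_patient, length, integer(1)) == 3L)]]
  expect_setequal(abc, c("A", "B", "C"))

  # ambiguous edge reported, not grouped
  expect_equal(nrow(out$ambiguous), 1L)
  expect_setequal(c(out$ambiguous$sample_a, out$ambiguous$sample_b),
                  c("D", "E"))

  # agrees with a brute-force component oracle
  oracle <- components_brute_force(c("A", "B", "C", "D", "E", "F"),
                                   c("A", "B"), c("B", "C"))
  oracle_sets <- vapply(oracle, function(s) paste(sort(s), collapse = ","),
                        character(1))
  got_sets <- vapply(by_patient, function(s) paste(sort(s), collapse = ","),
                     character(1))
  expect_setequal(unname(got_sets), unname(oracle_sets))

  # no MATCH edges: all singletons
  none <- group_patients(pairs[pairs$band != "MATCH", ], c("X", "Y"))
  expect_equal(nrow(none$groups), 2L)
  expect_equal(length(unique(none$groups$patient_id)), 2L)
})

test_that("matching is invariant to input sample order and to k", {
  sim <- generate_cohort(sim_config(n_patients = 8, draws_per_patient = 2,
                                    seed = 21))
  ref <- make_reference("KRAS", "p.G12D", "PATHOGENIC", 0.98)
  ann <- annotate_cohort(sim$cohort, ref)

  res_fwd <- match_patients(ann)
  res_rev <- match_patients(rev(ann))
  expect_identical(
    dplyr::arrange(res_fwd$groups, sample_id),
    dplyr::arrange(res_rev$groups, sample_id)
  )

  res_k1 <- match_patients(ann, match_config(k_clusters = 1))
  expect_identical(
    dplyr::arrange(res_fwd$groups, sample_id),
    dplyr::arrange(res_k1$groups, sample_id)
  )
})

test_that("empty identity vectors are excluded with a warning, not scored", {
  good <- make_annotated("S1", c("EGFR", "TP53"), c("p.Q787Q", "p.P72R"),
                         c(49, 51))
  good2 <- make_annotated("S2", c("EGFR", "TP53"), c("p.Q787Q", "p.P72R"),
                          c(50, 50))
  all_path <- make_annotated("S3", "BRAF", "p.V600E", 12, tier = "PATHOGENIC")
  # two scorable samples also trip the fewer-samples-than-clusters warning
  w <- capture_warnings(res <- match_patients(list(good, good2, all_path)))
  expect_true(any(grepl("empty identity vector", w)))
  expect_false("S3" %in% res$groups$sample_id)
  expect_true(all(c("S1", "S2") %in% res$groups$sample_id))
})
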