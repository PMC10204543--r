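test_that("draws order by date when available, else by sample id", {
  dated <- order_draws(c("B", "A"),
                       c(A = "2021-03-10", B = "2021-01-05"))
  expect_identical(dated$sample_id, c("B", "A"))
  expect_identical(dated$draw_index, 1:2)

  undated <- order_draws(c("S100", "S010"), NULL)
  expect_identical(undated$sample_id, c("S010", "S100"))

  expect_warning(
    mixed <- order_draws(c("S2", "S1"), c(S1 = "2021-01-01", S2 = NA)),
    "mixed"
  )
  expect_identical(mixed$sample_id, c("S1", "S2"))  # falls back to id order

  single <- order_draws("S1", NULL)
  expect_identical(single$draw_index, 1L)
})

test_that("undetected draws of a tracked mutation appear as explicit zeros", {
  # KRAS p.G12D detected only at the third of three draws
  draws <- list(
    make_annotated("P1-1", c("EGFR"), c("p.Q787Q"), c(49)),
    make_annotated("P1-2", c("EGFR"), c("p.Q787Q"), c(50)),
    make_annotated("P1-3", c("EGFR", "KRAS"), c("p.Q787Q", "p.G12D"),
                   c(51, 6), tier = c("NEUTRAL", "PATHOGENIC"))
  )
  names(draws) <- vapply(draws, `[[`, character(1), "sample_id")
  groups <- tibble::tibble(patient_id = "PT001",
                           sample_id = names(draws))
  tl <- build_timeline(groups, draws)

  kras <- tl$timeline[tl$timeline$gene == "KRAS", ]
  expect_equal(kras$draw_index, 1:3)
  expect_equal(kras$allele_frequency, c(0, 0, 6))
  # first detection at draw 3
  expect_equal(min(kras$draw_index[kras$allele_frequency > 0]), 3L)
})

test_that("germline and low-AF series are excluded from the default view", {
  one <- make_annotated(
    "S1",
    gene = c("KRAS", "TP53", "BRAF"),
    aa_change = c("p.G12D", "p.R175H", "p.V600E"),
    af = c(6, 51, 0.4),   # somatic, germline-range, sub-1%
    tier = rep("PATHOGENIC", 3)
  )
  groups <- tibble::tibble(patient_id = "PT001", sample_id = "S1")
  tl <- build_timeline(groups, list(S1 = one))
  expect_identical(unique(tl$timeline$gene), "KRAS")

  # both reappear when the filters are lifted
  tl_all <- build_timeline(groups, list(S1 = one),
                           include_germline = TRUE,
                           apply_low_af_filter = FALSE)
  expect_setequal(unique(tl_all$timeline$gene), c("KRAS", "TP53", "BRAF"))

  # filtered view is row-wise a subset of the scaffold over the full table
  expect_lte(nrow(tl$timeline), nrow(tl_all$timeline))
})

test_that("timeline series count equals distinct pathogenic mutations", {
  sim <- generate_cohort(sim_config(
    n_patients = 3, draws_per_patient = 3, seed = 9,
    pathogenic_scenarios = dplyr::bind_rows(
      scenario_new_detection(1),
      scenario_remission_recurrence(2)
    )
  ))
  ref <- make_reference(
    gene = c("KRAS", "BRAF", "KRAS"),
    aa_change = c("p.G12D", "p.V600E", "p.G12C"),
    classification = rep("PATHOGENIC", 3),
    fathmm_score = c(0.98, 0.97, 0.96)
  )
  res <- run_pipeline(sim$cohort, ref)

  series <- unique(res$timeline[, c("patient_id", "gene", "aa_change")])
  # distinct pathogenic mutations across each patient's annotated reports
  path_rows <- res$timeline_full[res$timeline_full$tier == "PATHOGENIC" &
                                   !res$timeline_full$germline_flag &
                                   !res$timeline_full$low_af_flag, ]
  expected <- unique(path_rows[, c("patient_id", "gene", "aa_change")])
  expect_equal(nrow(series), nrow(expected))

  # a patient with no pathogenic mutations contributes no series
  expect_equal(nrow(series), 3L)  # KRAS G12D, BRAF V600E, KRAS G12C
})

test_that("remission and recurrence are visible as a zero gap between draws", {
  sim <- generate_cohort(sim_config(
    n_patients = 1, draws_per_patient = 3, seed = 4,
    pathogenic_scenarios = scenario_remission_recurrence(1)
  ))
  ref <- make_reference(
    gene = c("BRAF", "KRAS"), aa_change = c("p.V600E", "p.G12C"),
    classification = c("PATHOGENIC", "PATHOGENIC"),
    fathmm_score = c(0.97, 0.96)
  )
  res <- run_pipeline(sim$cohort, ref)
  braf <- res$timeline[res$timeline$gene == "BRAF", ]
  kras <- res$timeline[res$timeline$gene == "KRAS", ]
  expect_true(braf$allele_frequency[braf$draw_index == 1] > 0)
  expect_equal(braf$allele_frequency[braf$draw_index %in% 2:3], c(0, 0))
  expect_equal(kras$allele_frequency[kras$draw_index %in% 1:2], c(0, 0))
  expect_true(kras$allele_frequency[kras$draw_index == 3] > 0)
})

test_that("export writes all tables and is byte-identical across reruns", {
  sim <- generate_cohort(sim_config(n_patients = 4, draws_per_patient = 2,
                                    seed = 31,
                                    pathogenic_scenarios =
                                      scenario_new_detection(1, vaf = 6)))
  ref <- make_reference("KRAS", "p.G12D", "PATHOGENIC", 0.98)

  run_once <- function(dir) {
    res <- run_pipeline(sim$cohort, ref)
    export_results(res, dir)
  }
  d1 <- file.path(tempfile(), "run1")
  d2 <- file.path(tempfile(), "run2")
  f1 <- run_once(d1)
  f2 <- run_once(d2)

  expect_setequal(basename(unname(f1)),
                  c("annotated.csv", "qc.csv", "pairs.csv", "ambiguous.csv",
                    "groups.csv", "timeline.csv", "timeline_full.csv"))
  sums1 <- unname(tools::md5sum(sort(unname(f1))))
  sums2 <- unname(tools::md5sum(sort(unname(f2))))
  expect_identical(sums1, sums2)
})

test_that("an empty cohort exports headers-only tables without crashing", {
  res <- list(
    annotated = list(),
    pairs = tibble::tibble(sample_a = character(0), sample_b = character(0),
                           score = numeric(0), band = character(0)),
    ambiguous = tibble::tibble(sample_a = character(0),
                               sample_b = character(0),
                               score = numeric(0), band = character(0)),
    groups = tibble::tibble(patient_id = character(0),
                            sample_id = character(0)),
    timeline = tibble::tibble(patient_id = character(0)),
    timeline_full = tibble::tibble(patient_id = character(0))
  )
  dir <- tempfile()
  files <- export_results(res, dir)
  expect_true(all(file.exists(files)))
  expect_equal(nrow(readr::read_csv(files[["groups"]],
                                    show_col_types = FALSE)), 0L)
})
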