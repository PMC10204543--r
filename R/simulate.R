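# Synthetic cohort simulator: panel reports with per-patient germline
# profiles, time-varying somatic pathogenic VAFs, sequencing noise, a
# matching mini-reference, and ground-truth patient labels.

#' The 56-gene targeted oncology panel
#'
#' Gene targets of the amplicon panel the simulated reports cover.
#'
#' @return Character vector of 56 HGNC gene symbols.
#' @export
panel_genes <- function() {
  c("ABL1", "AKT1", "ALK", "APC", "ATM", "BRAF", "CDH1", "CDKN2A", "CSF1R",
    "CTNNB1", "DDR2", "DNMT3A", "EGFR", "ERBB2", "ERBB4", "EZH2", "FBXW7",
    "FGFR1", "FGFR2", "FGFR3", "FLT3", "FOXL2", "GNA11", "GNAQ", "GNAS",
    "HNF1A", "HRAS", "IDH1", "IDH2", "JAK2", "JAK3", "KDR", "KIT", "KRAS",
    "MAP2K1", "MET", "MLH1", "MPL", "MSH6", "NOTCH1", "NPM1", "NRAS",
    "PDGFRA", "PIK3CA", "PTEN", "PTPN11", "RB1", "RET", "SMAD4", "SMARCB1",
    "SMO", "SRC", "STK11", "TP53", "TSC1", "VHL")
}

#' Simulation configuration
#'
#' Defaults encode the data-generating assumptions the pipeline relies on:
#' heterozygous germline variants near 50% allele frequency, homozygous near
#' 100%, per-draw resequencing jitter of a point or two, and a 1% detection
#' floor below which a variant is simply absent from the report.
#'
#' @param n_patients Number of patients.
#' @param draws_per_patient Blood draws per patient: a single integer or a
#'   length-`n_patients` vector.
#' @param panel Gene panel (default the 56-gene panel, [panel_genes()]).
#' @param n_germline_per_patient Germline/polymorphism variants per patient
#'   (default 20) — the identity signal.
#' @param het_af_mean,het_af_sd Heterozygous germline AF distribution,
#'   percent (default 50, 2.5).
#' @param hom_af_mean,hom_af_sd Homozygous germline AF distribution, percent
#'   (default 97, 1.5).
#' @param hom_fraction Probability a germline variant is homozygous
#'   (default 0.2).
#' @param noise_sd Per-draw resequencing jitter added to each germline AF,
#'   percentage points (default 1.5).
#' @param n_noise_rows Random low-AF neutral rows per report (default 5),
#'   AF uniform in \[1, 8\] percent.
#' @param pathogenic_scenarios Tibble/data frame with columns `patient`
#'   (integer index), `gene`, `aa_change`, `draw` (integer), `vaf` (percent):
#'   the injected somatic trajectory, one row per draw where the true VAF is
#'   nonzero. See [scenario_new_detection()] and
#'   [scenario_remission_recurrence()].
#' @param detection_floor Variants below this true VAF (percent) are omitted
#'   from the report, modelling the assay's detection limit (default 1).
#' @param seed Integer seed; fully determines the cohort.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 30,
                       draws_per_patient = 2,
                       panel = panel_genes(),
                       n_germline_per_patient = 20,
                       het_af_mean = 50, het_af_sd = 2.5,
                       hom_af_mean = 97, hom_af_sd = 1.5,
                       hom_fraction = 0.2,
                       noise_sd = 1.5,
                       n_noise_rows = 5,
                       pathogenic_scenarios = NULL,
                       detection_floor = 1,
                       seed = 1) {
  if (length(panel) == 0L) stop("panel must be nonempty", call. = FALSE)
  if (n_germline_per_patient < 1) {
    stop("n_germline_per_patient must be >= 1 (the identity signal)",
         call. = FALSE)
  }
  if (length(draws_per_patient) == 1L) {
    draws_per_patient <- rep(as.integer(draws_per_patient), n_patients)
  }
  stopifnot(length(draws_per_patient) == n_patients)
  if (!is.null(pathogenic_scenarios)) {
    pathogenic_scenarios <- tibble::as_tibble(pathogenic_scenarios)
    stopifnot(all(c("patient", "gene", "aa_change", "draw", "vaf") %in%
                    names(pathogenic_scenarios)))
    off_panel <- setdiff(pathogenic_scenarios$gene, panel)
    if (length(off_panel) > 0L) {
      stop("scenario gene(s) not on panel: ",
           paste(off_panel, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_patients = n_patients, draws_per_patient = draws_per_patient,
         panel = panel, n_germline_per_patient = n_germline_per_patient,
         het_af_mean = het_af_mean, het_af_sd = het_af_sd,
         hom_af_mean = hom_af_mean, hom_af_sd = hom_af_sd,
         hom_fraction = hom_fraction, noise_sd = noise_sd,
         n_noise_rows = n_noise_rows,
         pathogenic_scenarios = pathogenic_scenarios,
         detection_floor = detection_floor, seed = seed),
    class = "sim_config"
  )
}

#' Canned somatic trajectory: new detection at the third draw
#'
#' A KRAS mutation absent from the first two draws and detected in the third
#' — the pattern of a pancreatic-cancer monitoring course where ctDNA
#' becomes detectable as disease progresses.
#'
#' @param patient Patient index the trajectory is injected into (default 1).
#' @param vaf VAF at the detection draw, percent (default 6).
#' @return Scenario tibble for [sim_config()] (implies 3 draws).
#' @export
scenario_new_detection <- function(patient = 1, vaf = 6) {
  tibble::tibble(patient = patient, gene = "KRAS", aa_change = "p.G12D",
                 draw = 3L, vaf = vaf)
}

#' Canned somatic trajectory: remission then recurrence
#'
#' A BRAF mutation present at the first draw, absent at the second
#' (remission), then a new KRAS mutation at the third draw (recurrence with
#' a different clone) — the pattern of a colorectal-cancer monitoring course.
#'
#' @param patient Patient index (default 1).
#' @param vaf_braf,vaf_kras VAFs at their detection draws, percent.
#' @return Scenario tibble for [sim_config()] (implies 3 draws).
#' @export
scenario_remission_recurrence <- function(patient = 1, vaf_braf = 8,
                                          vaf_kras = 5) {
  tibble::tibble(
    patient = patient,
    gene = c("BRAF", "KRAS"),
    aa_change = c("p.V600E", "p.G12C"),
    draw = c(1L, 3L),
    vaf = c(vaf_braf, vaf_kras)
  )
}

# Pool of syntactically valid synthetic protein changes per gene: missense
# changes at positions 100, 110, ... cycling through residues. Deterministic,
# no real hotspot catalogue involved.
synthetic_aa_pool <- function(panel, per_gene = 40) {
  residues <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  pool <- expand.grid(gene = panel, i = seq_len(per_gene),
                      stringsAsFactors = FALSE)
  ref <- residues[(pool$i - 1L) %% 20L + 1L]
  alt <- residues[pool$i %% 20L + 1L]
  tibble::tibble(
    gene = pool$gene,
    aa_change = paste0("p.", ref, 100L + 10L * pool$i, alt)
  )
}

#' Generate a reference table covering a simulation
#'
#' Contains every scenario mutation as `PATHOGENIC` with a FATHMM score in
#' \[0.8, 1\], plus `n_neutral_entries` `NEUTRAL` entries (scores in
#' \[0.5, 0.8)) and `n_lower_entries` entries in the very-low score range
#' (< 0.5) drawn from the synthetic variant pool, so annotated reports
#' exercise all three tiers.
#'
#' @param panel Gene panel.
#' @param scenarios Scenario tibble (or `NULL`).
#' @param n_neutral_entries,n_lower_entries Counts of non-pathogenic entries.
#' @param seed Integer seed.
#' @return Tibble in the [load_reference()] CSV dialect.
#' @export
generate_reference <- function(panel = panel_genes(), scenarios = NULL,
                               n_neutral_entries = 40, n_lower_entries = 5,
                               seed = 1) {
  rng <- local_rng(seed + 7L)
  pool <- synthetic_aa_pool(panel)
  take <- pool[sample.int(nrow(pool), n_neutral_entries + n_lower_entries), ]
  entries <- tibble::tibble(
    gene = take$gene,
    aa_change = take$aa_change,
    classification = "NEUTRAL",
    fathmm_score = c(stats::runif(n_neutral_entries, 0.5, 0.79),
                     stats::runif(n_lower_entries, 0.05, 0.45))
  )
  if (!is.null(scenarios) && nrow(scenarios) > 0L) {
    sc <- dplyr::distinct(tibble::as_tibble(scenarios)[, c("gene", "aa_change")])
    entries <- dplyr::bind_rows(
      tibble::tibble(gene = sc$gene, aa_change = sc$aa_change,
                     classification = "PATHOGENIC",
                     fathmm_score = stats::runif(nrow(sc), 0.85, 0.99)),
      entries
    )
  }
  entries <- dplyr::distinct(entries, .data$gene, .data$aa_change,
                             .keep_all = TRUE)
  entries$fathmm_score <- round(entries$fathmm_score, 4)
  entries
}

#' Generate one patient's germline profile
#'
#' Samples `n_germline_per_patient` distinct `(gene, aa_change)` variants
#' from the synthetic pool and assigns each a zygosity (`hom` with
#' probability `hom_fraction`) and a patient-level true allele frequency
#' drawn from the heterozygous or homozygous distribution. Within
#' [generate_cohort()], profiles are resampled until every pair of patients
#' differs in at least 30% of keys, so identities are separable by
#' construction — as human germline genotypes are.
#'
#' @param config A [sim_config()]. RNG state is taken as-is (callers seed).
#' @return Tibble `gene`, `aa_change`, `zygosity`, `true_af`.
#' @export
generate_patient_profile <- function(config) {
  pool <- synthetic_aa_pool(config$panel)
  if (nrow(pool) < config$n_germline_per_patient) {
    stop("variant pool too small for n_germline_per_patient; enlarge panel",
         call. = FALSE)
  }
  take <- pool[sample.int(nrow(pool), config$n_germline_per_patient), ]
  zyg <- ifelse(stats::runif(nrow(take)) < config$hom_fraction, "hom", "het")
  af <- ifelse(
    zyg == "hom",
    stats::rnorm(nrow(take), config$hom_af_mean, config$hom_af_sd),
    stats::rnorm(nrow(take), config$het_af_mean, config$het_af_sd)
  )
  tibble::tibble(
    gene = take$gene, aa_change = take$aa_change,
    zygosity = zyg, true_af = pmin(pmax(af, 0), 100)
  )
}

# Seed the RNG for the calling function only; the caller's state is restored
# when it exits.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
  invisible(seed)
}

#' Generate a full synthetic cohort
#'
#' One report per (patient, draw): the patient's germline profile with
#' per-draw Gaussian jitter (sd `noise_sd`), injected scenario pathogenic
#' variants at their exact per-draw VAF when at or above the detection floor
#' (below it the row is omitted — the assay does not call it), and a few
#' random low-AF neutral noise rows. Also produces a matching reference via
#' [generate_reference()] and the ground-truth sample-to-patient labels.
#' The same seed yields a byte-identical cohort.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: when given, reports are written as TSVs in
#'   `dir/reports/`, the reference as `dir/reference.csv` and the truth
#'   labels as `dir/truth.csv` (kept out of the reports directory).
#' @return List with `cohort` (an `lb_cohort` of parsed-equivalent
#'   `sample_report`s), `reference` (tibble), `truth` (tibble `sample_id`,
#'   `patient_id`), `injected` (per-sample injected pathogenic rows) and
#'   `paths` (when `dir` was given).
#' @export
generate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  local_rng(config$seed)

  # Patient profiles, resampled until pairwise key overlap is below 70%.
  profiles <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    for (attempt in seq_len(50L)) {
      prof <- generate_patient_profile(config)
      keys <- paste(prof$gene, prof$aa_change)
      ok <- all(vapply(profiles[seq_len(p - 1L)], function(other) {
        if (is.null(other)) return(TRUE)
        other_keys <- paste(other$gene, other$aa_change)
        length(intersect(keys, other_keys)) /
          length(union(keys, other_keys)) < 0.7
      }, logical(1)))
      if (ok) break
      if (attempt == 50L) {
        stop("could not draw sufficiently distinct germline profiles; ",
             "enlarge the panel or reduce n_germline_per_patient",
             call. = FALSE)
      }
    }
    profiles[[p]] <- prof
  }

  scenarios <- config$pathogenic_scenarios
  reference <- generate_reference(config$panel, scenarios, seed = config$seed)

  pool <- synthetic_aa_pool(config$panel)
  cohort <- new_cohort()
  truth <- list()
  injected <- list()

  for (p in seq_len(config$n_patients)) {
    prof <- profiles[[p]]
    for (d in seq_len(config$draws_per_patient[p])) {
      sid <- sprintf("S%03d-%02d", p, d)

      af <- prof$true_af + stats::rnorm(nrow(prof), 0, config$noise_sd)
      rows <- tibble::tibble(
        gene = prof$gene, aa_change = prof$aa_change,
        allele_frequency = pmin(pmax(af, 0), 100)
      )

      noise_idx <- sample.int(nrow(pool), config$n_noise_rows)
      noise <- tibble::tibble(
        gene = pool$gene[noise_idx],
        aa_change = pool$aa_change[noise_idx],
        allele_frequency = stats::runif(config$n_noise_rows, 1, 8)
      )
      rows <- dplyr::bind_rows(rows, noise)

      if (!is.null(scenarios)) {
        sc <- scenarios[scenarios$patient == p & scenarios$draw == d &
                          scenarios$vaf >= config$detection_floor, ,
                        drop = FALSE]
        if (nrow(sc) > 0L) {
          rows <- dplyr::bind_rows(rows, tibble::tibble(
            gene = sc$gene, aa_change = sc$aa_change,
            allele_frequency = sc$vaf
          ))
          injected[[length(injected) + 1L]] <- tibble::tibble(
            sample_id = sid, gene = sc$gene, aa_change = sc$aa_change,
            true_vaf = sc$vaf
          )
        }
      }

      rows <- dplyr::distinct(rows, .data$gene, .data$aa_change,
                              .keep_all = TRUE)
      records <- tibble::tibble(
        sample_id = sid, gene = rows$gene, aa_change_raw = rows$aa_change,
        aa_change = rows$aa_change, nt_change = NA_character_,
        allele_frequency = round(rows$allele_frequency, 2),
        depth = NA_integer_
      )
      report <- structure(
        list(sample_id = sid, draw_date = sprintf("2021-%02d-01", d),
             source_path = NA_character_, records = records),
        class = "sample_report"
      )
      cohort <- add_report(cohort, report)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        sample_id = sid, patient_id = sprintf("TRUE-P%03d", p)
      )
    }
  }

  out <- list(
    cohort = cohort,
    reference = reference,
    truth = dplyr::bind_rows(truth),
    injected = if (length(injected) > 0L) dplyr::bind_rows(injected) else
      tibble::tibble(sample_id = character(0), gene = character(0),
                     aa_change = character(0), true_vaf = numeric(0))
  )

  if (!is.null(dir)) {
    reports_dir <- file.path(dir, "reports")
    dir.create(reports_dir, showWarnings = FALSE, recursive = TRUE)
    for (sid in names(out$cohort)) {
      write_report(out$cohort[[sid]],
                   file.path(reports_dir, paste0(sid, ".tsv")))
    }
    write_reference(out$reference, file.path(dir, "reference.csv"))
    readr::write_csv(out$truth, file.path(dir, "truth.csv"), progress = FALSE)
    out$paths <- list(reports = reports_dir,
                      reference = file.path(dir, "reference.csv"),
                      truth = file.path(dir, "truth.csv"))
  }
  out
}
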