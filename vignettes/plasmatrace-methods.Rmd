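---
title: "Methods: annotation, identity matching and longitudinal tracking of ctDNA reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation, identity matching and longitudinal tracking of ctDNA reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmatrace)
```

This vignette explains the models and procedures behind `plasmatrace`, the
assumptions they make, the tunable parameters and their defaults, and the
choices made where the design was genuinely open. The package processes
anonymous liquid-biopsy variant reports — tabular exports with one row per
observed gene and amino-acid change, carrying a variant allele frequency
(VAF, in percent) — through three stages: pathogenicity annotation, patient
identity matching, and longitudinal VAF assembly.

## 1. Input normalization

Reports arrive as TSV/CSV tables whose protein changes may use three-letter
HGVS codes (`p.Gly12Asp`) while mutation references use one-letter codes
(`p.G12D`). `normalize_aa_change()` converts three-letter residue tokens to
one-letter form, maps stop codons (`Ter`) to `*`, and preserves frameshift,
`del`/`ins`/`dup`/`ext` and synonymous (`=`) tokens. The function is
idempotent, so already-normalized strings pass through unchanged, and
unparseable strings become the empty string rather than an error: such rows
are retained in the report (their allele frequency may still matter to a
reviewer) but are excluded from reference joining and from identity vectors,
which both require a well-defined key.

Allele frequencies are kept on the percent scale throughout. Because
upstream exports differ, the AF column name and its scale (`percent` or
`fraction`, the latter multiplied by 100 on read) are configuration options
of `parse_report()` rather than assumptions.

Within one report, repeated calls of the same `(gene, aa_change)` — amplicon
panels can call a variant once per amplicon — are collapsed to the
highest-depth row, falling back to first occurrence when depth is absent.
Across reports, a sample id already present in the cohort store is skipped
with a warning, never silently merged: duplicate uploads must be visible.

## 2. Pathogenicity annotation

The reference is a deduplicated table of known mutations keyed by
`(gene, aa_change)`, each with a `PATHOGENIC`/`NEUTRAL` classification and a
FATHMM score in $[0,1]$ (1 = most severe). When the raw table contains
conflicting duplicates, the entry with the highest score wins, and
`PATHOGENIC` beats `NEUTRAL` on an exact score tie — the conservative choice
for a clinical-review context, where missing a pathogenic call is worse than
flagging one for review.

Tier assignment for an observed variant:

* **PATHOGENIC** — matched in the reference, classified pathogenic, and
  FATHMM score $\geq$ 0.8. The boundary is inclusive: a score of exactly
  0.8 counts, consistent with validation practice that treats 0.8 as the
  pathogenic cutoff.
* **LOWER** — matched with score $<$ 0.5: known, but with very low
  pathogenicity severity.
* **NEUTRAL** — everything else, including variants absent from the
  reference. No evidence is not evidence of pathogenicity; there is no
  separate "unknown" tier in the report layout this feeds.

Both cutoffs are parameters of `annotate_config()` (defaults 0.8 and 0.5,
with `pathogenic_cutoff > lower_cutoff` enforced). Raising the pathogenic
cutoff can only shrink the PATHOGENIC set — a monotonicity property the test
suite checks.

Two per-variant flags support downstream filtering. The **germline flag**
marks allele frequencies "around 50% or 100%": an inherited variant is in
essentially every cell, so cell-free DNA shows it near 50% (heterozygous) or
100% (homozygous), while somatic tumor variants sit far lower. The default
bands are symmetric: $[40, 60]$ for heterozygous and $\geq 90$ for
homozygous, both configurable. The **low-AF flag** marks frequencies
strictly below 1%, the practical detection limit of the assay; exactly 1% is
not flagged.

Report-level QC applies two independent checks: fewer than 32 gene+mutation
rows (`min_rows`), and a mutation-to-gene ratio above 0.25 (`max_ratio`).
The ratio's exact definition is genuinely ambiguous: taken as *all* rows
over the 56 panel genes, any report passing the 32-row minimum would also
exceed 0.25 ($32/56 \approx 0.57$), making the two rules contradictory. The
default mode therefore counts PATHOGENIC-tier rows per distinct gene in the
report — a small number in a clean report, inflated when sequencing noise
produces spurious pathogenic calls — and the literal rows-per-panel-gene
reading remains available as `ratio_mode = "rows_per_panel_gene"`.

## 3. Patient identity matching

Reports are anonymous, but the non-tumorigenic content of cell-free DNA —
germline variants, polymorphisms, synonymous changes — is a stable genetic
fingerprint of the donor. Each annotated report becomes a sparse
nonnegative vector: one dimension per non-PATHOGENIC `(gene, aa_change)`
with the allele frequency as magnitude. Pathogenic variants are excluded by
design: they change over time with tumor burden, which is precisely the
signal the *longitudinal* stage tracks and the *identity* stage must ignore.
Germline-flagged rows are included — they are the strongest identity signal.

Dimension keys default to `(gene, aa_change)` rather than gene alone: two
patients sharing a mutated gene but carrying different polymorphisms must
not collide on a dimension. A gene-level mode (summing a gene's AFs) is
retained for comparison experiments.

Similarity of two vectors is the cosine of their angle,
$\cos\theta = \frac{v_1 \cdot v_2}{\lVert v_1\rVert\,\lVert v_2\rVert}$,
computed over the union of keys with absent keys contributing 0. It is 1
for same-direction vectors, 0 for disjoint support, symmetric, and invariant
to positive rescaling — so a global shift in sequencing depth or recovery
does not change scores. An empty or zero-norm vector has no direction; its
score is `NA` with a warning, never a silent 0, and such samples are
excluded from matching entirely.

Pairs are banded by score: **MATCH** at $\geq 0.98$ (inclusive — the
threshold itself counts), **AMBIGUOUS** in $[0.95, 0.98)$, else
**NO_MATCH**. The ambiguous band is reported separately for manual review
(close relatives and noisy resequencing of the same patient both live
there) and is never used for grouping.

Scoring all $\binom{n}{2}$ pairs is wasteful at cohort scale, so samples
are first split by k-means (Lloyd's algorithm, $K = 2$ by default) on the
dense matrix spanned by the union of keys. Initial centers come from a
seeded farthest-point sweep (first center drawn with the configured seed,
each next center maximizing the distance to its nearest chosen center, ties
to the first index), making the partition reproducible. Pre-clustering is a
compute optimization, not a semantic one: samples left without a MATCH after
within-cluster scoring are rerun against every sample they have not yet been
scored with, across cluster boundaries (the rescue pass). This exhaustive,
deterministic rescue replaces a reshuffle-and-retry scheme; it is strictly
stronger, and it covers the case where one draw of a patient lands in a
different cluster than its already-matched siblings. On cohorts where
rescue converges, $K=1$ (no pre-clustering) and $K=2$ produce identical
final groups — a property the test suite checks.

Patients are the connected components of the graph whose edges are MATCH
pairs (transitive closure: if A–B and B–C match, {A, B, C} is one patient).
Samples with no MATCH edge become singleton patients. Patient labels are
assigned deterministically — groups ordered by smallest member sample id —
so pipeline output is invariant to input order.

The 0.98/0.95 thresholds are empirical values for a 56-gene panel with
roughly 20 germline markers per sample; they are configuration, not
constants, and transfer to other panels should be re-calibrated on a
labelled subset.

## 4. Longitudinal assembly

Once reports are grouped, each patient's draws are ordered by draw date
when every member has one, else lexicographically by sample id (with a
warning when dates are mixed) — anonymous reports carry no mandated date
field, so the ordering key is a documented convention. Draw indices run
$1..n$.

The default timeline view tracks PATHOGENIC-tier, non-germline series with
the low-AF filter applied. Filters select *series*: a
`(patient, gene, aa_change)` combination enters the view if any draw passes
(germline-free, at or above 1% AF); within a selected series, every draw of
the patient gets a row — the observed AF where detected, an explicit
`allele_frequency = 0` row where not. Without the zero rows, remission
(mutation present, then absent) would be indistinguishable from missing
data in long format. The complete annotated table, with patient and draw
columns attached and no filters, is emitted alongside; the filtered view is
always a subset of the scaffold it spans.

All outputs are CSVs (`export_results()`): annotated variants, per-sample
QC, scored pairs (4-decimal scores), ambiguous pairs, patient groups, and
the two timeline tables. Reruns on identical input and configuration are
byte-identical.

## 5. The synthetic cohort simulator

`generate_cohort()` generates the statistical structure the pipeline
assumes, at configurable scale, so every stage runs offline:

* **Germline profiles.** Each patient draws `n_germline_per_patient`
  (default 20) distinct variants from a pool of syntactically valid
  synthetic protein changes enumerated per panel gene (positions 110–500;
  no real hotspot catalogue is used or needed). A variant is homozygous
  with probability 0.2. Patient-level true AFs are drawn once per patient:
  heterozygous $\mathcal{N}(50, 2.5^2)$, homozygous
  $\mathcal{N}(97, 1.5^2)$, in percent. Profiles are resampled until every
  pair of patients differs in at least 30% of keys — human germline
  genotypes over ~2000 candidate variants are far more distinct than this
  floor.
* **Draws.** Each report re-observes the patient's profile with additive
  per-draw jitter $\mathcal{N}(0, 1.5^2)$ (resequencing noise), clamped to
  $[0, 100]$, plus 5 random low-AF neutral rows (AF uniform on $[1, 8]$
  percent) emulating sub-clonal and artifactual calls that differ between
  draws.
* **Somatic trajectories.** Scenario tables inject a pathogenic mutation at
  exact per-draw VAFs; a draw whose true VAF is below the 1% detection
  floor omits the row entirely — the assay does not call it — rather than
  reporting 0. Two canned scenarios cover the canonical monitoring
  patterns: new detection at the third draw (`scenario_new_detection()`)
  and remission followed by recurrence with a different clone
  (`scenario_remission_recurrence()`).
* **Reference.** The generated reference contains every scenario mutation
  as PATHOGENIC (scores in $[0.85, 0.99]$), plus NEUTRAL entries in
  $[0.5, 0.79]$ and a handful of very-low-score entries, drawn from the
  same synthetic pool so annotated reports exercise all three tiers.

Gaussian noise with clamping was chosen over a Beta-binomial read-count
model for transparency: the downstream pipeline consumes only AFs (read
depth is carried but unused), and the property that matters — same-patient
cosine similarity staying above 0.98 while cross-patient similarity stays
below 0.95 under jitter of a couple of percentage points — is driven by the
geometry of the germline profiles, not by the noise family. The simulator
does **not** model realistic tumor-fraction biology, clonal evolution,
sequencing-error spectra, or related individuals; a passing test suite
therefore demonstrates the pipeline's logic and thresholds under the
assumed germline geometry, not clinical performance on real cohorts, where
relatives and missed germline calls are the known failure modes of
identity matching.

Everything is driven by a single integer seed: the same seed reproduces a
cohort byte-identically, and the per-function RNG state is restored on
exit so the simulator does not perturb a caller's random stream.

## 6. Numerical and scale choices

* Cosine similarity is computed in double precision over shared keys; the
  test suite pins it to a brute-force two-loop oracle at $10^{-12}$.
* Scores are *banded* before any grouping decision, so floating-point noise
  only matters within $\sim 10^{-15}$ of a band edge; band edges themselves
  are inclusive on the left as documented above.
* K-means runs Lloyd's algorithm to convergence (at most 100 iterations) —
  on separable germline profiles it converges in a handful.
* Routine verification (the test suite and the acceptance script) uses
  simulated cohorts of 30 patients × 2 draws (60 reports, the published
  calibration size) over the 56-gene panel, repeated across 10 seeds, plus
  small constructed cohorts for the trajectory scenarios. These sizes
  exercise every code path — clustering, banding, rescue, grouping,
  timelines — while keeping a full run in seconds; the pipeline itself is
  $O(n^2)$ in pairs scored and comfortable at thousands of samples.

## 7. Known limitations

* Identity matching can be confounded by close relatives (high germline
  overlap) and by reports whose germline calls are largely missing; both
  appear in the ambiguous band for manual review rather than being
  resolved automatically.
* Matching keys are protein-level only; joining on nucleotide change is not
  supported (the reference format this emulates is keyed the same way).
* The QC ratio definition is a documented interpretation of an ambiguous
  rule (Section 2); both readings are exposed.
* Draw ordering without dates is lexicographic by sample id — a convention,
  correct only when ids sort chronologically.
* No clinical interpretation: tiers and flags summarize a reference lookup,
  not a treatment recommendation.
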