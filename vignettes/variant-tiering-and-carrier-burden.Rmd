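---
title: "Variant tiering and carrier-burden methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant tiering and carrier-burden methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repaircarrier)
```

# The analysis

`repaircarrier` reproduces a case/control carrier-burden analysis of rare
germline variants in DNA repair genes. The unit of inference is the
*carrier*: an individual with at least one qualifying variant in a gene (or
across the panel). The pipeline has three stages — exome quality control,
rule-based tier classification, and exact carrier association — plus a
synthetic-data generator that creates cohorts with known truth so every
stage can be validated without access to protected sequencing data.

## Quality control

Two filter levels, both consumed from upstream annotations rather than
recomputed from reads:

* **Samples** with less than 30% of target bases covered by at least 20
  reads are excluded with all their calls (`min_frac_bases_20x = 0.30`,
  strict less-than, so a sample at exactly 30% is retained).
* **Calls** are retained iff the upstream variant-quality recalibration
  flag is `PASS`, allele fraction ≥ 0.3, depth ≥ 12, and readPosRankSum is
  absent or strictly greater than −1.7.

The three value filters are applied as one conjunction; the result is
order-independent and idempotent, which the test suite asserts by
property. An **absent readPosRankSum is non-disqualifying**: the
annotation is routinely missing for indel and homozygous calls, and
discarding such calls would eliminate most frameshift variants — the very
class the Tier 1 rule targets. Thresholds are arguments of
`qc_thresholds()`, so sensitivity analyses need no code changes.

## Tier classification

`classify_variants()` applies, in order:

1. **Panel and rarity prefilter** — off-panel genes, intergenic variants,
   and common variants (MAF strictly above 0.01) are `EXCLUDED`. An absent
   MAF never triggers the rarity exclusion: a variant unobserved in the
   reference population is rare, not common.
2. **ClinVar benign precedence** — benign/likely-benign assertions with no
   coexisting pathogenic/likely-pathogenic (P/LP) code force `NEUTRAL`
   regardless of scores. Mixed submitter sets such as `5,4,3` count as
   P/LP: precedence belongs to the damaging assertion when submitters
   disagree, which is the only reading consistent with published variant
   tables that tier `5,3` and `5,4,3` variants as damaging.
3. **Tier 1 (protein-truncating)** — stopgain, frameshift indels and
   splice-altering variants with CADD phred ≥ 20, where ClinVar P/LP or,
   failing that, a protein-domain-disruption flag supports pathogenicity.
   **An absent CADD passes the CADD condition**: CADD phred is typically
   unannotated for indels in upstream pipelines, and requiring it would
   silently drop most frameshifts. Splice variants count as truncating
   even when represented as single-nucleotide substitutions.
4. **Tier 2 (damaging missense)** — missense variants that are ClinVar
   P/LP (scores then irrelevant, including a REVEL below threshold) or
   that reach both CADD ≥ 20 and REVEL ≥ 0.75.
5. Everything else is `NEUTRAL`.

All score comparisons are inclusive (≥) and classification is total and
deterministic; every assignment carries a machine-readable reason
(`TRUNCATING_PLP`, `MISSENSE_SCORES`, `OFF_PANEL`, ...). The
domain-disruption flag is an *input annotation* (UniProt-style domain
lookups are the user's responsibility); absence is treated as `FALSE`.
Thresholds (`max_maf = 0.01`, `min_cadd = 20`, `min_revel = 0.75`) live in
`classifier_thresholds()`.

The packaged 31-variant case table reproduces its published tier labels
with zero mismatches (11 Tier 1, 20 Tier 2); this is asserted in the test
suite.

## Carrier association

Cases and controls are counted differently, by design:

* **Genotyped cohorts**: a carrier is a distinct individual with ≥ 1
  qualifying variant; one man carrying two Tier 1 variants in the same
  gene counts once.
* **Allele-count summaries**: per gene, carriers = Σ allele counts over
  qualifying variants, under the assumption that each individual carries
  at most one deleterious mutation per gene (capped at the denominator).
  The `ALL` row sums per-gene counts, so an individual mutated in two
  different genes could be counted twice — a slight overestimate of the
  control carrier rate, accepted because it is conservative for
  case-enrichment claims.
* **Denominators**: the cohort-level covered-persons value by default;
  when per-variant denominators differ within a gene, the minimum across
  the gene's qualifying variants is used (conservative), and an ambiguous
  `ALL` denominator without an explicit cohort-level value is an error
  rather than a guess.

Each 2×2 table is tested with `fisher_two_sided()`: the exact
hypergeometric two-sided p-value by the minimum-likelihood convention —
the sum of point probabilities of all tables (margins fixed) no more
likely than the observed one, with a relative tie tolerance of `1e-7`.
The implementation is a direct `dhyper()` sum; the test suite verifies it
exhaustively against brute-force enumeration for every table with total
≤ 60 and against `stats::fisher.test()` on random tables. No
multiple-testing adjustment is applied, matching the source analysis;
p-values are reported unrounded, and rendered at 3 decimal places with a
`<0.001` floor (values below 0.0005) only in report output.

`expected_carriers(rate, n) = rate × n` supports back-of-envelope checks
such as the expected 1.1 BRCA2 carriers in 122 cases at a 0.93%
population carrier rate.

A note on the source tables: the study's abstract prints p = 0.030 and
p = 0.040 for two comparisons where its results table and text print
0.003 and 0.004. Recomputing from the printed counts yields 0.003/0.004,
so the package and its tests target the table values; the abstract figures
appear to be transposition errors and are deliberately not reconciled.

# The synthetic-data generator

`simulation_config()` defaults define the emulated study: 122 analyzable
cases, 6192 control persons, the observed per-gene lethal-case carrier
rates (`lethal_case_rates()`, e.g. Tier 1: CHEK2 5/122, ATM 4/122), and a
fraction of low-coverage samples equal to the study's 10-of-192
exclusion. Per individual and gene, carrier status is Bernoulli at the
configured Tier 1/Tier 2 probabilities (at most one qualifying variant
per gene per individual); control allele counts are
Binomial(*N*, rate) split multinomially across catalog variants — one
allele per carrier, mirroring the at-most-one-mutation assumption used in
estimation.

Two design choices matter for interpretation:

* **Intended-tier variants invert the classifier's rules** rather than
  sampling annotations until acceptance: deterministic, fast, and it makes
  the generator–classifier contract test (every intended-tier variant is
  assigned that tier; every noise variant is neutral or excluded)
  meaningful. Noise variants draw CADD uniformly on (5, 45), REVEL on
  (0, 1) and MAF log-uniformly up to 0.05, deliberately straddling every
  classification threshold.
* **Carrier calls are drawn from QC-passing distributions** (allele
  fraction Beta(20, 20) truncated at 0.3, depth Poisson(60) truncated at
  12, readPosRankSum standard normal truncated above −1.7, missing for
  90% of indels). The configured carrier rates are therefore the *post-QC
  truth* the pipeline should recover exactly; QC failures are injected
  separately into noise calls (15%, one failing field each) so the filters
  are still exercised. Had carrier calls been drawn from the untruncated
  distributions, the ~4.5% tail loss from the readPosRankSum filter alone
  would bias every recovery experiment low by construction.

What the generator does **not** emulate: linkage and relatedness,
population structure, per-variant coverage variation in controls,
annotation errors (wrong gene or consequence), and multi-allelic sites.
Passing recovery tests therefore validate the pipeline's bookkeeping and
statistics, not robustness to those real-data complications.

# Calibration experiments and their problem sizes

The acceptance-level tests run three simulation experiments, sized to
keep the default suite near a minute while leaving Monte-Carlo error
small relative to the tested effects:

* **Parameter recovery** — 200 replicate case cohorts (n = 122) at the
  study's six Tier 1 gene rates; pooled recovered carrier counts (over
  24,400 Bernoulli draws per gene) must fall within binomial intervals
  Bonferroni-adjusted across the six genes, giving the family of checks
  95% coverage. Per-gene 95% intervals would fail by chance in roughly a
  quarter of runs for reasons unrelated to correctness.
* **Type-I error** — 1000 replicates of case (n = 122) and control
  (n = 6192) cohorts at an identical 12.3% carrier rate; the rejection
  frequency at α = 0.05 must sit at the nominal level within three
  binomial standard errors (±2.1 points). The band is deliberately three
  SEs, not two: Fisher's exact test is conservative at discrete margins —
  its exact size at this configuration, computed by direct binomial
  enumeration, is 4.1%, not 5% — and the experiment should flag genuine
  miscalibration, not the test's well-known discreteness deficit.
* **Power** — at the study's observed contrast (12.3% vs 1.63%), the
  rejection frequency at α = 0.001 over 200 replicates must exceed 80%,
  consistent with the reported sub-0.001 finding (observed ≈ 97%).

Stochastic tests use seeds fixed in advance; results are reproducible
run-to-run.

# Numerical and I/O choices

* Typeset scientific notation (`2.5 × 10−5`, Unicode multiplication sign
  and minus, optional superscript carets) parses identically to `2.5e-5`;
  `-`, `.` and empty strings are missing values.
* Variant keys follow the 1-based VCF `chrom:pos:ref:alt` convention with
  the genome build as metadata; no left-alignment or liftover is
  performed — inputs are assumed pre-normalized. When coordinates are
  unavailable (as in published variant tables), a stable
  `gene:protein_change` surrogate is used.
* VCF INFO keys are config-mapped (`default_vcf_mapping()`, overridable
  via YAML) rather than hard-coded, because annotation dialects vary.
* The default gene panel ships the 17 genes with damaging case variants
  plus a documented extension list; the full 175-gene analysis panel used
  by the study is not printed anywhere, so faithful reuse on real data
  requires supplying your own panel file.
* Reports round rates to 2 decimals and p-values to 3 with a `<0.001`
  floor; all comparisons in code and tests use unrounded values.

# Known limitations

The classifier is a fixed rule set, not an ACMG engine: it computes no
pathogenicity predictions and resolves no transcript-consequence
ambiguity, trusting its input annotations. Control carrier estimation
inherits the at-most-one-mutation assumption and the `ALL`-row
double-counting caveat described above. The association stage performs no
adjustment for population stratification or other confounding — matching
the analysis it reproduces, which pooled two Nordic case populations
unadjusted — so p-values should be read accordingly.
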