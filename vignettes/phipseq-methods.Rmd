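---
title: "PhIP-Seq autoantibody discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PhIP-Seq autoantibody discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phipseqr)
```

Phage immunoprecipitation sequencing (PhIP-Seq) profiles serum antibody
reactivity against a phage-displayed library of proteome-tiling peptides:
antibodies immunoprecipitate the phage they bind, and sequencing the bound
phage yields a peptide x sample count matrix. `phipseqr` implements the
cohort-level analysis of such screens — background normalization against
bead-only mock immunoprecipitations, Z-scoring against control cohorts,
multi-criterion shared-antigen ("hit") calling, control-cohort downsampling,
and disease classification — together with a fully synthetic cohort
generator so every stage can be verified against known ground truth without
patient sera.

## The enrichment statistics

All statistics are computed at the gene level: peptide counts mapping to the
same gene are summed first (`collapse_to_gene()`), because autoantibody
signal is typically spread across a gene's tiles and validation assays work
with whole proteins.

Given gene-level counts $c_{gs}$ for gene $g$ in sample $s$:

1. **Percent normalization with pseudocount.** A pseudocount of 0.5 reads is
   added to every gene and counts are converted to percentages of each
   sample's total:
   $p_{gs} = 100\,(c_{gs} + 0.5)\big/\sum_{g'}(c_{g's} + 0.5)$.
   The pseudocount keeps every percentage strictly positive so later ratios
   are always defined. It is applied identically to case, control and
   mock-IP samples.

2. **Fold change over mock-IP.** Mock immunoprecipitations (protein A/G
   beads without serum) define the non-specific background. For each gene,
   $\mathrm{FC}_{gs} = p_{gs} \big/ \overline{p}^{\,\mathrm{mock}}_{g}$,
   where $\overline{p}^{\,\mathrm{mock}}_{g}$ is the mean mock-IP percentage.
   FC is a ratio of compositions, so it is invariant to sequencing depth.

3. **Z-scores against the control cohort.** For a case sample,
   $z_{gs} = (\mathrm{FC}_{gs} - \mu_g)/\sigma_g$ with $\mu_g, \sigma_g$ the
   mean and sample (n−1) standard deviation of the controls' FC for that
   gene. Each control is scored against all *other* controls
   (leave-one-out), so no sample contributes to its own reference. The n−1
   standard deviation was chosen for unbiasedness at modest control counts.
   Genes whose reference standard deviation is zero are flagged
   `degenerate_sd` and scored by convention ($z = \infty$ above the
   reference mean, 0 at it): such genes usually indicate a library design
   problem and silently dropping them would hide it.

## Hit criteria

A sample is *positive* for a gene when $z \ge 10$ (inclusive by default and
configurable, since the strict/inclusive distinction is immaterial at these
magnitudes). A gene is a shared candidate antigen when all four of the
following hold (`hit_call_config()` defaults in parentheses):

* **case frequency** — positive in at least 10% of cases;
* **control rarity** — positive controls below the cap; two readings are in
  use and both are exposed: an absolute cap (fewer than 2 positive controls,
  the default, suited to cohorts of tens) and a fractional cap (below 2%,
  suited to cohorts of hundreds);
* **strong positive** — at least one positive case reaches FC ≥ 50;
* **case dominance** — no positive control's FC exceeds the highest case FC.
  "Signal" here is FC, not z, because FC is the quantity compared across
  samples (z would re-use the control distribution twice). The dominance set
  is the *positive* controls by default; `dominance_all_controls = TRUE`
  compares against every control instead — the two differ only for controls
  with high FC but sub-threshold z, which at these thresholds is rare.

The criteria are a conjunction of thresholds, deliberately not a
p-value/FDR procedure; tightening any one threshold can only remove hits.

`downsample_controls()` measures how the apparent-hit count depends on
control cohort size: for each bin size it repeatedly subsamples controls
without replacement and recomputes Z-scores *against the subsample only* —
scoring against the full control set would erase exactly the small-cohort
false-positive inflation the analysis is meant to expose.

## Disease classification

`rpk_transform()` scales each sample to reads per 100,000 and takes
$\log_{10}(\mathrm{rpk} + 1)$; the offset maps zero counts to exactly 0.
`fit_logistic_cv()` fits an L1-penalized logistic regression (glmnet,
warm-started down a lambda path to the target penalty; the inverse
regularization strength C relates to glmnet's lambda as
$\lambda = 1/(nC)$, so the objective matches the conventional
$\sum_i \mathrm{loss}_i + \|w\|_1 / C$). Folds are stratified by class and
seeded; the single reported ROC/AUC pools out-of-fold predicted
probabilities across folds, and coefficients come from a final fit on all
samples. The default C is 1.0; the cohort-scale demonstrations in the test
suite use C = 0.3, which at ~1000 gene features and ~300 samples keeps the
model in the sparse regime (tens of nonzero coefficients) where the antigen
genes dominate the coefficient ranking.

## Radioligand binding assay index

For orthogonal whole-protein validation plates, `antibody_index()`
normalizes each sample's scintillation counts between the plate blanks and
the positive-control antibody:
$(\mathrm{sample} - \overline{\mathrm{blank}}) /
 (\mathrm{positive} - \overline{\mathrm{blank}})$.
Replicate sample wells are averaged before the formula (mean rather than
median; with the usual 2–3 replicates the two differ negligibly and the
mean matches the index's definition as a ratio of expectations), as is the
positive control when several wells are present. The index is affine
invariant in cpm. No positivity threshold is imposed — cutoffs are
antigen-specific and left to the caller.

## The synthetic cohort generator

`simulate_counts()` is a compositional (Dirichlet-multinomial) generator,
chosen because every downstream statistic is compositional — a percent of
total reads — so a compositional model is the faithful null:

1. one background peptide composition is drawn from a symmetric Dirichlet
   (library representation is never uniform);
2. mock-IP samples are multinomial draws from that background;
3. every serum sample perturbs the background with Dirichlet noise at
   concentration `dispersion`, then a Poisson(`private_reactivity_rate`)
   number of *private* genes get all their tiles multiplied by a value from
   `private_multiplier_range` — this models the patient-specific
   autoreactivity spectrum seen in cases **and** controls;
4. disease-shared spike genes are multiplied by their configured factor in
   `round(case_frequency × n_cases)` cases (round-half-up, sampled without
   replacement); frequencies are renormalized and counts drawn.

Everything in (3) and (4) is recorded in a truth table.

### Defaults and what they mean

* `n_genes = 200`, `peptides_per_gene = 4`, 49-aa tiles: desk-scale but
  structurally faithful (tiled genes, gene collapse matters). 49 aa is the
  conventional tile size for proteome-wide display libraries.
* `reads_per_sample = 1e5` (Poisson by default): enough depth that the
  pseudocount is negligible for expressed genes.
* `dispersion = 800`: per-gene Dirichlet concentration ≈ 4 at these library
  shapes, i.e. a gene-level FC coefficient of variation around 0.5. Real
  control cohorts show broad FC distributions (control samples reach 5–100×
  enrichments), which is why hit calling needs z ≥ 10 rather than a small FC
  cutoff; a much quieter background would be unrealistically easy.
* `private_reactivity_rate = 2`, multipliers 5–200: a few strong private
  reactivities per sample, reaching 100× enrichment — the heavy tail that
  makes small control cohorts dangerous.

### Compositional ceilings, expected fold change

Multiplying one gene's frequencies by $m$ inflates the sample total, so the
realized FC is below $m$; with several antigens spiked into the same case
the shrinkage compounds. `expected_spike_fc()` evaluates the first-order
expected FC of a spike design and `spike_multiplier_for_fc()` inverts it
(solving the coupled system across spike genes by fixed point). Designs
whose total enrichment mass feeds back with gain ≥ 1 are rejected as
compositionally infeasible — no multiplier can reach the requested FCs at
the requested frequencies and library size.

One consequence worth knowing: in spiked cases all *other* genes are
compositionally depleted. If the background is nearly noise-free, that
coherent depletion is a better classifier feature than the antigens
themselves, and L1 logistic regression will pick "depletion meter" genes
with negative coefficients. At realistic background dispersion the per-gene
depletion (≈ log of the case's enrichment mass, spread over every gene) sits
below the per-gene noise and the antigens dominate, as they should. This is
why the generator's default dispersion is deliberately broad, and why the
classifier demonstrations use libraries of ≥ 1000 genes, where the per-gene
spike mass is small.

### What the generator does not emulate

Phage amplification cycles, antibody affinity/avidity kinetics, epitope
overlap between homologous genes, batch effects (addressed by protocol, not
computation), sequencing error (reads are emitted error-free and in frame),
and pooled-immunoglobulin (IVIG) contamination. Passing tests on synthetic
cohorts therefore demonstrate the correctness and statistical behaviour of
the *pipeline*, not the biology of any particular cohort.

## Read counting

Synthetic FASTQ reads are reverse-translated with a fixed codon table (the
first codon per amino acid in the standard genetic code's conventional
enumeration) and counted back by exact frame-1 translated-prefix matching,
with an optional amino-acid k-mer fallback. A translated read matching
several peptides equally well is dropped and tallied as ambiguous — never
double-counted — and reads matching nothing (e.g. containing stop codons)
are tallied as unassigned. A general-purpose translated aligner is
deliberately out of scope: the pipeline's computation of record starts at
the count matrix, and the exact matcher guarantees count conservation for
round-trip verification (simulate reads → count → collapse reproduces the
simulated gene matrix exactly).

## Problem sizes used in the test suite

Unit tests run on 50–200-gene cohorts with tens of samples. The
cohort-level demonstrations use: downsampling — 200 genes, 20 cases, 60
controls, bins of 5–50 controls, 10 replicates × 10 seeds; spike recovery —
20 seeds of 10 cases/20 controls with two antigens at 20% frequency and
expected FC 80; classification — one 1000-gene cohort at the study scale of
128 cases and 186 controls with 15 antigens at 10–30% case frequency,
expected FC 80, plus label-permutation nulls. These sizes were chosen so
the full suite runs in well under a minute of simulation time while keeping
every Monte-Carlo margin comfortable.

## Known limitations

* Fold changes for genes with near-zero mock representation are noisy;
  the pseudocount bounds but does not remove this.
* The degenerate-sd convention (z = ∞/0) is deliberately blunt; degenerate
  genes should be audited, not interpreted.
* The downsampling analysis subsamples controls only; case downsampling
  (sensitivity vs case cohort size) is not implemented.
* `simulate_reads()` writes in-frame, error-free reads; the k-mer matcher
  exists for robustness exploration, not as a real aligner.
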