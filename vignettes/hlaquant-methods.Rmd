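---
title: "Methods: SILAC quantification of the HLA Class I immunopeptidome, proteome and interactome"
author: "hlaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SILAC quantification of the HLA Class I immunopeptidome, proteome and interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaquant)
```

# The experimental design this package models

SILAC (stable isotope labeling by amino acids in cell culture) grows one
cell line in light Lys/Arg and an isogenic comparison line in heavy
Lys8/Arg10, mixes the lysates 1:1, and quantifies each peptide species by
its heavy-over-light (H/L) MS1 intensity ratio. Here the heavy channel is
a drug-resistant derivative and the light channel its parental line, so
H/L < 1 means the species is less abundant upon resistance. One such
experiment yields three layers from a single affinity-purification
workflow:

* the **immunopeptidome** — 8–14-mer peptides eluted from HLA Class I
  molecules by mild acid;
* the **whole-cell proteome** — tryptic digest of total lysate;
* the **Class I interactome** — tryptic digest of the proteins co-purified
  with the HLA complex (AP-MS).

`hlaquant` implements the analysis downstream of the database search:
everything that turns peptide/protein intensity tables into normalized
ratios, differential calls, binder predictions, high-confidence
interactors and pathway-level summaries. Raw-spectra processing, search
engines and HLA typing are out of scope; their outputs are the package's
inputs.

# Quantification model

## Channel normalization

Within each replicate, heavy intensities are rescaled by
$\sum L / \sum H$ computed over rows detected in both channels
("total-intensity" or auto normalization). Rows detected in a single
channel are excluded from the factor — their downstream ratios are
conventions rather than measurements and would distort the totals — but
their present channel is rescaled by the same factor so all ratios share
one scale. The operation is idempotent.

## Capped ratios

Species detected only in the heavy channel receive the ratio 256, species
detected only in the light channel 0.01. These conventional values exist
so that one-channel detections — often the most extreme changes — can
participate in differential calls; they are flagged (`capped`) and never
enter t-tests or correlation analyses.

## Replicate aggregation

The summary log2 ratio per feature is the **median** of the replicate
log2 ratios. The median rather than the mean is used because one capped
or outlying replicate should not dominate a three-replicate summary; the
aggregator is permutation-invariant by construction. Significance is a
two-sided one-sample t-test of the uncapped replicate log2 ratios against
zero, computed when at least two uncapped replicates with nonzero
variance exist; otherwise the p-value is absent. Normalization is applied
per replicate (whether the original study normalized per fraction or per
combined run is unstated; per replicate is the conservative reading that
keeps replicates independent).

## Replicate correlation

Pairwise Pearson correlation of log2 ratios over features quantified
without capping in both members of a pair; pairs sharing fewer than three
features are reported absent. On the default synthetic data all pairs
exceed 0.8, the reproducibility bound the design targets.

# Peptidome analyses

The **discovery cascade** counts peptides surviving, in order:
identification; presence of at least one Lys/Arg (only labeled peptides
can be quantified by SILAC); a valid (possibly capped) ratio; length
8–14, the Class I groove range. Counts are monotone non-increasing.

**Differential presentation** partitions quantified peptides at inclusive
fold-change cutoffs: increased at H/L ≥ 2.0, reduced at H/L ≤ 0.5.
Inclusivity at the boundary is a deliberate choice (the convention is
stated nowhere, and fixing it makes behaviour testable); capped ratios
participate, so a heavy-only peptide is "increased". Reported
percentages are integer percentages of the quantified total, rounded
half away from zero — the rounding rule under which all of the pipeline's
summary percentages are reproducible in exact integer arithmetic.

The **global shift** is the five-number summary of the per-peptide log2
ratios, capped values included; a below-zero median is the headline
signature of globally reduced presentation.

# Binder calling: a PWM %rank stand-in

Neural-network MHC binding predictors are external trained models; this
package replaces them with a transparent position-weight-matrix pipeline
whose claim is the *pipeline logic*, not affinity-prediction accuracy.
Precomputed percentile ranks from an external predictor can be
substituted wherever binder calls are consumed.

* **Training**: per-allele epitope lists give position frequencies with a
  background-weighted pseudocount,
  $f_{a,p} = (c_{a,p} + \kappa\,b_a)/(n + \kappa)$ with $\kappa = 1$ by
  default.
* **Scoring**: summed log-odds in bits,
  $s = \sum_p \log_2(f_{r_p,p} / b_{r_p})$.
* **%rank**: the percentage of background scores *strictly greater* than
  the query (ties favor the query; the convention is fixed so tests are
  exact). Backgrounds are sliding windows of the reference proteome,
  deduplicated, sampled with a recorded seed (default 5000 per
  allele/length; at least 1000 keeps the 2% cutoff stable).
* **Classes**: strong at %rank ≤ 2.0 (the conventional strong-binder
  cutoff, taken as stated), weak at ≤ 10, else non. Peptides whose length
  no allele covers are classed non and flagged uncovered.

**Motif comparison** contrasts per-position residue frequencies between a
sample and a reference set as
$z_{a,p} = (f^{s}_{a,p} - f^{r}_{a,p}) / \sqrt{f^{r}_{a,p}(1 -
f^{r}_{a,p})/n_s}$. Reference frequencies are clamped to
$[1/(n_r+20),\; 1 - 1/(n_r+20)]$: the lower floor avoids division by zero
for residues absent from the reference, and the symmetric upper clamp —
this package's choice — avoids the same degeneracy for residues fixed in
the reference.

# Interactome analyses

A protein is a **high-confidence interactor (HCI)** iff identification
FDR < 0.01 (strict), unique peptides ≥ 2 (inclusive), and it is absent
from the contaminant list; contaminants match by accession with a
gene-symbol fallback because common contaminant repositories are
gene-keyed while search output is accession-keyed. The filter is
deterministic, order-independent and idempotent.

Overlap statistics use inclusion–exclusion; known-interactor recovery
reports the integer percentage of a curated known list found among the
HCIs, and the complement as novel interactors.

**Differential interaction** calls increased at H/L ≥ 1.5 and decreased
at ≤ 0.67, *requiring* statistical significance (p < 0.05) for measured
ratios; capped HCIs are called on the ratio alone since no p-value is
computable for them. The significance level is this package's choice —
the calls are described as "statistically significant" changes without a
stated alpha, and 0.05 is the field default.

# Cross-layer integration

* **Peptide vs source protein**: each protein's whole-proteome log2 ratio
  is paired with the median log2 ratio of its presented peptides (median
  over siblings); least-squares slope, Pearson r and its two-sided p are
  reported. Capped values are excluded from all correlation analyses.
* **Proteome vs interactome**: Pearson correlation over shared, uncapped
  accessions.
* **Altered-gene selection**: strict |log2 H/L| > 0.6. Whether the
  original selection also demanded a significance filter is unstated; the
  magnitude-only rule is used, and the enrichment universe is all genes
  quantified in the relevant layer (standard over-representation
  practice).
* **Enrichment**: upper-tail hypergeometric $P(X \ge k)$ per gene set,
  Benjamini–Hochberg adjustment across sets (the adjustment method is
  unnamed in the convention this follows; BH is the field default for
  "adjusted p < 0.05").
* **Activation z-score**: proprietary knowledge-base scores are replaced
  by a sign-concordance statistic: over the $m$ set genes passing the
  altered cutoff and carrying an annotated expected direction
  ($d_g = \pm 1$), $z = \sum_g \mathrm{sign}(\log_2 r_g)\, d_g / \sqrt m$,
  bounded by $\pm\sqrt m$; positive means net activation in the heavy
  condition. This is documented as a stand-in, not a claim of equivalence
  with any commercial tool.

# The synthetic-data generator

`generate_experiment()` produces a complete experiment with planted
truth. Its defaults *are* the study conditions the package targets: 1217
identified peptides, three replicates, 9-mer-dominant length weights
(45% 9-mers), 62% Lys/Arg-containing peptides (between the two cell
lines' observed 65% and 61%), a planted global log2 downshift of −0.5,
54% reduced and 5% increased quantified peptides, a 5000-protein
proteome, a 600-row interactome with 10% contaminant rows, sub-threshold
identifications, 10% + 10% planted differential interactors, and a
407-entry known-interactor list with 161 entries inside the planted HCI
set.

Key design choices:

* **Intensity model**: per-feature base abundance is log-normal
  (log2 ~ Normal(21, 1.5) for peptides); per replicate, heavy = light ×
  planted ratio × noise, with log2-noise SD 0.2 per channel draw. The
  noise level is chosen so that replicate Pearson correlations exceed
  0.8, the only quantitative reproducibility constraint available.
* **Channel-sum balance**: total-intensity normalization forces
  $\sum H = \sum L$; a generator that planted a global downshift in every
  peptide equally would see that downshift erased by its own
  normalization step. The generator therefore rescales the *rows* with
  planted ratio > 1 (both channels, so no ratio changes) until the
  channel sums balance per replicate. In real data this balance is
  supplied by the dominance of a few highly abundant species; here it is
  made exact. When a configuration has no up-shifted rows the balance is
  impossible and the generator warns.
* **Label consistency**: planted "unchanged" effects are clamped away
  from the calling cutoffs (peptides to |log2| ≤ 0.8 against cutoffs at
  ±1; interactors to |log2| ≤ 0.45 against 0.585) so planted labels are
  consistent with planted ratios, as the truth contract requires.
  Planted differential interactor magnitudes are drawn from |log2| in
  [0.9, 1.5]: below ~0.8 the three-replicate t-test lacks the power
  (closed-form noncentral-t power < 0.95 at noise 0.2) for the
  significance-gated calls to recover the planted fractions.
* **Sequences**: peptides are sampled from fixed anchor-constrained
  synthetic allele PWMs (hydrophobic anchors at position 2 and the
  C-terminus, so Lys/Arg are depleted at anchors), the Lys/Arg content is
  enforced per-peptide at non-anchor positions, and every peptide is
  implanted verbatim into its source protein so the mapping is
  verifiable by string search.
* **One-channel species** are encoded as absent (not zero) intensities,
  distinguishing "not detected" from a measured zero; they are drawn
  from the planted reduced/increased pools so their capped calls agree
  with their labels.
* **Cross-layer regimes**: peptide ratios are planted independently of
  the proteome (the no-correlation regime), while unchanged interactors
  track their protein's proteome fold change plus independent noise (the
  positive-correlation regime).

What the generator deliberately does **not** emulate: spectra, retention
time, charge states, isotope envelopes or fractionation; peptide lengths
outside 8–14 (the length weights cover 8..14 only, so the last cascade
stage removes nothing on synthetic data); intensity-dependent noise or
missingness; real allele motifs. Tests passing on synthetic data
therefore validate the pipeline's logic and statistics, not its behavior
on real instrument artifacts.

# Numerical conventions and problem sizes

Integer percentages round half away from zero and are computed in exact
integer arithmetic when inputs are whole numbers. Percentile-rank ties
resolve in the query's favor. All randomness flows through explicit
seeds (the generator's configuration seed; a recorded seed per %rank
background draw), making every analysis byte-reproducible.

The test suite exercises generated experiments of 400–2000 peptides,
600–2500 proteins and 300–600 interactome rows with three replicates —
sizes at which the planted-fraction recovery tolerances (±3–4 percentage
points) are comfortably above binomial noise while the whole suite runs
in well under a minute per file. `scripts/acceptance.R` runs the full
default-scale experiment.

# Interfaces

The exported functions are the package's interface; the pipeline is
driven either programmatically (`pipeline_config()` + `run_pipeline()`)
or from a YAML file (`read_pipeline_config()`), and
`scripts/acceptance.R` is the reproducible end-to-end entry point. Every
threshold is a named, overridable configuration key with the
conventional value as default.

# Known limitations

* The PWM %rank binder stand-in shares none of the training data of
  neural predictors; absolute sensitivities are meaningful only against
  the package's own synthetic motifs.
* The activation z-score is a sign-concordance summary; it ignores
  effect magnitudes and gene–gene correlation.
* The generator's planted fractions are recovered within tolerance only
  when effect sizes clear the calling cutoffs by more than the
  replicate-noise scale, which is by design: recovery under weaker
  effects is a power question, not a correctness question.
* A single experiment models one cell-line pair; two-pair comparisons
  (HCI overlap between lines) are supported by running the pipeline
  twice and comparing HCI sets with `overlap_stats()`.
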