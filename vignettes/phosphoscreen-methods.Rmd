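---
title: "Methods: phosphosite processing, differential calling, and the reversal screen"
author: "phosphoScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphosite processing, differential calling, and the reversal screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoScreen)
```

# The data model

The central object is a `PhosphoExperiment`, a `SummarizedExperiment`
holding one row per phosphosite × multiplicity state and one column per
sample. A *phosphosite* is a specific S/T/Y residue of a protein; the
*multiplicity* state (`"1"`, `"2"`, `"3+"`) records how many phosphate
groups the quantified peptide form carried — MaxQuant exports these as
`___1/___2/___3` intensity column suffixes, and the reader expands each
file row into one record per state that carries at least one quantified
value. Intensities are stored with `NA` for missing; a zero in the input
is read as missing because MaxQuant writes 0 for unquantified sites, and
a 0 taken at face value would corrupt both the valid-value filter and any
mean-based imputation.

Gene symbols (uppercased) are the join key between the site table, the
gene-set annotations, and the PPI edge list: published reversal tables and
STRING flat files both speak symbols, so matching anywhere else would need
an identifier-mapping service the pipeline deliberately avoids.

# Site processing

The processing chain and its parameters (`processingParams()`):

| stage | rule | default | rationale |
|---|---|---|---|
| class-I filter | localization probability ≥ `minLocProb` AND delta score ≥ `minDeltaScore` | 0.75 / 8 | the conventional class-I definition: the phosphate is confidently placed on the reported residue rather than a neighbouring S/T/Y |
| valid-value filter | observed fraction ≥ `minValidFraction` in ≥ 1 group | 0.5 | keeps sites quantifiable in at least one condition; with 3 replicates this means 2 of 3 (1/3 fails, 2/3 passes — the comparison is on fractions, not counts) |
| log2 | log2 of observed cells | on | intensities are treated as log-normal |
| median normalization | per sample subtract the sample median, add back the grand median of the pre-normalization medians | on | removes per-sample loading differences while preserving overall location; after one pass all sample medians agree to 1e-9, and a second pass is the identity |
| group-mean imputation | missing cell filled with its group's mean of observed values, only when the group retains ≥ `minValidFraction` observed | on | a group with 1 of 3 values observed gives no defensible central value, so such cells stay missing |

All thresholds are inclusive (≥). Stage order is configurable via
`stageOrder`; the default runs imputation **last, on the normalized log2
scale**. Imputing on the raw scale would fill cells with arithmetic means
dominated by the highest replicate (the raw distribution is heavily
right-skewed), and imputing before normalization would bake per-sample
loading offsets into the filled values. The alternative order — valid-value
filter, impute on raw scale, then filter/normalize/log — is expressible
with `stageOrder` for users who want to reproduce that convention.

Degenerate inputs are handled explicitly: a filter may legitimately empty
the table (warning, not error); a sample with zero observed values cannot
be median-normalized and raises an error naming the sample; log2 refuses
non-positive observed values (zeros are already missing by construction).

# Differential sites

For a contrast N/D, `computeContrast()` reports per site the fold change
`log2FC = mean(N) − mean(D)` on the log2 scale, a two-sided two-sample
t-test p-value, and a call in {up, down, ns} requiring both
`|log2FC| ≥ minAbsLog2FC` (default log2 1.5) and `p < maxP` (default
0.05, raw). These cutoffs are the field-standard pairing for a
fold-change + t-test screen and are fully configurable; no multiplicity
correction is applied by default (a BH option exists, in which case the
adjusted p gates significance).

**Choice of t-test.** The default is Student's pooled-variance test. With
n = 3 per group — the study size this pipeline targets — the
Welch-Satterthwaite approximation is markedly conservative: its estimated
degrees of freedom fall below the pooled 4, and a Monte Carlo check at
n = 3/3 with equal variances puts its type-I rate near 0.036 at the
nominal 0.05, while the pooled test sits at the nominal level. The
package's null-calibration test (10,000 simulated null sites through the
full pipeline) asserts that the realized false-positive fraction lies
within 3 binomial standard errors of 0.05, which the pooled test
satisfies. Welch remains available (`test = "welch"`) for designs with
real variance heterogeneity and larger n.

Sites with fewer than two observed values in either group are reported
with `p = NA` and `call = "ns"` rather than dropped, so row accounting is
preserved across the pipeline. A site with zero variance and zero
difference yields `t = 0/0` and is `ns`; a zero-variance nonzero
difference yields `p = 0` and is called.

# Enrichment

`fisherEnrichment()` computes the one-sided hypergeometric upper-tail
p-value P(X ≥ k) for drawing k set members in a foreground of n from a
universe of N containing K members, via `phyper(k − 1, K, N − K, n,
lower.tail = FALSE)`; `k = 0` gives p = 1 because the upper tail includes
zero. The test-suite oracle is an independent exhaustive enumeration over
all achievable overlaps using binomial coefficients, checked to 1e-12 on
random universes with N ≤ 50.

Design choices: the background universe is the set of proteins quantified
after processing (not the whole proteome) — the standard choice that asks
"among what we could have seen, is this set over-represented?" — and is
overridable by passing any universe. The foreground for a contrast is the
set of proteins carrying at least one significant site; a protein with
both up and down sites counts once. Ranking is by p ascending, then
enrichment score `(k/n)/(K/N)` descending, then set id — a total,
deterministic order, so "top 20" is well defined even under ties.

# The reversal screen

A protein is *reversed* when it has a significant site in one direction
in the disease contrast (H/C) and a significant site in the opposite
direction in a treatment contrast (S/H or E/H). Matching is at the
**protein level by default**: disease and treatment typically regulate
different positions of the same protein (a calcium-channel subunit may
lose phosphorylation at one serine with disease while treatment increases
it at another), so insisting on the same site would miss exactly the
biology the screen exists for. A strict same-site mode
(`mode = "site"`, identical protein/position/multiplicity) is provided.

Classification: only Down→Up evidence gives class `down_up`; only
Up→Down gives `up_down`; distinct site pairs supporting both patterns
give `mixed` (a single pair can never be mixed). Swapping the two input
contrasts maps `down_up` ↔ `up_down` and fixes `mixed` — an antisymmetry
the test suite asserts on fuzzed tables against a brute-force double loop
over all site pairs.

Hits are then restricted to proteins belonging to at least one of the
top-20 KEGG pathways. Which contrast's top-20 applies is genuinely open;
the pipeline defaults to the **union** of the disease and the treatment
top-20 (configurable to either alone), on the argument that a pathway
prominent in either contrast is a legitimate context for a reversal.
Because both differential tables must describe the same processed data,
each carries a provenance token of its processing history and the screen
refuses mismatched tables.

# PPI subnetworks

Edges are canonicalized on input (undirected, self-loops dropped,
duplicates collapsed to the maximum confidence, milli-scaled STRING
scores divided by 1000), filtered at combined-score ≥ 0.7 (inclusive),
and induced on the hit proteins. Isolated nodes are retained and flagged
— a reversal hit with no high-confidence interactions is still a hit.
Components come from `igraph`; the test oracle is a hand-written flood
fill. The score in the input file is assumed to be the STRING combined
score; channel subscores are outside scope. Hubs are ranked by degree
with a lexicographic tie-break.

# The synthetic-data generator

`simulateStudy()` emulates the study conditions the pipeline targets:
4 groups × 3 biological replicates; 21,239 sites on 4,290 proteins;
S/T/Y composition 82.76 / 16.12 / 1.12%; multiplicity classes in
proportion 17,003 : 2,824 : 571 : 95 (the two largest classes collapse to
`"3+"` in the site table, matching what the `___3` column can express).

On the log2 scale an intensity is
`protein baseline + site offset + group effect + replicate noise`, with
defaults N(23, 2²) for baselines, N(0, 1) site offsets, and N(0, 0.3²)
replicate noise — a log-normal LFQ model, which is exactly what the
log2 / median-normalization chain presumes. The group effect is ±1.5 log2
units in H (vs C) for a spiked fraction of sites (6% by default);
reversal proteins carry **two** spiked sites whose effect is returned to
the C level in S and/or E, so the treatment-vs-H contrast shows the
opposite significant direction. Two sites per reversal protein reflects
how reversed proteins present in practice (multiple regulated positions)
and makes protein-level recovery robust to a single site dropping out to
missingness. Mixed-class proteins (up to `nMixedProteins` per treatment)
get discordant signs on their two sites.

Missingness is `rate × ((1 − w) + 2w(1 − u))` where `u` is the cell's
intensity percentile and `w` the MNAR weight (defaults 0.2 and 0.8): the
expected rate is `rate` regardless of `w`, while `w > 0` concentrates
missingness at low intensity, reproducing the left-censoring of real LFQ
data (the observed-value mean exceeds the all-value mean — a property the
tests assert).

Identifiability choices, made as generator design and not revisited:
spiked sites receive class-I localization probabilities and delta scores,
and reversal proteins are drawn from the upper half of the abundance
distribution among proteins with ≥ 2 sites — recovery is only a
meaningful quantity for signal the confidence filters are designed to
keep; spiking un-localizable or barely-detected sites would measure the
filters, not the screen. Localization probabilities are Beta(6, 1)
(about 18% below 0.75) and delta scores Gamma(shape 2, scale 15) (about
10% below 8), so the class-I filter has real work to do on the null
background. One designated target pathway per treatment is packed with
reversal proteins (60% of the set by default) and high-confidence edges
are oversampled within target sets, giving enrichment ranking and
subnetwork extraction known answers.

What the generator does **not** emulate: peptide identification,
retention-time or ion-mobility structure, shared-peptide ambiguity,
batch effects, and correlated site effects beyond the within-protein
reversal constraint. Passing recovery tests therefore demonstrates the
pipeline's statistical machinery under its own model assumptions, not
performance on any particular real dataset.

# Problem sizes and determinism

The test suite and the acceptance script use: the full default study
(21,239 sites) for spiked-recovery and enrichment-rank checks; 10,000
sites for the null calibration (chosen with `missingRate = 0` so the
calibration measures the test itself rather than the interaction of
missingness and imputation); ≤ 200 sites for brute-force reversal
oracles and ≤ 50 nodes for flood-fill graph oracles; N ≤ 50 for
exhaustive hypergeometric enumeration. Every stochastic step flows from a
single integer seed; the same seed reproduces every table bit-identically,
and `runPipeline()` with a fixed config is a pure function.

# Known limitations

* No moderated-variance (empirical Bayes) test; with n = 3 a
  limma-style approach would gain power, but the package implements the
  plain fold-change + t-test criterion it documents.
* No alternative imputation (kNN, MinProb); group means shrink
  within-group variance, which is why imputation is last in the default
  stage order and why untestable sites are reported rather than forced
  through.
* GO annotations are used as flat sets; no DAG propagation.
* The identifier namespace is uppercase gene symbols; cross-species or
  isoform-resolved work needs pre-mapped inputs.
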