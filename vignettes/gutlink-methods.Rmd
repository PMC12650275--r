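---
title: "gutlink: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gutlink: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gutlink analyses the data produced by a typical diet-intervention trial
in an aquaculture or nutrition setting: a handful of treatment groups
with few biological replicates, one 16S amplicon ASV table across all
animals, a panel of host traits (biochemistry, histomorphometry,
relative gene expression), and qPCR Ct values. This vignette explains
the statistical machinery stage by stage, the tunable parameters and
their defaults, what the bundled synthetic generator does and does not
emulate, and the numerical and design choices made where more than one
defensible option existed.

## The data model

An `asv_table` holds a non-negative integer count matrix (samples x
ASVs) and a sample-to-group factor. Taxonomy travels separately as a
seven-rank data frame. Phenotypes are a numeric samples x traits matrix
whose columns carry a category tag ("Gut health" or "Gut development").
Ct tables bundle the Ct matrix with per-gene primer efficiencies, the
reference gene, and the calibrator group.

## Synthetic trials with planted ground truth

`generate_asv_table()` draws counts from a lognormal-latent /
multinomial-sampling model:

* each ASV gets a baseline log abundance `mu ~ N(0, 2)` and an occupancy
  probability `~ Beta(0.4, 1.2)`, so most ASVs are absent from most
  samples — the hallmark sparsity of 16S tables;
* per-sample read totals are Poisson around `depth_mean` (default
  33,000, a realistic per-sample yield for this trial size), and cells
  are one multinomial draw per sample, which preserves the compositional
  coupling real tables have;
* planted differential ASVs receive a `planted_log2fc` shift (default 3,
  alternating signs) in their contrast group. Their baselines are drawn
  from `N(1, 1)` and their occupancy forced to 1: an effect planted on a
  taxon below the detection floor of the sequencing depth would be
  unmeasurable by any method, so planted signal is kept observable by
  construction;
* planted module ASVs share a per-sample latent factor. With more than
  one module the factors are orthogonalized in-sample: planted modules
  are distinct by design, and at 12 samples a chance correlation between
  two raw Gaussian factors would otherwise leak one module's signal into
  another's phenotype block;
* taxonomy assigns phyla from `phylum_weights` (defaults dominated by
  Proteobacteria, Actinobacteria, Chloroflexi, Firmicutes and
  Fusobacteria, the usual freshwater-fish gut profile).

`generate_phenotypes()` emits a 26-trait panel (6 biochemical, 3
histological, 17 gene-expression traits). Traits of a linked block equal
`r f + sqrt(1 - r^2) eps` against their module's factor
(`r = module_phenotype_r`); all remaining traits carry independent
random group effects plus unit noise — so group structure exists in the
phenotype panel whether or not a microbial link does.
`generate_ct_table()` gives the reference gene a group-invariant
expected Ct, target genes baselines in 22–28 cycles, optional planted
log2 fold changes (one Ct cycle per doubling), and efficiencies uniform
in 85–115%.

What the generator does **not** emulate: taxon-specific phylogenetic
signal, chimeras or sequencing error (it starts at the denoised-table
level), overdispersion beyond the lognormal latent layer, and real
taxon identities. Tests passing on synthetic data therefore demonstrate
that the algorithms recover the structure they claim to recover under a
realistic sparsity/depth regime — not that any particular biological
claim holds in real data.

All generator randomness flows from explicit seeds; no function touches
the global RNG state without restoring it.

## Community profiles

Rarefaction is multivariate-hypergeometric subsampling (without
replacement, via `vegan::rrarefy` under a fixed seed) to a uniform
depth; samples below the target are dropped, never up-sampled, and the
default depth is the minimum sample total. Shannon diversity uses the
natural log (configurable). The group partition report pools counts
within each group and calls an ASV "observed" at pooled count > 0 — the
convention UpSet plots of pooled groups imply; percentage shares are
totals over the summed totals, to 2 decimals. PCoA is classical scaling
(`stats::cmdscale`); negative eigenvalues (Bray–Curtis is a semi-metric)
are dropped from the variance denominator with a message rather than
corrected, the simplest defensible treatment.

## Group statistics

`gate_and_compare()` reproduces the two-branch testing convention:
Shapiro–Wilk per group and Levene (center = mean) across groups at
alpha = 0.05 gate into one-way ANOVA + Tukey HSD; otherwise
Kruskal–Wallis + Dunn's tests with tie-corrected z statistics and
Bonferroni adjustment (Holm and none available). At n = 3 per group the
normality gate has little power; it is applied anyway because it is the
field's stated procedure, and groups where Shapiro–Wilk cannot run
(n < 3, constant values) route to the nonparametric branch. Fully
degenerate input (zero variance overall) short-circuits to omnibus
p = 1 with all letters "a". Letters come from the insert-and-absorb
compact-letter algorithm, lettered alphabetically from the highest group
mean; the suite verifies the display invariant (two groups share a
letter iff their pairwise p >= 0.05).

`2^-ΔΔCt` follows the Livak convention with an arithmetic mean of the
calibrator ΔCt, so the calibrator group's geometric mean expression is
1 by construction. The 90–110% efficiency gate is inclusive and
advisory (a warning, not a filter).

## Differential ASV screen

Per ASV, an ordinary linear model of `log2(relative abundance +
pseudocount)` on the group indicator; with two groups this *is* the
pooled-variance t-test, and it is computed in that closed form,
vectorized (the suite checks the algebraic identity against `lm()`).
The pseudocount defaults to half the smallest nonzero relative
abundance — scale-aware and standard for log-ratio screens. "Fold
change > 1" is read on the log2 scale (`|log2 FC| > 1`, i.e. >2-fold);
a `fc_scale = "ratio"` argument offers the literal-ratio reading. No
multiple-testing correction is applied by default, mirroring the
raw-threshold convention; `adjust = "BH"` is available. ASVs with all
zeros in both groups are excluded; all-equal values yield p = 1 rather
than an error. Measured on null simulations the screen's type-I error is
~0.025 — conservative, because sparse ASVs produce many
low-information tests.

## Module mining and phenotype linking

The differential ASV set (union across contrasts in the pipeline) feeds
a signed Spearman adjacency at `|rho| >= 0.7`, with a sensitivity rebuild
at 0.8. Modules come from greedy modularity maximization on absolute
weights — deterministic under the stable node order, with seeded Louvain
as an alternative — and modules below `min_size` pool into "unassigned".
A module eigenvector is the first principal component of the
column-standardized member submatrix, sign-oriented so its mean
correlation with members is non-negative; phenotype trait blocks come
from average-linkage clustering on `1 - |rho|` cut at `n_blocks`, each
summarized by the same eigengene construction and labelled by majority
category.

Links are assessed two ways per (module, block) pair and reported side
by side: a Mantel test (Spearman flavor) between the Euclidean distance
matrices of the two eigenvectors, permutation p with
`(1 + #{r* >= r}) / (1 + B)` and exact enumeration available for n <= 7;
and the direct Spearman correlation of the scores. A pair is flagged
significant only when **both** views pass `|r| > 0.3` and `p < 0.05` —
the correlation magnitude threshold applied to `|r|` so that strong
negative links count. Biomarkers within a significant module are its
members ranked by `|cor(member, eigenvector)|`, the module-membership
convention.

**A calibration caveat that matters.** With 3 module eigenvectors, 10
phenotype eigengenes and 12 samples, 30 pairs are tested at a fixed
per-pair threshold. Even under the dual-view conjunction the measured
joint false-link probability is ~1.2% per pair, so the chance of at
least one spurious link per experiment is ~30%. Requiring an experiment
to report *exactly* the planted link therefore succeeds in only
~60–85% of runs, and no per-pair rule at these thresholds can push that
above ~90% without multiplicity control (Bonferroni-level alpha ~0.004),
which the field's convention — and this package's default — does not
apply. Practically: treat a single strong link as credible, but treat
the *absence of any other* link as uncertain at this design size, and
prefer the biomarker robustness check (persistence across the 0.7/0.8
thresholds) over the raw link count.

## Ecological networks

The whole-community network uses a correlation threshold chosen either
as the fixed conventional value 0.995 (default, for reproducibility) or
by an RMT-style scan: at each candidate, eigenvalue nearest-neighbour
spacings of the thresholded matrix (degeneracies collapsed, spline
unfolding) are chi-square-tested against the unit exponential, and the
smallest Poisson-consistent candidate wins. Topology reports the
standard panel; the clustering coefficient is the unweighted local
coefficient with degree < 2 nodes contributing zero, modularity comes
from the greedy partition on absolute weights, module count ignores
singleton communities, and mean path distance averages over connected
pairs only (the networks are fragmented). The null model is
degree-preserving double-edge-swap rewiring (10 swaps per edge per
randomization, 100 randomizations by default), with an Erdős–Rényi
fallback when the graph is too small to rewire. Cross-group module
preservation uses a one-sided Fisher exact test (overlap enrichment
against the union node universe); similar pairs merge into clusters by
transitive closure and the retained percentage is similar/total pairs.

## Neutral community model

The Sloan fit predicts a taxon's occurrence frequency from its mean
relative abundance `p`: `F(p) = 1 - pbeta(d, Nm p, Nm (1 - p))` with
detection limit `d = 1/N` at mean depth `N`. `Nm` is fitted by least
squares on the frequency scale over `Nm in [1, 1e6]` (log-scale bounded
search), `R² = 1 - SSE/SST` may be negative for poor fits, and the 95%
band is the Wilson interval of the predicted frequency at the sample
count. `simulate_ncm()` draws a lognormal metacommunity and
Beta-distributed local abundances per the Sloan stationary
distribution, giving the self-consistency oracle: fits on its output
recover `Nm` within ~25% and `R² >= 0.6`, while planted-deterministic
communities from the trial generator fit poorly — the qualitative
contrast between stochastic and deterministic assembly.

## Functional projection

A deliberately minimal Tax4Fun-style stage: pathway abundance is the
matrix product of relative abundances with a user-supplied non-negative
taxon-to-KO weight matrix, renormalized per sample, with unmapped mass
reported as coverage. Reference databases are inputs, not bundled; a
small synthetic mapping ships in the tests. Only pathways whose KO1
ancestor is "Metabolism" survive the filter, and per-pathway group
differences reuse the gated comparison with the conventional star
cutpoints (0.05 / 0.01 / 0.001).

## Pipeline and reproducibility

`run_pipeline()` chains profiles → group statistics → differential
screen → linking (on the differential union set) → whole-community
network → neutral model → optional functional projection, writing one
artifact per stage plus an md5 manifest; a rerun with the same config
reproduces every checksum. Stage failures abort with the stage name. At
the strict 0.995 threshold a 12-sample Spearman network can be empty;
the pipeline records that as a result rather than failing.

## Problem sizes

The test suite and the acceptance script run the full trial size (1,500
ASVs, 4 x 3 samples, ~33,000 reads per sample) for single-table
operations, and scale repetition counts to what the properties need:
20–25 seeds for recovery rates, 50 for type-I calibration, 200 for the
Mantel uniformity check, 100 randomizations for network nulls in
analyses and 20–50 in tests. These sizes were chosen to give stable
estimates of the rates being asserted.

## Known limitations

* The linking stage's false-link behaviour at small n, discussed above.
* The differential screen is a log-linear model on relative abundances,
  not a count model; it ignores compositional bias and will inherit
  spurious shifts when a large fraction of the community genuinely
  changes.
* The normality gate is nearly powerless at n = 3; the parametric branch
  is chosen for almost all well-behaved data at that size.
* The RMT scan needs a reasonably rich spectrum (>= 20 distinct
  eigenvalues after thresholding) to assess a candidate; small matrices
  fall back to the fixed threshold.
* Phylogenetic methods (UniFrac, tree building) are out of scope; the
  pipeline starts from a finished ASV table and taxonomy.
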