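---
title: "Methods: consensus differential expression and likelihood cell typing for snRNA-seq cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus differential expression and likelihood cell typing for snRNA-seq cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model of the data

`snconsensus` implements the computational core of a stratified case/control
single-nucleus RNA-seq (snRNA-seq) analysis, of the kind used to study
postmortem human substantia nigra under crossed disease conditions — here,
substance-use-disorder status (SUD+/−) crossed with HIV level (HIV−, HIV+u
with undetectable final viral load, HIV+d with detectable viral load),
giving six donor groups. The observed data are sparse nucleus × gene
integer count matrices with donor, library and (eventually) cell-type
annotations, plus a donor covariate table.

Counts are modeled throughout as negative binomial (NB) with
mean–dispersion parameterization: a gene with mean $\mu$ and dispersion
$\alpha$ has variance $\mu + \alpha\mu^2$. This is the standard
overdispersed count model for UMI data and is shared between the synthetic
cohort generator and the differential-expression engine, so that every
recovery test exercises the same distributional assumptions the estimator
makes.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure every downstream
stage relies on, with ground-truth labels for recovery testing:

* **Cohort shape.** Defaults mirror the motivating study: six donor groups
  with 13/15/10/20/7/25 donors (90 total), a nominal 1,000 nuclei per
  donor, and 12 cell types dominated by oligodendrocytes (55%), with
  oligodendrocyte precursors, microglia, astrocytes, dopaminergic and
  GABAergic neurons, vasculature and immune types making up the rest.
  Tests and examples run deliberately scaled-down configurations (tens of
  donors, 20–200 nuclei per donor, a few hundred genes); the generator is
  the same code at every scale.
* **Baseline expression.** Per-gene mean counts are lognormal
  (`meanlog = log(0.2)`, `sdlog = 1.2`), giving the heavy-tailed mean
  distribution and high sparsity typical of nuclear UMI data. Library
  size varies per nucleus as a lognormal factor (`sigma = 0.35`).
* **Markers.** Each cell type carries a disjoint set of positive marker
  genes (default 5) overexpressed by `marker_l2fc` (default 2, log2 units)
  in their own type.
* **Mitochondrial content.** A configurable number of `MT-`-prefixed genes
  (default 13, matching the human mitochondrial protein-coding gene count)
  receive a shared per-nucleus lognormal "mitochondrial load" factor, so
  the QC mitochondrial fraction has a realistic right tail.
* **Planted differential expression.** A planted DEG multiplies the mean
  of one gene, in one cell type, for donors of one group, by
  $2^{\mathrm{l2fc}}$. Planted DEGs accept an explicit baseline mean
  (default 1 count/nucleus in the test fixtures): a differential effect
  planted on a never-expressed gene is unrecoverable by any method and
  unrepresentative of reported DEGs, so the planted baseline is part of
  the declared study conditions rather than a random draw.
* **Coordination blocks.** A block of genes shares a donor-level latent
  factor $f_d \sim N(0, \sigma_f^2)$ entering multiplicatively as
  $2^{f_d \cdot \text{loading}}$, keeping counts non-negative and effect
  sizes interpretable in log2 units. Raw factors are drawn independently
  per block and then decorrelated in-sample (Gram–Schmidt within each
  donor group, rescaled to the block's factor SD). Without this step,
  chance correlation between two "independent" 24-donor factor vectors is
  regularly large enough (|r| ≈ 0.5) that two planted blocks are genuinely
  coordinated in that realization, making the ground-truth labels wrong
  rather than the recovery hard. In-sample orthogonalization makes block
  independence true by construction at any donor count.

What the generator does **not** emulate: ambient RNA, doublets,
batch-specific expression artifacts beyond a per-library label, zero
inflation beyond NB sparsity, and gene–gene correlation within a nucleus.
Passing recovery tests therefore demonstrate correctness of the
estimators under the declared model, not robustness to artifacts that the
upstream tools (demultiplexing, ambient-RNA and doublet removal) are
assumed to have handled.

# Quality control

`compute_qc_metrics()` computes, per nucleus, the mitochondrial UMI
fraction, detected genes, and total UMIs; `tail_filter()` removes nuclei
in the **upper** tails only, with cutoffs set at empirical quantiles of
the combined dataset (defaults: top 10% mitochondrial fraction, top 5%
genes/nucleus, top 5% UMIs/nucleus). The quantile is the linear
interpolation (type 7) estimate and removal requires strictly exceeding
the cutoff, so boundary nuclei are kept. There is deliberately no
lower-tail gene filter: nigral neurons and some immune cells genuinely
express fewer genes per nucleus, and low-count data are instead excluded
cell-type-wise during differential expression.

# Dimensionality reduction and back-projection

`rank_hvgs()` ranks genes by standardized variance: a loess trend (span
0.3) of log10 variance on log10 mean over expressed genes, standardization
of counts by the trend-predicted SD with clipping at $\sqrt{n}$, and
ranking by the variance of the clipped values. The span is the
convention of the standardized-variance ("vst") method; the method itself
only prescribes a smooth trend. `marker_retention_curve()` reports how
many marker-database genes are retained as a function of HVG count and
suggests the elbow (maximum perpendicular distance from the chord); the
retained HVG count is always an explicit configuration choice, the elbow
being advisory.

`scale_and_pca()` zero-centers and unit-scales each HVG **without value
capping** and stores the scaling means and SDs together with the PCA
loadings, because the whole point is to return to count space later.
`apply_batch_correction()` is a hook with identity default and a simple
per-batch mean-centering alternative; any function with the same
signature can be plugged in. The package does not reimplement mixture
based correctors; the hook exists so the pipeline's contract (corrected
embedding in, corrected counts out) is testable.

`backproject_counts()` reverses the transform per gene: project back
through the loadings; set the lowest 1% of each gene's corrected
distribution (≤ its 1st percentile) to the scaled zero-count value; shift
the distribution so its minimum matches the uncorrected counterpart;
rescale; clamp residual negatives at zero; truncate toward zero to
integers. Two numerical choices matter here. First, "zeroing" assigns the
*scaled value of a zero count*, not literal zero in scaled space — this is
the only reading under which the documented identity limit (full-rank PCA
plus identity correction returns the original counts exactly) holds, and
under which existing non-negative counts are untouched whenever at least
~1% of the gene's values are zeros. Second, the integer truncation adds a
$10^{-6}$ guard before truncating, so float round-off in an exact
reconstruction cannot drop integers by one; truncation (not rounding) is
used so the correction never fabricates counts.

# Clustering plumbing

`build_neighbor_graph()` computes exact Euclidean k-nearest neighbors
(default 20) in PCA space with ties broken by index;
`detect_communities()` wraps modularity-based Leiden clustering (default
resolution 0.5) and accepts any substitute community detector. These are
infrastructure for cell typing, not methodological contributions, and are
treated as replaceable.

# Likelihood-based cell typing

Cell typing operates on clusters, not nuclei. For each cluster,
`find_distinguishing_hvgs()` finds genes overexpressed versus all other
clusters combined — one-vs-rest two-sided Wilcoxon rank-sum tests on
total-count-normalized (median-total target), log1p-transformed data,
BH-corrected across genes — under k-fold leave-one-fold-out validation
(default k = 10, folds stratified by cluster): a *distinguishing HVG*
must pass l2fc > 1 and adjusted p < 0.01 in **every** fold, and carries
its cross-fold mean l2fc.

`loglikelihood_scores()` scores a cluster against a marker database by
treating each marker's probability of being a true defining gene as
proportional to its overexpression, assuming independence across markers:
the log-likelihood for a type is simply the sum of the stored mean l2fc
over that type's positive markers that are distinguishing HVGs (0 for
markers that are not, or that are absent from the gene universe).
No specificity weighting is applied — a deliberate choice to avoid
upweighting markers that look specific merely because of database
sparsity. Negative markers, when enabled, subtract symmetrically; they
are off by default because suppressed markers are an unsafe assumption
for cells in non-normative states. `assign_cell_types()` takes the
argmax, labels all-zero clusters "unassigned", and breaks exact ties
deterministically (more contributing markers, then lexicographic) with a
flag.

`refine_clusters()` merges same-type clusters that are contiguous in the
kNN graph — contiguity meaning the clusters share at least 1% of the
smaller cluster's neighbor edges, a graph-based stand-in for the visual
adjacency a human would use on an embedding — then re-clusters listed
target clusters in isolation at low resolution (default 0.1) and re-types
everything through the same likelihood pipeline. Which clusters deserve
subclustering is inherently a judgment call; the list of targets is
config input by design.

# Consensus differential expression

The DEA contribution is the **cross-fold consensus wrapper**, not the NB
engine. `crossfold_consensus_dea()` splits one cell type's nuclei into k
disjoint random folds stratified by donor (default k = 3, chosen by the
power analysis below), fits the NB Wald model per fold, and calls a gene
a consensus DEG only if its BH-adjusted p-value is below the threshold in
**every** fold. Spuriously low dispersion estimates — from within-donor
correlation or low counts — inflate apparent effects in a
subset-dependent way; random re-subsetting perturbs them, so demanding
significance in all folds suppresses exactly that failure mode. Reported
effect sizes are cross-fold means of l2fc and of normalized counts.

The design (`build_design()`) is a 6-level combined (HIV level, SUD)
group factor plus covariates: other-substance SUD, age, sex, race,
ethnicity, overdose death, postmortem interval, tissue location, and —
only in the SUD formula — CD4 nadir, which proxies long-term
immunosuppression and is excluded from HIV contrasts because it
recapitulates viral-load variation. Numeric covariates are standardized;
categorical covariates inducing identical donor partitions are collapsed
to one; a design left rank-deficient after this pruning is an error that
names the aliased columns.

The engine (`nb_wald_fit()`) uses median-of-ratios size factors with a
positive-count fallback, per-gene ML dispersion (moment-based start,
profile optimization, one refit), and a Wald test of the group contrast
with BH correction. It deliberately omits DESeq2's dispersion-trend
shrinkage, independent filtering and outlier replacement: those controls
matter most in small-sample bulk designs, whereas here each fold spans
all ~90 donors and thousands of nuclei, and the consensus wrapper
provides the false-positive control. The engine is cross-checked against
DESeq2 on simulated data in the test suite (l2fc correlation > 0.98);
DESeq2 is never used as the implementation. Genes with zero counts in
more than $(1 - 1/k)$ of a fold's nuclei are not tested in that fold,
mirroring low-count exclusion; with k = 1 the wrapper reduces exactly to
a single Wald fit. No post-hoc l2fc cutoff is applied by default (the
effective detectable l2fc depends on FDR, sample size and data content);
an optional threshold exists but is off.

Whether DEA should consume back-projected corrected counts or
pre-correction counts is not uniquely determined; the pipeline defaults
to corrected counts (the denoised dataset the rest of the analysis uses)
and exposes the alternative via `use_corrected_counts = FALSE`.

# Coordinated DEG subclusters

For a chosen DEA and cell types, `donor_mean_expression()` builds a DEG ×
case-donor matrix of mean normalized expression, with rows labeled
`cell-type_direction_gene` so a gene differentially expressed in two cell
types contributes two rows. `similarity_matrix()` computes cross-donor
Pearson correlations (pairwise-complete, minimum 3 shared donors) with
the two-tailed test at 0.05 and gates similarity by significance:
$\mathrm{sim}_{ij} = |r_{ij}|$ if $p_{ij} < 0.05$, else 0. Distances are
$\mathrm{dist}_{ij} = 1/(1+\mathrm{sim}_{ij}) \in [0.5, 1]$ — the +1
avoids division by zero and the nonlinearity compresses the distance
range so only pronounced similarity separates clusters.

`cluster_and_split()` builds an average-linkage tree, cuts it at a
linkage distance of 0.95 to form initial clusters, and then splits each
cluster at dendrogram-adjacent leaf pairs whose pairwise distance is at
least 3 SD above the cluster's mean adjacent distance. Requesting the
full linkage tree with a distance threshold of zero — a common way this
step is configured — taken literally yields singleton clusters with
nothing to split; cutting at 0.95 instead, i.e. merging whenever average
similarity exceeds about 0.05, produces algorithm-generated clusters with
visible substructure for the split rule to act on. This cut is this
package's documented interpretation, and no equivalence with any
external cluster numbering is claimed.
Subclusters are named `C<cluster>S<subcluster>` with 0-based subcluster
indices in leaf order, and retained when their mean pairwise similarity
is at least 0.75; singletons have undefined mean similarity and are never
retained.

# Composition and overlap testing

`proportion_mle()` gives per-donor binomial MLEs $\hat p = k/n$ of
cell-type occurrence. `proportion_ks_tests()` compares, for every
unordered donor-group pair and every cell type, the two groups' donor
distributions of $\hat p$ with a two-sample Kolmogorov–Smirnov test, BH
corrected within each group pair across cell types. The exact
small-sample KS null is used when both groups have ≤ 25 donors, the
asymptotic form otherwise, and the variant is reported. All cell types in
the table are tested for every pair — 6 groups × 12 types = exactly 180
tests — with types absent from a group flagged rather than skipped, so
the test count is a stable denominator.

`overlap_permutation_test()` draws the two observed DEG-set sizes from
the HVG background (default 20,000) independently and without
replacement, 100,000 times, and reports the fraction of iterations whose
overlap reaches the observed overlap — an upper bound on the p-value,
reported as `< 1/iterations` when no iteration qualifies. The
closed-form hypergeometric tail is returned alongside as a cross-check;
the sampling test is kept as the primary output because it generalizes
to structured backgrounds where no closed form applies.

# Power simulations and fold selection

`wilcoxon_power_lognormal()` estimates the power to detect a log2 fold
change between two lognormal expression distributions
$\exp(N(\mu_i, \sigma^2))$ with $|\mu_1 - \mu_2| = \ln(2)\,\mathrm{l2fc}$
and $\sigma^2 = 1$; `sample_size_search()` walks s = 10, 12, 14, … with
10,000 iterations per size until estimated power reaches 80% at p < 0.05.

One design decision here deserves a frank account. The study this
pipeline was built around reports thresholds of s = 158, 42, 20 per
group at l2fc 0.5, 1.0, 1.5 for this simulation, describing the test as
a rank-sum test. The *unpaired* two-sample Wilcoxon rank-sum test under
this parameterization crosses 80% power earlier — at about s = 140, 36,
18, consistently across seeds and confirmed with an independent
implementation — while the *paired* Wilcoxon signed-rank test (exact
null for small samples, normal approximation beyond n = 50) reproduces
156–158, 42 and 20. The package therefore defaults to the signed-rank
variant, which reproduces the reported values, and exposes the rank-sum
variant through `test = "rank-sum"`. The variance
parameterization ("variance of 1" on the underlying normal versus the
count scale) was examined as an alternative explanation and rejected: the
count-scale reading requires an unstated baseline mean and moves the
thresholds in the wrong direction. `sigma2` remains configurable.

Note also that at l2fc 0.5 the power curve crosses 80% shallowly
(≈ 0.002 per step of 2), so with 10,000 iterations the search's stopping
point genuinely varies by a couple of steps around s ≈ 156; the
acceptance tolerance for that threshold reflects this stopping
distribution, not implementation slack.

`distinguishing_power_normal()` is the analogous check on the log1p
scale (normal distributions with means 1 and $2^{\mathrm{l2fc}}$, equal
variance) used to size distinguishing-HVG detection at p = 0.01.
`select_k()` chooses the cross-validation fold count: the smallest k ≥ 2
such that every cluster, with one fold removed, still meets the powered
minimum — $\lfloor \mathrm{size} \cdot (k-1)/k \rfloor \ge n_{\min}$ —
optionally incremented by 1 (the default) for margin.

# Problem sizes, determinism and limitations

The test suite and the acceptance script run everything on synthetic
cohorts sized for a laptop-class machine: recovery suites use 90-donor,
single-cell-type cohorts of 9,000 nuclei × 400 genes (planted DEG
recall), 4,500 nuclei × 2,000 genes (null false-positive rate), 2,400
nuclei × 300 genes across 20 seeds (cell typing), and 2,000 × 500 (exact
back-projection); the power searches use the full 10,000 iterations per
candidate size. These sizes were chosen so each suite exercises the same
estimators at donor counts matching the study design while completing in
minutes.

All randomness flows through explicit integer seeds (one RNG, fixed
generator kind), and stage seeds derive from a single global seed via a
documented splitting function; identical configuration and seed give
bit-identical outputs, including sparse matrices.

Known limitations: the NB engine's dispersion estimates are per-gene ML
without shrinkage and can be unstable for genes expressed in very few
nuclei (such genes are typically excluded by the fold-wise low-count
filter); the back-projection identity requires every corrected gene to
have ≥ ~1% zero counts (true of essentially all genes in sparse UMI
data); contiguity-based cluster merging approximates, but does not
reproduce, judgments made visually on an embedding; and the synthetic
generator's independence assumptions mean recovery results bound
performance under model correctness, not under real-data artifacts.
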