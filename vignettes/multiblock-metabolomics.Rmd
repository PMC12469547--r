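---
title: "Multiblock differential analysis of urine metabolomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiblock differential analysis of urine metabolomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metabloc` analyses a samples-by-metabolites intensity matrix from a
two-group urine study. This vignette explains the statistical models at
each stage, the assumptions they make, the parameters worth knowing
about, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the methodology left genuine choices.

## The analysis chain

### Dilution normalization (PQN)

Urine concentration varies several-fold between infants, multiplying
every metabolite of a sample by a common unknown factor. PQN estimates
that factor as the median, over metabolites, of the ratios between a
sample's intensities and a reference spectrum, and divides the sample by
it. We use the per-metabolite median across **all** samples (both groups
pooled) as the reference: restricting the reference to one group would
make the normalization depend on the contrast under study. The quotient
median is robust as long as well under half of the metabolites are
shifted in one direction — which is why the generator balances up- and
down-regulated metabolites, as the study design this emulates reports.

PQN is an exact fixed point only against a *stored* reference: dividing
by the coefficients and then recomputing the median reference from the
normalized matrix moves the coefficients by a few percent (the median
row itself changes). `pqn_normalize(x, reference = prev$reference_spectrum)`
gives the exact idempotent form; the tests check both behaviours.

Zero, negative or missing intensities are refused rather than imputed —
imputation is an upstream decision that should not happen silently
inside a normalizer.

### Univariate screen

Per metabolite, a two-sided Mann–Whitney U test compares the groups
(exact enumeration when the pooled sample size is at most 12 with no
ties, otherwise the normal approximation with tie and continuity
corrections), p-values are adjusted by Benjamini–Hochberg, and the
log2 fold change is the log ratio of group means of PQN-normalized
(never autoscaled — those values can be negative) intensities with Term
as reference, so positive values mean elevated in Prem. The volcano rule
declares a metabolite significant when FDR < `alpha` (default 0.05) and
|log2FC| > `fc_threshold` (default 0.6, i.e. a 50% concentration
change). The mean is the default fold-change estimator; `estimator =
"median"` is available for heavy-tailed data.

### PLS-DA, Q2Y and permutation validation

The class is dummy-coded 0/1 and centered; NIPALS PLS1 extracts
components maximizing covariance with it. Defaults: 2 predictive
components (score plots conventionally show components 1 and 2), sign
fixed so the largest-magnitude weight element is positive (otherwise
scores flip arbitrarily between runs).

R2Y is in-sample explained class variance. Q2Y is estimated by 7-fold
stratified cross-validation of the PRESS statistic; fold centering *and
scaling are re-estimated on each training fold* and applied to the
held-out fold, so no scaling information leaks — the conservative
default where the original protocol is unstated. Significance comes from
a permutation test (default 200 label permutations; folds re-drawn per
permutation) with the add-one estimator
\((1+\#\{perm \ge obs\})/(B+1)\), so p is never exactly zero and its
floor is \(1/(B+1) \approx 0.005\).

### The normality-plot threshold

Three selection steps (VIP scores, Gini importances, betweenness
centralities) share one visual rule: plot the scores on a normal
probability plot and cut where the upper tail "starts to deviate". Our
operationalization: sort the scores against Blom plotting positions,
fit a reference line by least squares to the central 50% of points, flag
a point as deviating when its residual above the line exceeds `k_sd`
(default 2) pointwise order-statistic standard errors — the classic QQ
confidence band, which widens in the tails — and place the threshold at
the largest gap between consecutive sorted scores adjoining the
deviating suffix.

Two details matter. A fixed residual scale (e.g. a MAD of the central
residuals) cannot work here: central order statistics hug the line, so
their MAD is tiny, and a detached outlier cloud compresses the plotting
positions of the bulk tail, lifting legitimate bulk points far above the
line — a fixed scale then sweeps much of the bulk into the selection.
The widening band fixes the false-positive side and the gap placement
separates a detached cloud from displaced bulk points. Second, the rule
is a heuristic for a visual judgement: `k_sd`, the central-window
fraction and `min_tail` are exposed, and a manual threshold (such as the
conventional VIP cut-offs 1.5 for LC-MS and 1.4 for NMR data) always
overrides it.

### Multiblock scoring

Metabolites carry up to three functional annotations; a block keeps its
members present in the matrix and is discarded below three members. Each
block gets a two-class OPLS-DA (one predictive component plus, by
default, one orthogonal component in the Trygg–Wold scheme) on the
globally autoscaled columns; its predictive score t1 summarizes the
block's class-related variation per sample. Block scores are weighted by
\(\omega_k = \sqrt{n_k}/\sqrt{\sum_m n_m}\) — the variance-balancing
choice, so \(\sum_k \omega_k^2 = 1\) and no block dominates purely by
size; linear weighting is available via `weighting = "linear"`.
Metabolites in several blocks contribute fully to each; there is no
multiplicity down-weighting.

The blocked representation is validated by fitting a PLS-DA on the block
scores and correlating its t1 with the unblocked model's t1 (flagged as
distorted below |r| = 0.7). **Important:** because the block scores are
themselves fitted to the labels, the blocked model's permutation test
rebuilds every per-block OPLS-DA under each permuted labeling. Permuting
labels over the fixed score matrix would compare against a null that
still carries the original labels' overfitting and would be strongly
anti-conservative.

Block selection uses a 500-tree random forest's Mean Decrease Gini with
the normality-plot rule (below 10 blocks the rule is too unreliable and
nothing is selected unless a manual threshold is given).

### Differential networks

Per group, the correlation matrix of block scores is shrunk toward the
identity with the analytic Schäfer–Strimmer intensity and inverted to
give partial correlations; edge p-values use the null density of sample
partial correlations with \(\kappa = n-(G-2)-1\) effective degrees of
freedom (exact under Gaussian independence, verified by simulation in
the tests). This analytic null replaces the empirical-null mixture of
the package the original workflow used, trading a little adaptivity for
determinism. The *minimal network* keeps the shortest prefix of edges —
ranked by p ascending, ties by |pcor| descending then lexicographic pair
order, fixed for reproducibility — in which every node keeps at least
one edge ("coverage"); a connectivity-based variant is available via
`minimal_criterion = "connectivity"`. The Prem-specific network is the
edge-set difference of the two minimal networks; hubs are nodes of high
unweighted shortest-path betweenness (Brandes), selected by the
normality-plot rule. Betweenness is computed on the differential graph
(the graph the hub figure of such studies displays); computing it on
each group's network instead is a one-line change on the returned
objects.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions: 96 Term vs 45 Prem
samples with 74 features in 14 blocks (NMR-style default) or 96 vs 28
with 521 metabolites in 66 blocks (LC-MS-style), log-normal baselines,
per-sample log-normal dilution (`dilution_sd = 0.3`), multiplicative
measurement noise, within-block correlation (`within_block_rho = 0.5`
via a per-block identity factor), and ~46% differential metabolites with
|log2FC| drawn from 0.2–1.5, signs split evenly.

Design choices a user should know:

- **Dysregulation is block-concentrated.** A fraction
  (`frac_focal_blocks = 0.15`) of blocks is "focal": up to four of their
  members get fold changes from the upper half of the range; the
  remaining quota is spread evenly (about two members per block) with
  lower-half magnitudes. This mirrors the block-level heterogeneity that
  makes block selection meaningful; with uniformly spread effects the
  Gini importances form a continuum and no selection threshold exists.
- **Group-specific dependence rides on severity factors.** Each block
  has a per-sample "dysregulation severity" factor that modulates its
  differential members along the sign of their effect, in Prem samples
  only (`severity_sd = 0.3` on the log2 scale — preterm cohorts are
  markedly more heterogeneous than term ones). In the Prem group these
  factors are correlated along a planted star forest over the blocks
  (hub + 2 leaves, `edge_strength = 0.85`, spanning all blocks by
  default); in Term they are independent. The severity layer, not the
  block identity factor, carries the plantable dependence because the
  orthogonal component of per-block OPLS-DA removes exactly the
  class-unrelated shared variation — dependence planted there is
  invisible to t1 scores *by construction*.
- **Within-block signs alternate** (a dysregulated pathway accumulates
  some members and depletes others), with phases balanced globally so
  the PQN quotient median stays unbiased.
- `noise_cv = 0.12` reflects the precision of absolute-quantification
  urine profiling after QC filtering; it is also the regime in which the
  planted dependence is identifiable at n = 45.

What the generator does **not** emulate: batch/run-order drift and QC
correction (removed upstream in real pipelines), missing values and
limits of detection, heavy-tailed or skewed abundance distributions
beyond log-normality, correlations between clinical covariates and the
group label (the generated `sex`/`delivery` covariates are neutral by
construction), and any chemistry (adducts, isotopes, peak overlap).
Passing tests therefore demonstrate the *pipeline's* correctness and
calibration under a plausible generative model, not robustness to all
real-data pathologies.

## Numerical conventions

- Dummy y centered; two-class contrasts only.
- Weight vectors unit-norm; sign convention: largest-|w| element
  positive, applied to every extracted component and block score.
- Rank exhaustion in NIPALS (residual X'y below 1e-12 of the response
  scale) raises an error asking for fewer components.
- Constant columns are dropped with a warning at autoscaling; a fold
  with zero variance in cross-validation falls back to unit scale for
  that column.
- Stratified folds are re-drawn (up to 25 times) if a training fold
  loses a class.
- Permutation p-values use the add-one estimator; seeds control fold
  draws, permutations and the forest.
- Edge ordering ties broken by |pcor| then lexicographic node pair;
  identical inputs give byte-identical outputs under a fixed
  `pipeline_config()` seed.

## Known limitations

- **In-sample block scores overfit.** Per-block t1 scores are supervised
  summaries; on data with no real signal they still separate the groups
  in-sample, so per-block tests on the scores are anti-conservative, and
  in roughly a quarter of null datasets one spurious block detaches on
  the Gini normality plot. The calibrated guard is the blocked model's
  rebuild-per-permutation test — consult it before reading the block
  selection.
- **Differential-edge recovery is partial at study-scale n.** With 45
  Prem samples, 14 blocks and the coverage-based minimal networks, the
  acceptance script's recovery of planted Prem-specific edges runs
  around 0.55–0.65 sensitivity and 0.6–0.75 precision at full default
  settings: planted edges are lost to chance overlap with the Term
  minimal network (whose coverage prefix holds a dozen noise edges), to
  sampling noise in partial correlations conditioned on 12 other blocks,
  and to metabolites annotated to several blocks injecting their primary
  block's variation into other blocks' scores. Betweenness hubs of the
  differential network inherit this uncertainty — treat them as
  hypotheses, not identifications.
- The normality-plot threshold is an operationalized visual heuristic;
  for reporting, prefer stating a manual threshold.
- LC-MS-scale group networks (66 blocks vs 28 Prem samples) are deep in
  the shrinkage regime; their edge p-values are conservative and the
  minimal networks correspondingly coarse.

## Problem sizes used in the test suite

Unit tests run on small matrices (tens of samples, up to ~50 features);
calibration checks use 2000 Mann–Whitney replicates, 50 permutation-test
replicates and 20-seed generator sweeps; the end-to-end emulations run
once per platform at the full study dimensions (141×74 and 124×521).
These sizes keep the whole suite and the acceptance script within a few
minutes on a single core while leaving Monte-Carlo error well inside the
asserted margins.
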