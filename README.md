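# metabloc

Multiblock differential analysis of two-group urinary metabolomics data.

Urine intensity matrices (LC-MS or NMR) comparing two clinical groups —
here labelled `Term` (reference) and `Prem` — are confounded by strong
per-sample dilution, and individual metabolite tests say little about
which *biological functions* are disrupted. `metabloc` implements the
complete analysis chain used for this kind of study:

1. **Preprocessing** — probabilistic quotient normalization (PQN) against
   the pooled median spectrum removes dilution; autoscaling puts every
   metabolite on unit variance.
2. **Univariate screen** — per-metabolite Mann–Whitney U tests,
   Benjamini–Hochberg FDR, log2 fold changes (Prem over Term), and the
   volcano rule (FDR < 0.05, |log2FC| > 0.6).
3. **Latent modelling** — NIPALS PLS-DA of the dummy-coded class with
   cross-validated Q2Y, permutation validation (default 200 label
   permutations), VIP scores
   \(VIP_j = \sqrt{p\,\sum_a SSY_a w_{aj}^2 / \sum_a SSY_a}\), and a
   normality-plot rule that reads a selection threshold off a QQ plot.
4. **Multiblock scoring** — metabolites are grouped into functional
   blocks (up to three annotations each; blocks with fewer than three
   members are discarded); each block gets an OPLS-DA model whose
   predictive score t1, weighted by \(\sqrt{n_k}/\sqrt{\sum_m n_m}\),
   summarizes the block per sample. A PLS-DA on the block scores is
   checked against the unblocked model, and a random forest ranks blocks
   by Mean Decrease Gini.
5. **Differential networks** — per-group shrinkage partial correlations
   (Schäfer–Strimmer \(\lambda\)) over the block scores, analytic edge
   p-values from \(r^2 \sim Beta(1/2, (\kappa-1)/2)\) with
   \(\kappa = n-(G-2)-1\), minimal networks (fewest interactions covering
   every node), Term-from-Prem edge subtraction, and betweenness-based
   hub selection.

Because cohort data of this kind is rarely shareable, the package ships a
synthetic-data generator (`synth_config()` / `generate_dataset()`) that
emulates the study design — unbalanced groups, log-normal abundances,
multiplicative dilution, ~46% differential metabolites concentrated in a
few focal blocks, within-block correlation, and Prem-specific block-block
dependence — with the full ground truth returned, so every stage is
testable end to end.

## Worked example

```r
library(metabloc)

d <- generate_dataset(synth_config(seed = 3))
d
#> Synthetic metabolomics dataset
#>   141 samples (96 Term, 45 Prem) x 74 metabolites, 14 blocks
#>   34 differential metabolites planted; 10 Prem-specific block edges

res <- run_pipeline(d$features, d$metadata, d$blocks, "run1",
                    pipeline_config(seed = 4))
res$permutation
#> Permutation validation (200 permutations, 2 components)
#>   R2Y = 0.955 (p = 0.0050)   Q2Y = 0.925 (p = 0.0050)
res$blocked_validation
#> Blocked vs unblocked PLS-DA comparison
#>   |r(t1 blocked, t1 unblocked)| = 0.996 -> similar mapping
#>   unblocked: R2Y 0.955 (p 0.0050), Q2Y 0.933 (p 0.0050)
#>   blocked:   R2Y 0.936 (p 0.0050), Q2Y 0.917 (p 0.0050)
```

Reading the output: the groups separate strongly (R2Y and Q2Y above 0.9,
permutation p = 1/201, the smallest attainable with 200 permutations),
and collapsing 74 metabolites to 14 weighted block scores leaves the
sample map essentially unchanged (|r| = 0.996), so the block-level view
is a faithful summary. Of the 34 planted differential metabolites, 17
pass the volcano rule (12 up, 5 down in Prem) — the remainder carry
planted effects below the 0.6 fold-change threshold. `res$hubs$hubs`
names the blocks with the highest betweenness in the Prem-specific
network (`B04`, `B08` here); with moderate sample sizes these network
bottlenecks are estimates and need not coincide with the planted hub
blocks (see the vignette's limitations section).

All stage outputs are written under `run1/` (`preprocess/`,
`univariate/`, `latent/`, `multiblock/`, `network/`, `report.json`,
`manifest.json`). A thin command-line wrapper with the same
functionality lives at `inst/cli/metabloc.R`
(`simulate` / `run -c config.yaml` / `subgroups --by <covariate>`).

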