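# refstab

Reference-gene stability ranking for RT-qPCR normalization.

## The problem

Quantitative RT-PCR expression values are only as good as their
normalization. Target-gene Cq (quantification-cycle) values are divided by a
normalization factor built from *reference genes* — genes assumed to be
stably expressed across the samples under study. That assumption fails often
enough (classically for *GAPDH* and *ACTB*) that choosing reference genes is
itself a statistical problem: given a panel of candidate genes measured over
many samples and tissue types, which genes are most stable, and how many are
needed?

`refstab` implements, from Cq tables, the three algorithms in routine use
for this question, plus the plumbing around them:

- **Comparative-Cq quantification** — relative quantities
  `q = E^(Cq_min − Cq)` per gene, with per-gene amplification efficiency
  `E = 10^(−1/slope)` estimated from standard-curve dilution series
  (`fit_standard_curve()`, `efficiency_from_slope()`,
  `relative_quantities()`).
- **geNorm** — gene-stability value `M_j = mean_k SD_s(log2 q_js/q_ks)`,
  iterative exclusion of the least stable gene, and the pairwise-variation
  series `V(n/n+1) = SD_s(log2 NF_n/NF_{n+1})` for choosing the panel size
  (`genorm_rank()`, `nf_pairwise_variation()`), where `NF_n` is the
  geometric mean of the `n` most stable genes' quantities. Suggestive
  cutoff: `V ≤ 0.15`.
- **NormFinder-style decomposition** — sample-centered log quantities are
  decomposed per tissue group into a gene-specific intra-group variance
  `σ²` (moment-corrected for the centering) and a shrunken inter-group
  deviation `d̃`; the stability value is
  `ρ = mean_g(|d̃| + sqrt(σ²/n_g))`, lower = more stable
  (`normfinder_stability()`).
- **BestKeeper** — crossing-point descriptives on raw Cq (geometric mean,
  SD, CV%, x-fold coefficients `base^ΔCq` with the negative-at-minimum sign
  convention), the per-sample geometric-mean index, and gene–index /
  gene–gene Pearson correlations with two-sided p-values; ranking by
  ascending Cq SD with the `SD < 1` consistency flag (`bestkeeper()`).
- **Consensus** — geometric mean of the three ranks plus the V-rule panel
  recommendation (`consensus_rank()`, `recommend_panel_size()`), all wired
  together by `run_stability()`.
- **Synthetic Cq generator** — `simulate_cq()` draws
  `Cq = μ_gene + δ_gene,group + loading_sample + ε` with planted ground
  truth, and `preset_paper_like()` ships a 10-gene × 12-tissue × 54-sample
  survey-scale world for validation.

## Worked example

```r
library(refstab)

sim <- simulate_cq(preset_paper_like(42))   # 10 genes x 54 samples, 12 tissues
res <- run_stability(sim$table)             # geNorm + NormFinder + BestKeeper
print(res$genorm)
print(res$consensus)
```

```
genorm_result (10 genes)
     gene      M rank
1     UXT 0.3696    1
2    RPS9 0.3696    1
3   RPS23 0.4623    2
4    RPL4 0.4940    3
5  EEF1A1 0.8851    4
...
10  RPS15 2.0950    9
V(n/n+1): V2/3=0.1416  V3/4=0.1069  V4/5=0.1678 ...

consensus_result
     gene genorm_rank normfinder_rank bestkeeper_rank aggregate_score
1     UXT           1               2               1          1.2599
2    RPS9           1               1               2          1.2599
3   RPS23           2               5               3          3.1072
...
10  RPS15           9              10              10          9.6549
recommended panel (n = 2, V = 0.1416): UXT, RPS9
```

Reading this: the two geNorm survivors (`UXT`, `RPS9`) share rank 1 with the
common M of their pair (the algorithm cannot separate the final two); the
planted-stable genes occupy the consensus top 4 and the planted-unstable
pair (`B2M`, regulated in three tissues; `RPS15`, noisiest) sits at the
bottom of every ranking. `V(2/3) = 0.14 ≤ 0.15`, so two reference genes
suffice for this (simulated) panel; heterogeneous real tissue panels often
stay above the cutoff, in which case the size at the lowest V is recommended
with `threshold_met = FALSE`.

Real data enter as plain CSV/TSV (`read_cq_table()`, long or wide layout,
technical duplicates collapsed by `collapse_replicates()`), or through the
CLI:

```sh
Rscript inst/cli/refstab.R simulate --preset paper-like --seed 42 --out sim/
Rscript inst/cli/refstab.R run --cq sim/cq_long.csv --layout long --out out/ --format markdown
```

## Documentation

The methods vignette (`vignettes/reference-gene-stability.Rmd`) describes
the statistical model behind each algorithm, the simulator's stated world
and its limits, and the numerical design choices.
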