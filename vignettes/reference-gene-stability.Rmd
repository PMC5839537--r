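---
title: "Ranking reference genes for RT-qPCR normalization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking reference genes for RT-qPCR normalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The measurement model

A well's quantification cycle Cq is, to good approximation, linear in the
log of the template amount: one extra cycle corresponds to one halving of
input when amplification doubles per cycle. `refstab` works throughout on
the additive model

```
Cq[g, s] = mu_g + delta_{g, group(s)} + L_s + eps[g, s]
```

where `mu_g` is the gene's expression baseline, `delta` a group-specific
regulation shift (a *regulated* gene — the thing a reference gene must not
be), `L_s` a per-sample loading effect shared by **all** genes in sample `s`
(total RNA input, RT yield, pipetting), and `eps ~ N(0, sigma_g^2)`
gene-specific noise. Normality on the Cq scale means log-normal,
multiplicative noise on the quantity scale — the implicit assumption of all
three stability algorithms, and the one the synthetic generator makes
explicit.

A good reference gene has small `sigma_g` and no `delta`. The loading `L_s`
is precisely what normalization is meant to remove, so a stability measure
must be *blind* to it. All three algorithms achieve this differently, and
the package property-tests each route (multiplying one sample's quantities
by any constant changes no geNorm or NormFinder output to 1e-9).

## Quantification

Relative quantities use the comparative-Cq transform
`q[g, s] = E_g^(minCq_g − Cq[g, s])` with the per-gene minimum as reference
point, so `q ∈ (0, 1]` and each gene's maximum is exactly 1. Any common
per-gene reference cancels in every downstream log-ratio and variance, so
this choice is presentation-only (tested as a shift-invariance property).
The amplification base defaults to `E = 2` (100% efficiency); per-gene
efficiencies from standard curves (`E = 10^(−1/slope)`, OLS on Cq vs log10
input) are honored whenever supplied. Typical assay slopes fall between
about −3.1 and −3.6, i.e. efficiencies of roughly 88–110%.

## geNorm

For genes `j, k` the pairwise variation `V_jk` is the sample SD (n−1
denominator) of `log2(q_j/q_k)` over samples; the loading cancels inside
the ratio. The stability value `M_j` averages `V_jk` over all partners in
the active set. The ranking removes the highest-M gene, recomputes, and
stops at two genes — which by construction share the same M (their common
pairwise V) and share rank 1. Exact ties on exclusion (certain on synthetic
duplicates, measure-zero on real data) remove the later gene in input
order, with a message.

The panel-size series builds normalization factors `NF_n` as geometric
means of the top-`n` genes (geNorm order) and reports
`V(n/n+1) = SD(log2 NF_n/NF_{n+1}))` for all `n = 2..k−1`, not just the
first few — tissue-wise analyses routinely inspect the whole series.
`recommend_panel_size()` takes the smallest `n` with `V ≤ 0.15` (boundary
inclusive); when nothing passes — common for panels spanning many diverse
tissues — it recommends the size at the minimum V with
`threshold_met = FALSE`, treating 0.15 as the suggestive criterion it is
rather than a universal cutoff.

Numerical conventions (the underlying methods papers leave them open): log
base 2 and the n−1 SD denominator throughout. Any fixed base rescales all M
and V by a constant and preserves every ranking, so this is a reporting
convention, not a modelling choice.

## NormFinder-style decomposition

The original model-based approach is distributed as a closed tool without
published constants, so `refstab` implements a concrete, moment-matched
rendition and validates it by parameter recovery and planted-gene ranking
rather than by digit-matching the binary:

1. **Centering.** `z = y − colMeans(y)` on `y = log2(q)` removes loading
   exactly but injects `−(1/k) * sum_i eps_i` into every cell, correlating
   genes.
2. **Moment inversion.** Within group `g`,
   `Var(z_i) = sigma_i^2 (1 − 2/k) + S/k^2` with `S = sum_i sigma_i^2`.
   Summing over genes gives `S = (k/(k−1)) sum_i s2_i`, hence the unbiased
   corrected estimate `sigma2_i = (s2_i − S/k^2) / (1 − 2/k)`, floored at
   1e-8 so negative moment estimates cannot break the shrinkage ratio
   below. The correction is undefined at `k ≤ 2`, hence the hard 3-gene
   minimum.
3. **Inter-group deviations.** `d_ig = zbar_ig − mean_g'(zbar_ig')`; the
   true between-group variance is estimated as
   `gamma2_i = max(0, sum_g d^2/(G−1) − mean_g(sigma2_ig/n_g))` and the
   deviations shrunk by the reliability ratio
   `d~ = d * gamma2 / (gamma2 + sigma2/n_g)` — genes whose apparent group
   effects are explainable by sampling noise are pulled to zero.
4. **Stability.** `rho_i = mean_g(|d~_ig| + sqrt(sigma2_ig/n_g))`;
   ungrouped mode reduces to `rho = sqrt(sigma2_i)`.

Recovery behaviour worth knowing: for a gene whose own variance is small
relative to `S/k^2` (a very stable gene among noisy companions), the
corrected estimate is unbiased but inherits the companions' sampling noise
— at k = 10 with noise SDs 0.2–1.6 and 200 samples per group, a single
dataset estimates a sigma = 0.2 gene with roughly 8% relative SE. Recovery
tests therefore aggregate over seeds. The `max(0, ·)` in `gamma2` also
makes single-dataset rho rankings of nearly-tied genes noisy; orderings, not
rho digits, are the robust output.

## BestKeeper

Descriptives are computed on **raw Cq**, per gene, over all its non-missing
samples: geometric/arithmetic mean, extremes, SD (sample SD by default; the
mean absolute deviation about the arithmetic mean is available via
`sd_method = "mad"` since descriptions of the original tool differ and
printed tables cannot adjudicate), CV% on Cq. The x-fold coefficients
re-express dispersion on the fold-change scale, `base^deltaCq`, with the
original sign convention: negative at the minimum Cq (highest expression),
positive at the maximum, and `sd_xfold = base^sd_cq` — identities tested as
cross-field invariants to 1e-9. The per-sample index is the geometric mean
Cq of the candidate genes (complete cases); gene-vs-index and gene-vs-gene
Pearson correlations carry two-sided p-values from the t transform
(`p` floored at the smallest positive double for |r| = 1; one-sided tests
are not offered). Ranking sorts by ascending `sd_cq` (ties: `sd_xfold`,
then input order); the `SD < 1` cycle rule flags genes as inconsistent but
never excludes them. Correlations are attached as advisory output only —
raw-Cq correlations conflate loading with co-regulation, which is why they
do not enter the sort.

## Consensus and missing data

The three algorithms agree on well-separated data but need a tie-breaking
total order for reporting. The consensus is the geometric mean of the three
per-gene ranks (ties within an algorithm carry shared minimum ranks into
the product; aggregate ties break by geNorm rank, then input order). This
is an explicit artifact convention — the methods literature intersects
rankings narratively and states no formula. The recommended panel is the
top `panel_size` genes of the **geNorm** order, since the V series that
fixes the size is defined on that order.

Missing-data policy: geNorm and NormFinder require a rectangular matrix and
run on the complete-case subset (listwise deletion, minimum 3 surviving
samples); BestKeeper descriptives use all non-missing values per gene while
the index uses complete cases. Technical duplicates collapse by arithmetic
mean (the field runs duplicates but states no collapse rule; median is
offered), with a QC warning at replicate spreads above 0.5 cycles.

## The synthetic world

`preset_paper_like(seed)` encodes a survey-scale stated world emulating a
12-tissue, 5-animal livestock design with 54 usable samples (unbalanced:
ovary 3, testis 2, mammary gland 4, the rest 5 — sex-specific tissues
cannot come from every animal; no exclusion rule is guessed beyond that).
Baselines span 19.3–25.6 cycles; loading SD is 0.7 cycles; per-gene noise
SDs are graded 0.27–1.80 so that four namesake genes (UXT, RPS9, RPS23,
RPL4) are clearly most stable, a middle tier (EEF1A1, ACTB, GAPDH, HMBS)
is intermediate, and two are clearly worst: RPS15 (noise SD 1.8) and B2M
(noise SD 1.35 **plus** a +1.5-cycle regulation shift in spleen, liver and
intestine — the classic immune-tissue B2M failure mode). Total per-gene Cq
SDs then span about 0.75–1.9 cycles, the range reported for real
multi-tissue surveys. The separation between tiers is deliberately clear:
the preset validates that the algorithms recover a *known* ordering, which
requires the ordering to be identifiable at n = 54.

What the generator does **not** emulate: amplification-curve artifacts,
melt-curve failures, inter-run calibration drift, non-normal outliers,
correlated regulation across genes, and missingness mechanisms (cells are
missing only if you make them so). A green recovery test therefore
establishes that the algorithms and their implementation work under the
model they assume — not that the model captures every pathology of real
plates.

Seeds are mandatory everywhere (`sim_config` refuses to default one), the
generator restores the caller's RNG state, and identical seeds reproduce
tables bit-for-bit.

## Numerical choices and limitations

- Variance floor 1e-8 (NormFinder), p-value floor at the smallest positive
  double, hard error below 3 complete-case samples or 3 genes: all guard
  degenerate denominators rather than change well-posed answers.
- geNorm exclusion ties: later gene in input order, logged. Full-tie
  BestKeeper rankings preserve input order.
- Reports round scores to 4 decimals and Cq-scale descriptives to 2, and
  serialize with stable key order, so reports are byte-identical across
  runs.
- The NormFinder constants here are one defensible moment-matched choice;
  other renditions (including the original tool) can differ in rho's scale.
  Cross-tool comparisons should be made on rankings.
- No target-gene ΔΔCq engine and no candidate-pair selection: the package
  ranks reference genes and recommends a panel; applying the normalization
  factor to targets is downstream.
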