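---
title: "Detecting fecundity candidate genes with ROH and F_ST selection signatures"
author: "fecundscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fecundity candidate genes with ROH and F_ST selection signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fecundscan)
```

## The problem and the design

Reproductive traits in sheep have low heritability, so phenotypic selection
for fecundity (lambs per ewe per mating per year, here 0, 1 or 2) makes slow
progress. An alternative is to look for *selection signatures*: genomic
footprints left where selection has pushed haplotypes toward fixation. This
package implements a two-signature genome scan designed for a small,
single-flock setting — on the order of 48 ewes genotyped on a ~50k SNP array
— where two subpopulations are first *constructed from the phenotype* and
then compared genetically:

1. **Phenotype adjustment.** Fecundity is regressed on management and body
   covariates with a Gaussian identity-link linear model; covariates are
   screened by Wald chi-squared tests ($W = (\hat\beta/\mathrm{se})^2$ on
   1 df, retain $p < 0.05$) and the final model keeps only the intercept and
   body condition: $y = \beta_0 + \beta_1 x_{bc}$.
2. **Group formation.** The fitted (adjusted) phenotypes are clustered by
   agglomerative hierarchical clustering on Euclidean distances; the tree is
   cut at $k = 2$ and the larger-mean cluster is labelled *high fecundity*.
   Welch's unequal-variance $t$-test quantifies the group difference.
3. **Marker QC.** Markers are removed when MAF $< 0.05$, the Hardy–Weinberg
   exact test gives $p < 10^{-6}$, or call rate $< 90\%$. All three filters
   are evaluated on the full input matrix and the union is removed, so the
   per-filter counts can overlap.
4. **Runs of homozygosity (ROH).** Per individual, a window of 15 SNPs
   slides along each chromosome; a window is homozygous if it has at most 1
   heterozygous and at most 1 missing call. Each SNP's score is the fraction
   of windows covering it that are homozygous; SNPs with score strictly
   above 0.05 are "in state", and maximal in-state stretches of at least 20
   SNPs are runs. Per group, the in-run frequency of each SNP is the
   fraction of the group's ewes with a run covering it; stretches of at
   least 3 consecutive SNPs with frequency $\ge 0.75$ are *consensus
   candidate haplotypes*.
5. **Per-SNP fixation indices.** Within each group
   $F = 1 - H_o/H_e$ with $H_e = 2p(1-p)$ from the group allele frequency
   ($F \equiv 0$ where $H_e = 0$), plus the two-population Weir–Cockerham
   $\theta = a/(a+b+c)$ from the among-population, among-individual and
   within-individual variance components. Markers in the top 20% of the
   ranking statistic are candidates.
6. **Annotation.** Candidate SNPs are flanked by $\pm 50$ kb (haplotypes
   flanked outward from their span), overlapping same-method/group regions
   are merged, and genes overlapping a region by at least 1 bp (closed
   1-based intervals) are reported per method and group.

## Choice of the F_ST ranking statistic

The published description of the differential statistic — "the difference
between the fixation values per SNP between the subpopulations" — reads as
$\Delta = |F_{high} - F_{low}|$, and the package computes it. But $\Delta$
cannot, even in principle, detect *symmetric* differentiation: two groups at
alt-allele frequencies 0.9 and 0.1 are each in internal Hardy–Weinberg
proportions, so $F_{high}$ and $F_{low}$ have the same null distribution and
their difference is pure sampling noise. In a 50-replicate check at study
scale (0.9 vs 0.1 planted at 20 of 2000 loci, $n = 48$), ranking by
$\Delta$ recovered 17% of planted loci — chance level for a top-20% rule —
while ranking by Weir–Cockerham $\theta$, which measures between-group
differentiation directly, recovered 100%. `select_candidates()` therefore
ranks by $\theta$ by default and keeps `stat = "delta"` available as the
literal published wording.

A related, expected interaction: strongly differentiated loci show excess
homozygosity in the *pooled* sample (the Wahlund effect), so a minority of
them can legitimately fail the pooled-sample Hardy–Weinberg QC filter before
the scan ever sees them. With frequencies 0.9/0.1 and $n = 48$ roughly a
third of such loci fall below $p = 10^{-6}$; this is a property of pooled
QC, not a defect of the scan, and the end-to-end tests assert recovery for
the loci that survive QC.

## Direction of the Hardy–Weinberg filter

Published QC descriptions sometimes print the exclusion inequality as
"$p > 10^{-6}$", which taken literally would discard nearly every marker
*in* equilibrium. The package follows standard practice — markers with
$p < 10^{-6}$ are removed — and exposes `hwe_exclude = "above"` for anyone
who wants the printed sign.

## Tunable parameters

| Parameter | Default | Units / range | Where |
|---|---|---|---|
| `maf_min` | 0.05 | frequency | `apply_qc()` |
| `hwe_p_min` | 1e-6 | p-value | `apply_qc()` |
| `call_rate_min` | 0.90 | fraction | `apply_qc()` |
| `window_size` | 15 | SNPs | `roh_params()` |
| `threshold` | 0.05 | score, strict `>` | `roh_params()` |
| `min_snp` | 20 | SNPs per run | `roh_params()` |
| `max_opp_window`, `max_miss_window` | 1, 1 | calls per window | `roh_params()` |
| `hap_min_freq` | 0.75 | inclusive `>=` | `call_candidate_haplotypes()` |
| `hap_min_snps` | 3 | SNPs | `call_candidate_haplotypes()` |
| `top_fraction` | 0.20 | upper quantile | `select_candidates()` |
| `flank` | 50000 | bp | `build_regions()` |
| `k`, `linkage` | 2, complete | — | `assign_groups()` |

The linkage defaults to complete because the cited clustering routine's
default is used when none is stated; it is configurable. Gap, length and
density constraints on runs exist in some ROH implementations but are not
part of this method's definition; they are available in `roh_params()` and
disabled by default.

## Numerical choices

* **HWE exact test.** The p-value is the sum of probabilities of
  heterozygote configurations (conditional on allele counts) no more
  probable than the observed one; configurations tied with the observed
  probability are included, with a $1 + 10^{-9}$ relative guard against
  floating-point jitter. Monomorphic markers give $p = 1$.
* **SNP in-state rule.** Strictly greater than `threshold`, matching the
  reference sliding-window implementation. Note a side effect: with
  `window_size = 1` a SNP's score is 0 or 1, so `threshold` must be below 1
  for the degenerate "maximal homozygous stretch" reduction to hold.
* **Consensus frequency boundary.** Inclusive ($\ge 0.75$): a 4-ewe group
  with 3 covered ewes meets the cutoff.
* **Top-quantile selection.** The threshold is R's default (type 7)
  empirical quantile at $1 - \mathrm{fraction}$; markers at or above it are
  selected, so exact ties at the threshold are all included and under a
  continuous null the selected fraction is exactly the configured one.
* **Run length.** `length_bp = end_bp - start_bp + 1` (closed 1-based
  intervals, consistently with the rest of the package; BED conversion
  happens only at the file boundary).
* **PCA.** Missing genotypes are mean-imputed per marker; markers are
  centred and scaled to unit variance (the drift scaling $\sqrt{2p(1-p)}$
  is available); components are oriented so the largest-magnitude loading
  is positive, which makes score plots reproducible.
* **PED import.** The reference allele at each marker is the first
  non-missing allele seen in file order. The choice is arbitrary and all
  downstream statistics are invariant to it (asserted by a test).
* **Zero-variance degenerate cases.** Constant body condition falls back to
  an intercept-only fit with a warning; identical adjusted phenotypes are
  rejected (no group structure); two identical constant groups give Welch
  $t = 0, p = 1$; a clustering cut that isolates a single ewe skips the
  Welch test with a warning instead of failing the assignment.

## The synthetic population

`simulate_population()` generates the study conditions end to end: 23 high-
and 25 low-fecundity ewes, 25 autosomes × 2000 biallelic SNPs (50k markers,
~1.11e8 bp per autosome), baseline alt-allele frequencies uniform on
[0.05, 0.5] under Hardy–Weinberg proportions, 1% random missingness, and
planted structure:

* **QC failures** in the proportions such markers make up on a real 50k
  ovine chip (~7.4% MAF failures, ~1% HWE failures with inbreeding-like
  homozygote excess $F = 0.95$, ~0.5% call-rate failures). The MAF and
  call-rate failures are *guaranteed*, not probabilistic: excess alt
  alleles are demoted after sampling and a minimum missing count is
  enforced, so the generator's truth table is exactly contained in the QC
  removals.
* **Shared ROH tracts** (by default three tracts of 30–40 SNPs with carrier
  fractions 0.80–0.85, echoing the chromosomes a real scan flagged):
  carriers within the designated group are overwritten with a single shared
  homozygous haplotype before missingness is applied.
* **Differentiated loci** (20 SNPs at frequencies 0.9 vs 0.1 spread over
  ten chromosomes). A locus may not be both differentiated and inside a
  planted tract; the configuration is rejected otherwise.
* **Phenotypes** follow the liability model
  $y = \beta_0 + \beta_1 x_{bc} + \delta_g + \varepsilon$,
  $\varepsilon \sim N(0, 0.25^2)$, rounded to the nearest of {0, 1, 2}.
  The group offset $\delta_g$ is *calibrated* numerically so the expected
  discretized mean equals the configured target (1.3 high / 1.1 low) — a
  calibration constant of the generator, not a fitted quantity.

Body condition is the only covariate with a real effect, and its
distribution differs by group (high: scores 4–5, low: 1–2). This coupling is
deliberate: the pipeline's adjusted phenotype is the model *fit* from body
condition, so clustering can only recover the groups if body condition
carries the group signal — exactly the situation in which this
covariate-adjustment design is informative. The two-score gap between the
supports also makes the $k = 2$ complete-linkage cut of the fitted values
deterministic; adjacent supports would leave the cut to linkage
tie-breaking. Record year, age, hours to estrus and number of births are
simulated with no effect, which is what the Wald screen should (and does)
conclude.

What the generator does **not** emulate: linkage disequilibrium and
realistic recombination (markers are independent given their frequencies),
pedigree structure and relatedness, X-chromosome inheritance, genotyping
batch effects, and informative missingness (missingness is uniform at
random; the real pattern was never published). Passing tests therefore
demonstrate that the *machinery* recovers planted signals under the stated
noise model, not that the scan has any particular power on LD-structured
real data.

## Problem sizes used by the test suite

Unit tests run on matrices up to 48 × 2000; the acceptance suite verifies
the HWE test against full enumeration for every genotype triple with
$n \le 50$, ROH detection against a brute-force window oracle on 100 random
20 × 200 instances, Weir–Cockerham $\theta$ against a step-by-step
variance-component evaluation to $10^{-12}$, planted-locus recovery over
200 replicates at study scale (48 × 2000), and one full chip-scale run
(48 × 50,000). `scripts/acceptance.R` repeats the chip-scale run and the
200-replicate recovery from scratch at an arbitrary seed.

## Known limitations

* With ~23 ewes per group the consensus-haplotype frequency has a
  granularity of ~0.04, so the 0.75 cutoff is effectively "18 of 23".
  Carrier fractions near the cutoff will flicker across seeds.
* The Welch test on *adjusted* phenotypes between *clusters of those same
  adjusted phenotypes* is circular by construction (the published design);
  its p-value describes separation achieved by the clustering, not an
  independent group contrast.
* Pooled-sample HWE QC and strong differentiation interact (Wahlund
  effect, above); a scan aiming to keep every differentiated locus would
  test HWE within groups instead, at the cost of deviating from the
  published QC.
* The per-marker scan ignores LD; neighbouring candidates are partially
  redundant, which is why overlapping candidate regions are merged before
  gene lookup by default.
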