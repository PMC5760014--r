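---
title: "Cross-trait pleiotropy from summary statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait pleiotropy from summary statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pleioconj` asks a simple epidemiological question of two genome-wide
association studies: do variants associated with one disease tend to also be
associated with the other, and if so, which loci carry the shared signal?
It answers with three connected layers — stratified fold enrichment,
conditional/conjunction false discovery rates, and LD-aware locus
post-processing — plus a functional follow-up layer for expression data.
Everything operates on summary statistics (per-variant p-values and signed
log-odds effects); no genotypes are required.

## Input model and harmonization

Each trait enters as a table of rsID, chromosome, 1-based position, effect
and other allele, p-value, and effect. Odds ratios are log-transformed on
read so the effect is always a signed log-odds value; "direction of allelic
effect" is then literally a sign. Harmonization intersects the two variant
sets by rsID and re-expresses trait 2's effect relative to trait 1's effect
allele: a swapped allele pair negates the effect, an irreconcilable pair is
dropped and counted. Palindromic (A/T, C/G) variants are dropped by default
because strand cannot be resolved without allele frequencies, which the
input format does not carry; a flag retains them. Duplicate rsIDs keep the
first occurrence. Harmonization is idempotent: re-harmonizing its own output
changes nothing.

Genomic-control correction estimates the inflation factor
$\lambda = \mathrm{median}(\chi^2_{obs}) / \mathrm{qchisq}(0.5, 1)$ from the
1-df chi-squares implied by the p-values, and divides every chi-square by
$\lambda$ when $\lambda > 1$ (never inflating when $\lambda \le 1$). The
correction is rank-preserving. All variants are used by default; in a
strongly polygenic pair, true association mass inflates $\lambda$ and the
correction is then conservative — visible in the simulated study, where
planted polygenic signal alone pushes $\lambda$ to ~1.7. Below 100 variants
the median is too unstable and $\lambda$ is forced to 1 with a warning.

## Stratified fold enrichment

For threshold $t$ on $-\log_{10} p_1$ and cumulative secondary strata
$\{-\log_{10} p_2 \ge c\}$,

$$FE(t, c) = \frac{\Pr(-\log_{10} p_1 \ge t \mid \text{stratum } c)}
                   {\Pr(-\log_{10} p_1 \ge t)}.$$

The all-variant baseline is identically 1, so any upward deflection of a
stricter stratum is enrichment. The grid uses 301 equally spaced points on
$[0, 7.3]$ — capped just below genome-wide significance
($p = 5\times10^{-8}$) to focus on sub-threshold polygenic signal — and
default strata $c \in \{0, 1, 2, 3\}$. Grid points with an empty
denominator tail are marked undefined rather than dropped, and an empty
stratum yields a flagged, all-`NA` curve. The companion true-discovery-rate
surface reads the same information as
$TDR(t, c) = 1 - \min\{1, p(t)/\hat F_c(p(t))\}$ with $\hat F_c$ the
stratum's empirical cdf of $p_1$.

The region-exclusion re-analysis removes every variant inside a named
region (default extended MHC, chr6:25–35 Mb, GRCh37 — the conventional
interval, since no coordinates are standard across studies), within a 1-Mb
flank, or in LD ($r^2 > 0.2$) with a removed variant, then recomputes the
curves. A collapse of the enrichment after exclusion demonstrates that the
region drives the shared signal.

## Conditional and conjunction FDR

The conditional FDR of trait 1 given trait 2 is estimated empirically with
a conservative null proportion $\pi_0 = 1$:

$$\widehat{FDR}(p_1 \mid p_2) = \min\left\{1,\;
  \frac{p_1}{\hat F(p_1 \mid P_2 \le p_2)}\right\},$$

where $\hat F$ is the empirical cdf of $p_1$ within the cumulative stratum
of variants whose second p-value is at least as small as $p_2$ (inclusive
comparisons throughout; an empty stratum returns 1). The conjunction FDR —
the posterior probability that a variant is null for either trait or both —
is the maximum of the two conditional FDRs, the only concrete estimator
consistent with that verbal definition. Variants with conjunction FDR
below 0.05 are reported: five expected false discoveries per 100 reported.

For whole-genome work the estimator is evaluated on a binned 2-D lookup:
200 bins per axis on $-\log_{10} p \in [0, 20]$ (p floored at $10^{-20}$ to
avoid infinities), the direct estimator computed exactly at every grid
vertex, optional monotonization by running minima along both axes in the
direction of increasing significance, and clamped bilinear interpolation
(never extrapolated beyond the most significant bin). At the vertices the
lookup reproduces the direct estimator to machine precision, which is how
the two are cross-checked.

When an LD table is available, the empirical cdfs are estimated on a
randomly LD-pruned subset (greedy scan in a seeded random order, keeping a
variant unless it correlates at $r^2 > 0.2$ with an already kept one).
Without pruning, an associated 50-variant block contributes 50 copies of
essentially one observation to the joint tails, and the inflated cdfs make
mild joint signal look stronger than one locus of evidence warrants. This
follows the cited stratified-FDR tooling; per-variant results are still
reported for every variant by interpolation.

## Locus post-processing

Selected variants are ranked by conjunction FDR (ties broken by the
primary-trait p-value, then lexicographic rsID) and greedily clumped: a
variant is pruned iff it correlates at $r^2 > 0.2$ with a retained
higher-ranked variant. The result depends only on the total rank order,
not input order. The locus filter then (i) removes direction-discordant
loci — opposite effect signs after harmonization — and (ii) LD-deduplicates
the rest; the discordance filter runs first, matching how the published
analyses narrate their counts, though the order is configurable since it is
not logically forced. On the packaged 21-locus worked example this yields
the printed 5 discordant, 1 LD-pruned (the $r^2 = 1$ pair, tie resolved to
the lexicographically smaller rsID), 15 survivors, 8 on chromosome 6.
Nearest-gene annotation minimizes distance to user-supplied intervals
(distance 0 inside; ties to the smaller start, then name), with BED input
converted from 0-based half-open to 1-based inclusive coordinates.

## The synthetic-data generator

The simulator draws variants in LD blocks with exchangeable correlation:
within a block of size $B$, z-scores share correlation $r$ both in their
noise and through the smeared noncentrality
$\sqrt{n_t}\,(R\beta_t)$, $R$ the exchangeable correlation matrix. Causal
status is a four-component mixture over {null, trait-1-only, trait-2-only,
pleiotropic}; pleiotropic effect pairs are bivariate normal with
correlation $\rho$. P-values are two-sided normal tails, the case-control
convention. Defaults — 20,000 variants, blocks of 50 at $r = 0.8$
(pairwise $r^2 = 0.64$, comfortably above the 0.2 clumping threshold so
block structure is actually exercised), causal rates 0.5% per
trait-specific class and 0.2% pleiotropic, effect s.d. 0.05 on the log-odds
scale with effective sample sizes of 10,000 (so a causal variant's
noncentrality is $\sim N(0, 5)$, a strong GWAS locus), $\rho = 0.8$ — are
chosen once as a plausible mid-size case-control pair and used as the
standing study conditions throughout the tests and the acceptance script.
Exchangeable blocks keep every moment analytically checkable while still
producing LD-smeared signal for the pruning and clumping machinery.

What the generator does not emulate: realistic minor-allele-frequency
spectra and the MAF-dependence of power; variable LD within and between
blocks (every within-block pair has the same $r^2$, every between-block
pair is independent); population stratification beyond a scalar variance
inflation; binary-trait effect-size/frequency coupling. Passing tests on
these simulations therefore validate the estimators' logic and
calibration, not robustness to real-data artefacts.

Uniformity of null p-values is tested by Kolmogorov–Smirnov on one variant
per block: the KS test assumes independent observations, and within-block
correlation violates that by design, while the block subsample is exactly
independent. The null-calibration check uses the raw (uncapped) estimator
$p_1/\hat F(p_1 \mid p_2)$, whose null expectation is 1 by the $F(p) = p$
argument; the capped value is the reported FDR.

The expression-side generator produces a genes-by-samples matrix with
planted per-gene dosage slopes and group shifts, samples assigned
round-robin to three regions, and genotype dosages
$\mathrm{Binomial}(2, 0.3)$. The default cohort shape is 11 controls
against 17 cases, the size at which the pooled-region comparison is
expected to operate.

## Functional follow-up

Cis pairs are variants within 1 Mb (inclusive) of a gene's transcription
start site — interval start on the + strand, end on the − strand. The eQTL
test is an additive-model ANCOVA: a least-squares fit of expression on
dosage plus optional numeric covariates (none by default, as the source
datasets' covariates are unspecified), reporting the dosage slope, t and
two-sided p; perfect fits report the smallest positive double rather than
zero, and degenerate designs (constant dosage, too few samples) are flagged
per pair rather than failing the batch. The significance gate is strict
($p <$ threshold, default the pre-established Bonferroni level
$3.9\times10^{-5}$; equality fails). Differential expression pools samples
across regions — treating them as independent to maximize power at these
cohort sizes; a region-covariate variant sits behind a flag — and applies
Welch's two-sample t-test per gene, the standard two-group choice at
microarray scale (the test is injectable since the original analysis'
statistic is unstated); absent genes yield explicit not-available records,
and significance is marked at $p \le 0.05$. Cell-type assignment is the
argmax of a gene's mean expression over the eight surveyed CNS classes,
ties broken by a fixed canonical order (neurons, fetal astrocytes, mature
astrocytes, OPCs, newly formed oligodendrocytes, myelinating
oligodendrocytes, microglia/macrophages, endothelial, pericytes); genes
missing from the profile are reported "not found". The assignment is
invariant to positive per-gene rescaling, so expression units cancel.

## Evaluation design and known limitations

Simulation truth is evaluated at the block (locus) level: a reported lead
counts as a true discovery iff its LD block carries causal signal for both
traits — a pleiotropic variant, or co-located trait-1 and trait-2 causal
variants, which LD fuses into one jointly associated locus. Per-variant
class labels would misclassify a lead that tags a causal block.

The clearest limitation found in this evaluation: per-variant conjunction
FDR values are honest posteriors (selecting variants at conjFDR < 0.05
keeps the variant-level false proportion at its nominal level, ~0.06
measured at the default study conditions), but the subsequent clump-to-lead
step selects each block's *best* variant. A null or single-trait block gets
several quasi-independent chances for its minimum to cross the threshold,
while each truly pleiotropic block collapses to a single lead — so the
false proportion among lead loci (~0.27 under the default block structure)
exceeds the per-variant level. The effect shrinks as within-block
correlation approaches 1 (a block then behaves as one variant) and is
absent without LD. Users reading clumped locus lists should treat the
nominal threshold as a per-variant, not per-locus, guarantee; the
simulation drivers report both levels.

Problem sizes used in the packaged checks: 50 null replicates of 20,000
independent variant pairs for calibration; 100 (tests) or 30 (acceptance
script) replicates of 50,000 variants in 50-variant blocks for FDP and
power; 100,000 variants for inflation-factor recovery and null enrichment
bounds; a single planted pleiotropic block in 20,000 variants for the
region-exclusion contrast. The analysis drivers under `analysis/` run one
50,000-variant study end to end and write their tables under
`results/analysis/`.
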