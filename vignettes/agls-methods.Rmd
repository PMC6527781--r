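---
title: "AGLS single-marker association: model, decomposition and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AGLS single-marker association: model, decomposition and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aglsgwas)
```

## The model and the approximation

The phenotype analyzed is a *yield deviation*: a record with fixed
non-genetic effects (herd-year-season and the like) already removed by an
upstream evaluation system. For one SNP the model is

$$ y = \mu\mathbf{1} + X_g g + Z a + e, \qquad
   \mathrm{var}(y) = V = \sigma_a^2 Z A Z' + \sigma_e^2 I $$

with $g = (g_{11}, g_{12}, g_{22})'$ the genotypic values of the three
SNP genotypes, $a$ the additive polygenic values with relationship matrix
$A$, and $e$ iid residuals. The GLS estimator of the fixed effects and
the mixed-model-equation (MME) estimator are algebraically identical
(both are the BLUE), and the MME form can be written as ordinary least
squares on BLUP-adjusted phenotypes:
$\hat b = (X'X)^- X'(y - Z\hat a)$. Neither $V^{-1}$ nor $A^{-1}$ is
computable for cohorts of hundreds of thousands, so AGLS substitutes an
*external* polygenic estimate from routine genetic evaluation,
$\tilde a = 2\cdot\mathrm{PTA}$, and fits least squares on
$y^* = y - 2\cdot\mathrm{PTA}$. Two approximations are involved: the
external $\tilde a$ stands in for the in-sample BLUP, and the t-test uses
the least-squares rather than the GLS variance formula. The `oracle`
functions (`gls_blue()`, `mme_blue()`, `exact_contrast_t()`) implement
the exact estimators with dense algebra at small $n$ precisely so both
approximations can be measured: when the PTAs carry the exact BLUP, AGLS
reproduces the BLUE to machine precision (an identity, verified in the
test suite), and the AGLS-vs-oracle error shrinks as PTA reliability
rises.

## Contrast tests

Writing $P_{11}, P_{12}, P_{22}$ for genotype frequencies and $p_1, p_2$
for allele frequencies *of the analyzed individuals at that SNP*, the
additive contrast

$$ s_a = \left(\frac{P_{11}}{p_1},\;
   \frac{0.5\,P_{12}(p_2 - p_1)}{p_1 p_2},\;
   -\frac{P_{22}}{p_2}\right) $$

is valid under Hardy–Weinberg disequilibrium and reduces to
$(p_1,\, p_2 - p_1,\, -p_2)$ under equilibrium; it always sums to zero
because $p_1 = P_{11} + P_{12}/2$. The dominance contrast is the constant
$(-0.5, 1, -0.5)$. The statistic is
$t = |s'\hat g| / \sqrt{v^2\, s' (X'X)^-_{gg} s}$ with two-sided p-values
from the t distribution on $n-k$ degrees of freedom.

Numerical and inferential choices:

* **Cell-means parameterization.** The design $(\mu + \text{three class
  dummies})$ is rank-deficient; we drop $\mu$ and fit the three class
  means directly, making $X'X$ diagonal and $\hat g$ unique. All reported
  contrasts are invariant to this choice; $k$ = number of classes
  present.
* **Per-SNP residual variance.** $v^2 = \mathrm{RSS}/(n-k)$ from the same
  SNP's fit, not a shared null-model variance; with two classes the test
  degenerates gracefully to a two-sample comparison because absent
  classes have zero frequency and hence zero additive coefficient.
* **Dominance testability.** The dominance contrast needs all three
  classes observed; we additionally require a configurable minimum class
  count (`min_class_count`, default 5) so a near-empty heterozygote or
  homozygote cell cannot produce a wild statistic. At biobank scale the
  rule is inert; at simulation scale it matters.
* **Missing data.** Pairwise deletion per SNP: an individual missing this
  SNP's genotype (or the trait's phenotype/PTA) is dropped for this SNP
  (or trait) only, and frequencies are computed over the same individuals
  as the fit.
* **Extreme p-values.** The exact two-sided tail is evaluated in log
  space, but once it falls below $10^{-308}$ — the double-precision
  print floor that motivated the original workaround — reported
  significance switches to the empirical power law
  $\log_{10}(1/p) = 0.2416\, t^{1.9713}$ and the row is flagged
  (`empirical_p_used`). The coefficients are configurable, and
  `refit_empirical_coeffs()` re-estimates them from a run's own
  representable $(t, \log_{10}(1/p))$ pairs by log–log least squares.
  Over the representable range the law correlates with the exact tail at
  better than 0.999, so the extrapolation joins smoothly.

## Allelic decomposition

From $\hat g$ and the frequencies, the allelic means
$\mu_1, \mu_2$, the SNP mean $\mu = p_1\mu_1 + p_2\mu_2$, allelic effects
$a_i = \mu_i - \mu$, the average effect of gene substitution
$\alpha = \mu_1 - \mu_2 = s_a'\hat g = a_1 - a_2$, and the dominance
effect $\delta = g_{12} - (g_{11}+g_{22})/2$ are computed per SNP. Three
identities are enforced by tests on every run: the three routes to
$\alpha$ coincide, $p_1 a_1 + p_2 a_2 = 0$, and allele relabeling flips
$\alpha$ while leaving $\delta$ unchanged.

Allelic effects about a SNP's own mean are not comparable across SNPs, so
*comparable* effects replace $\mu$ with $\mu_{all}$, the unweighted mean
of $\mu$ over the reporting SNP set. We compute $\mu_{all}$ per trait
over SNPs passing the MAF ≥ 0.05 reporting filter, because comparability
is only ever invoked for reported SNPs; cross-trait effect rankings
(e.g. antagonistic-pleiotropy screens) use the comparable effects for the
same reason. The MAF filter never gates testing — the t-test already
accounts for frequency-driven variance, whereas raw allelic effects do
not, which is why rare-allele effect *sizes* are unreliable and only
their reporting is suppressed (flagged, never deleted).

Two classifications are attached. The **dominance mode** calls positive
(negative) overdominance when the heterozygote value lies above (below)
both homozygotes, complete dominance when it equals one homozygote within
a tolerance of 5% of the homozygote spread, and partial dominance in
between. The **allelic pattern** operationalizes a conceptual typology —
symmetric, asymmetric, uni-allelic — that was never given numeric
boundaries; we use the magnitude ratio
$r = \min(|a_1|,|a_2|)/\max(|a_1|,|a_2|)$ with uni-allelic at
$r \le 0.2$, symmetric at $r \ge 0.8$ with opposing signs, asymmetric
otherwise. Both thresholds are parameters of `agls_control()` and are
reported with the output; the defaults are our reading of "similar",
"larger than" and "neutral", nothing more.

## Conditional analysis

To separate linkage-disequilibrium shadows from independent signals, the
index SNP's estimated genotypic values are subtracted from $y^*$ class
by class and the region is rescanned on the residuals. A SNP in perfect
LD with the index has identical class membership, so its residual class
means are all zero and its conditional $t$ is exactly 0; the test suite
checks this limit, the idempotence of conditioning, and that unlinked
SNPs are essentially untouched. For the retention summary, "top
fraction" membership is fixed by the *unconditional* scan: per trait,
the cutoff is the $\lceil f \cdot n \rceil$-th largest unconditional
$\log_{10}(1/p)$, and a conditional result survives if it still exceeds
that cutoff. The alternative reading — re-deriving the threshold from
the conditional scan itself — would make the before/after counts
incommensurable, so the fixed-cutoff definition is used and documented
here. Individuals with a missing index genotype are dropped from both
arms to keep them comparable.

## What the generator emulates — and what it does not

`sim_config()`/`simulate_dataset()` produce cohorts with the structure
the method assumes:

* **Genotypes** drawn per SNP from
  $(p_1^2 + f p_1 p_2,\; 2 p_1 p_2 (1-f),\; p_2^2 + f p_1 p_2)$ — an
  inbreeding-style HWD parameterization ($f = 0$ is HWE, $f > 0$ excess
  homozygosity) exercising exactly the disequilibrium the additive
  contrast is built to absorb. A1 frequencies default to Uniform(0.1,
  0.5); LD blocks are induced by copying a source column with
  probabilistic redraws.
* **Polygenic values** built as standardized sums of many small
  background-locus effects on genotypes *independent of the tested
  panel* (so null-SNP calibration is exact by construction), scaled to
  $\sigma_a^2$; an `"mvn"` mode draws $a$ multivariate normal with an
  explicit, recorded relationship matrix for the oracle tests.
* **PTAs** as $\mathrm{PTA} = 0.5(r\,a/\sigma_a +
  \sqrt{1-r^2}\,z)\sigma_a$ with $r^2$ the stated reliability, so
  $\mathrm{cor}(2\,\mathrm{PTA}, a) = r$ and reliability 1 returns
  $a/2$ exactly.
* **Causal SNPs** parameterized directly by $(\alpha, \delta)$: class
  values $g = x(-2p_2,\, p_1 - p_2,\, 2p_1) + (0, \delta, 0)$ with $x$
  solved so the decomposition under the *realized* sample frequencies
  returns the requested $\alpha$ exactly. Antagonistic pleiotropy is a
  single SNP given opposite-sign $\alpha$ on two traits.

Default trait settings — $\sigma_a^2 = 1$, $\sigma_e^2 = 2$
($h^2 = 1/3$, typical of a production trait), reliability 0.8
(cows with own records plus ancestry) — are fixed study conditions, not
tuning dials. The generator does **not** emulate: real evaluation-system
PTAs (whose error structure comes from an 80-million-animal pedigree
evaluation, far richer than a single reliability), coalescent LD and
haplotype structure, selection, or pedigree loops. Passing tests
therefore certify the estimator's algebra and sampling behavior under
the stated model, not robustness to those real-data features.

## Problem sizes and test design

The suite's simulation sizes are chosen to make Monte-Carlo noise small
relative to the asserted tolerances while keeping a full run around a
minute: null calibration uses 2,000 SNPs × 2,000 individuals at
reliability 0.8 (binomial 95% interval on a 0.05 rate); effect recovery
uses 200 replicates of $n = 5{,}000$ at MAF 0.3 with the bias bound at
two Monte-Carlo standard errors; the oracle equivalence sweeps 50 random
instances of $n \le 200$; the end-to-end reproducibility check runs
5,000 × 2,000 × 2 traits twice and compares file hashes. Identity-style
properties (contrast zero-sums, decomposition identities, perfect-LD
annihilation) are asserted at $10^{-8}$–$10^{-12}$, i.e. at numerical
precision, not statistical tolerance.

## Known limitations

* AGLS inherits whatever stratification correction the PTAs encode; with
  low-reliability or biased external estimates the test drifts toward a
  plain least-squares GWAS.
* The per-SNP $v^2$ makes tests across SNPs slightly heteroscedastic in
  small samples; at the intended cohort sizes the effect is negligible.
* Only biallelic SNPs are supported; multiallelic VCF records are
  skipped with a warning.
* The conditional analysis removes one index SNP at a time; no joint or
  stepwise multi-SNP conditioning is provided.
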