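---
title: "Multiple-trait QTL detection by maximum bootstrap power: models and methods"
author: "mbpqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-trait QTL detection by maximum bootstrap power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbpqtl)
```

## The problem

A quantitative trait locus (QTL) rarely affects every trait measured on a
mapping population. The standard multiple-trait scan nevertheless fits a
QTL effect on all p traits at every locus and tests them jointly; each
truly null effect adds a degree of freedom without adding signal, so
power is lost exactly where multiple-trait analysis should help most —
when the QTL touches only a few traits. `mbpqtl` implements a family of
procedures that exclude *trivial* effects (zero or statistically
negligible) before the QTL test, centred on **maximum bootstrap power
(MBP)**: a resampling rule for choosing how many effects to keep.

The population is a panel of recombinant inbred lines (RILs): fully
homozygous, so each marker has two genotype classes, coded
$x_{nl} = +1/2$ (AA) or $-1/2$ (aa).

## Model and test statistics

At scanning locus $l$ the traits follow the multivariate regression

$$ y_{nk} = \beta_{0k} + x_{nl}\,\beta_{lk} + \epsilon_{nk},
   \qquad (\epsilon_{n1},\dots,\epsilon_{np}) \sim N_p(0, \Sigma), $$

with unrestricted positive-definite residual covariance $\Sigma$. The
joint test of a QTL on an *active* trait set $K$ constrains
$\beta_{lk} = 0$ for $k \in \bar K$ (the trivial set) and compares
against the no-QTL model by the likelihood ratio statistic
$T = N \log\left(\det\hat\Sigma_0 / \det\hat\Sigma_1\right)$, i.e.
$-2\times$ the log-likelihood difference under maximum-likelihood
(divide-by-$N$) covariance estimates, asymptotically $\chi^2_{|K|}$ under
the null.

One numerical point deserves emphasis. With effects on only part of the
traits, the constrained model is a seemingly-unrelated regression:
per-trait least squares does **not** maximize the joint likelihood, and
plugging OLS residual covariances into the determinant ratio produces
statistics that can decrease when an effect is added. The exact MLE is
available in closed form because the likelihood factorizes as
$f(Y_{\bar K}\mid 1)\, f(Y_K \mid 1, x, Y_{\bar K})$, each factor an
unrestricted multivariate regression. This collapses to the identity

$$ T(K) \;=\; T_{\text{full}}(\text{all } p \text{ traits})
           \;-\; T_{\text{full}}(\bar K \text{ traits alone}), $$

where $T_{\text{full}}(S)$ is the ordinary all-effects Wilks statistic
computed on the trait subset $S$. `mbpqtl` computes every statistic this
way, from two cross-product matrices per locus ($C_0$ for intercept-only
residuals and its rank-one update $C_1$ for the genotype regression),
with determinants via symmetric positive-definite factorization in
compiled code. Nestedness $T_{l1} \le T_{l2} \le \dots \le T_{lp}$ then
holds exactly, not just approximately.

**Backward elimination.** The *best k effects* at a locus are the
survivors after $p - k$ removals, each removal taking the effect whose
deletion reduces the joint LRT least. Ties (rare with continuous data)
remove the lower trait index, making scans deterministic. Forward or
stepwise selection would also fit this frame; backward elimination is
used because it starts from the full model that the comparison procedure
("All") fits anyway and is cheaper than stepwise search.

**Degenerate loci.** A locus that is monomorphic — including in a
bootstrap or jackknife resample — carries no information; all its
statistics are scored 0 (with a message) rather than erroring, so
resampling loops never abort. A singular residual covariance
(duplicated traits, $N \le p + 2$) is a hard error.

## Genome-wide thresholds

All thresholds come from permutations of whole genotype rows against
fixed phenotype rows, which preserves both the trait correlation and the
linkage disequilibrium among markers. One permutation pass records every
null quantity needed:

* $\lambda_k(\alpha)$: per effect count $k$, the $(1-\alpha)$ empirical
  quantile of the genome-wide maximum of the best-$k$ statistic. The
  quantile is the $\lceil (1-\alpha) B \rceil$-th order statistic
  (conservative, reproducible).
* $\lambda_k(\beta)$: the jointly calibrated version — a common
  per-family level $\beta \le \alpha$ such that the event "some locus
  and some $k$ exceeds" has probability at most $\alpha$, with equal
  exceedance probability across $k$. Because the empirical thresholds
  move only at order-statistic steps, the calibration is solved exactly:
  rank each permutation's maxima within their columns, take each
  permutation's worst-case rank, and set the common threshold index to
  the $\lceil (1-\alpha) B\rceil$-th order statistic of those worst
  cases. This is equivalent to the usual monotone bisection on $\beta$
  at the resolution limit $1/B$ of the permutation sample, but is
  deterministic and cannot fail to bracket. On independent columns it
  reproduces the Šidák level $1-(1-\alpha)^{1/p}$; on perfectly
  dependent columns it returns $\beta = \alpha$.
* $\tau(\alpha)$: the $(1-\alpha)$ quantile of the maximum over all
  (locus, trait) pairs of the individual-effect statistic (each effect
  given all others) — multiplicity-adjusted in both dimensions.
* Sequential thresholds: permuted data are pushed through the same
  least-significant-effect removal as real data; the statistic at the
  step with $k$ effects remaining is the drop $T_{lk} - T_{l,k-1}$, and
  the $p$ per-step thresholds are equalized and jointly calibrated with
  the same scheme as $\lambda_k(\beta)$. Many other admissible threshold
  schemes exist for sequential testing; this one mirrors the
  equal-probability constraint used for $\lambda_k(\beta)$ and controls
  the familywise rate by construction.
* BIC-style penalty: one-step forward selection on permuted data (the
  best single effect anywhere in the genome); the $(1-\alpha)$ quantile
  of these maxima is the fixed retention penalty.

## Detection procedures

* **All** — claim locus $l$ iff $T_{lp} > \lambda_p(\alpha)$.
* **MBP** — take $B$ nonparametric bootstrap samples (whole individuals
  with replacement, genotype and phenotype rows paired). For each $k$,
  $f_k$ is the fraction of samples whose best-$k$ statistic exceeds its
  genome-wide threshold; $k_0 = \arg\max_k f_k$, ties resolved as the
  integer part of the mean of the smallest and largest maximizer. The
  claim tests the *original* data's $T_{k_0}$ against
  $\lambda_{k_0}(\alpha)$. When effects are moderately large $f_k$
  saturates at 1, so the bootstrap exceedance can use the stricter
  $\lambda_k(\beta)$; the default switches this on for $p > 3$, and the
  final claim still uses $\lambda_{k_0}(\alpha)$, following the
  procedure's definition.
* **Indv** — claim iff any individual-effect statistic exceeds
  $\tau(\alpha)$; the exceeding traits are the associations directly.
* **Seq** — at each locus remove least significant effects one at a
  time, claiming when a step's drop exceeds its per-step threshold.
* **BICdelta** — backward elimination with the fixed penalty; claim iff
  any effect is retained.

## QTL-trait associations (idv)

After a locus is claimed, each nontrivial effect is tested given the
other nontrivial effects (trivial effects fixed at zero, hypotheses with
one degree of freedom), against $\chi^2_1(1 - \alpha/k_0)$ — Bonferroni
over the $k_0$ tested effects only. Trivial traits are reported
non-significant without testing. Because tests happen only at claimed
loci, the two-step procedure cannot raise the genome-wide type I error
for QTL detection; the Bonferroni factor $k_0 < p$ is what makes
MBP+idv more powerful than All+idv per trait. The error budget $\alpha$
is spent per claimed locus (not shared across loci), matching how the
follow-up test is defined.

## Synthetic data generator

The generator emulates a biparental RIL panel:

* **Genotypes.** First marker of each chromosome is a fair coin; along a
  chromosome, markers $d$ cM apart recombine with the RIL-by-selfing
  frequency $R = 2r/(1+2r)$, $r = (1-e^{-2d/100})/2$ (Haldane, no
  interference; the map-function choice is isolated in
  `rilRecombinationFreq()` so Kosambi could be swapped). Chromosomes
  segregate independently; lines are fully inbred, matching the
  $\pm 1/2$ coding. Real RIL genotypes (genotyping error, segregation
  distortion, residual heterozygosity) are *not* emulated.
* **Traits.** Rows are $\beta_0 + \sum_l x_{il}\gamma_l + \epsilon_i$
  with $\epsilon_i \sim N_p(0, \Sigma)$. `truncateAndScaleEffects()`
  reproduces the construction used to build realistic effect sets from a
  fitted model: keep $\hat\beta_{lk}$ when
  $|\hat\beta_{lk}|/\sqrt{\hat\sigma_{kk}} \ge 0.45$, scale survivors by
  $1/3$ (both parameters adjustable; scales $1/4$ and $1/2$ and random
  sign assignment, applied independently per entry, are reachable
  through the same interface). The standardization divides by the
  residual SD of the trait, the natural scale-free reading of the
  selection rule.
* **Calibrated specs.** `makeEffectSpec()` builds a spec from a target
  pattern of nonzero-effect counts and a per-trait variance-explained
  range: under $\pm 1/2$ coding with balanced alleles,
  $\mathrm{Var}(x) = 1/4$ and
  $h^2 = (\gamma^2/4)/(\gamma^2/4 + \sigma_{kk})$, solved for $\gamma$
  with one $h^2$ drawn per QTL (equal across its nonzero traits). The
  solution ignores covariance between linked QTL, so realized per-trait
  fractions are approximate when QTL share a chromosome. The default
  residual correlation is exchangeable with $\rho = 0.66$ — the median
  pairwise correlation of the motivating 16-gene expression panel —
  and the default $h^2$ range 0.2–5.9% matches that study's simulated
  per-trait QTL contributions.

Because the generator draws from exactly the model the tests assume
(multivariate normal residuals, marker-positioned QTL, complete data),
passing calibration suites demonstrates internal correctness of the
procedures, not robustness to real-data violations such as
non-normality, missing genotypes, or QTL between markers.

## Study profiles and numerical choices

The Monte Carlo drivers (`type1ErrorStudy()`, `powerStudy()`) re-estimate
all thresholds inside every replicate, as a faithful simulation of the
full analysis pipeline. The package's desk-scale default profile is
$N = 100$ individuals, $p = 8$ traits, $L = 30$ markers on 5 chromosomes
(10 cM spacing), 300 permutations, 100 bootstraps and 100 replicates:
small enough that the complete studies run in a few minutes on one core,
large enough that a 95% binomial interval around a 5% rate
($\pm 4.3$ percentage points) is informative. The power scenario scales
the motivating study's nonzero-effect pattern (1, 11, 16, 3, 7 of 16
traits) to $p = 8$ as (1, 6, 8, 3, 4), one QTL per chromosome. At full
scale the corresponding settings would be $N = 211$, $p = 16$, $L = 95$,
1200 permutations, 250 bootstraps and 250 replicates.

Other choices made where the design was genuinely open:

* MLE (divide-by-$N$) covariance estimates, so the statistic is exactly
  $-2\Delta$ log-likelihood; REML-style estimates would differ by
  $O(1/N)$ and break the determinant identity above.
* The oracle mode of `powerStudy()` that fits exactly the true nonzero
  set is scored against that fixed set's own permutation threshold
  (`fixedSetThresholds()`); the selected best-$k$ null is stochastically
  larger and would handicap the oracle.
* Permutation seeds, bootstrap seeds and per-replicate seeds are all
  derived from one master seed by fixed integer substreams, so every
  study is bit-reproducible and replicates are order-independent.
* The delete-1 jackknife summary zeroes per-locus relative frequencies
  below 0.25 by default (configurable); the relative frequency is a
  comparative surrogate for power, not an estimate of it.

## Known limitations

* Scans test marker positions only; interval-mapping mixture likelihoods
  between markers are out of scope.
* No covariates, no kinship/mixed-model correction, no epistasis, no
  multi-QTL joint models across loci.
* Missing genotypes or phenotypes are rejected, not imputed;
  heterozygous classes are rejected (RIL coding).
* When the true nonzero count equals $p$ and effects are large, the
  bootstrap frequencies saturate and the tie rule pulls $k_0$ toward
  $(1+p)/2$: MBP's tendency to *over*estimate the nontrivial count
  applies where selection has headroom ($m < p$), and its QTL claim
  (which uses the best-$k_0$ statistic, not the count) is what the
  procedure controls.
* $f_k$ from bootstrap samples overestimates exceedance probabilities
  relative to independent replicates; it is used only to rank $k$, never
  reported as power.

## A worked desk-scale example

```{r example, eval = FALSE}
map <- deskMap()                         # 30 markers, 5 chromosomes
spec <- makeEffectSpec(map, qtlLoci = c("m2", "m9", "m21"), p = 8,
                       nzeCounts = c(1, 6, 3), seed = 42)
g <- simulateRILGenotypes(map, n = 100, seed = 1)
y <- simulateTraits(g, spec, seed = 2)
cross <- qtlCross(g, y, map)

thr <- estimateThresholds(cross, alpha = 0.05, nPermutations = 300,
                          seed = 3)
res <- mbpDetect(cross, thr, B = 100, seed = 4)
res$detection
associationTests(res$detection, cross)
```
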