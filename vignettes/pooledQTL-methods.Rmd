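---
title: "Mapping QTLs from pooled segregants: models and design choices"
author: "pooledQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTLs from pooled segregants: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In bulk segregant analysis with sequencing (BSA-seq), a diploid hybrid of a
*superior* and an *inferior* parent strain is sporulated, haploid segregants
are phenotyped, and DNA from a pool of the phenotypic extremes is sequenced
together with the superior parent.  At every SNP that distinguishes the
parents, the *variant frequency* -- the fraction of pooled reads carrying
the superior parent's (non-reference) allele -- is ~50% under random
segregation.  Genomic regions where the selected pool deviates from 1:1
harbour quantitative trait loci (QTLs): upward deviations point at
causative alleles from the superior parent, downward deviations at
recessive deleterious alleles that the superior parent happens to carry
(QTLs "linked to the inferior parent").  An *unselected* pool of the same
size ("pool 0") is sequenced as a baseline: contrasting a selected pool
against it absorbs systematic wave-like frequency artefacts, so inference
is on the log odds ratio between the pools rather than on raw deviations
from 50%.

`pooledQTL` implements this analysis as four layers -- marker filtering,
frequency smoothing, simultaneous Monte-Carlo inference with QTL calling,
and individual-segregant fine mapping -- plus a synthetic cross generator
that makes every layer testable by parameter recovery.

# Marker filter

A SNP is usable as a marker only if the superior parent's own sequencing
supports it cleanly: total depth at least `minCoverage` (default 20 reads;
20-fold coverage compensates sequencing errors by the weight of correct
reads) and a variant-read fraction of at least `minRatio` (default 80%).
Both comparisons are inclusive, and the filter is applied to the parent
only -- the pools' frequencies are the quantity under study and must be
free to vary.  Markers missing from a pool are kept with (0, 0) counts and
zero likelihood weight, so all pools share one marker frame.

# Smoothing model

Per pool and chromosome, variant reads at marker $i$ are modelled as
$v_i \sim \mathrm{Binomial}(n_i, p(x_i))$ with
$\operatorname{logit} p(x) = \eta(x)$ expanded in a cubic B-spline basis
with 20 interior knots placed at marker-position quantiles.  The
coefficients maximise the binomial log-likelihood minus
$\lambda\,\|\Delta^2\beta\|^2$ (a second-order difference penalty), fitted
by penalised IRLS with step halving on the penalised deviance.  $\lambda$
is selected by minimising the effective-df--corrected deviance
$D(\lambda) + 2\,\mathrm{edf}(\lambda)$ over a log-spaced grid
($10^{-4}$--$10^8$), warm-starting each fit from the previous one.

Numerical choices:

* Saturated stretches (all reads variant) are kept finite by capping
  $|\eta|$ at 15 during iteration and for reporting frequencies; no
  pseudo-counts are added, so interior fits are unbiased.
* The penalty nullspace contains linear trends, so the extreme-smoothing
  limit is the linear-logit fit; for trend-free data it is exactly the
  constant logit of the pooled frequency.
* Convergence is declared on a relative penalised-deviance change below
  $10^{-8}$ or a sup-norm change of $\eta$ below $10^{-6}$; failure to
  converge raises an error carrying the deviance trace.

The model-based coefficient covariance is the inverse penalised
information $V_m = (X^\top W X + \lambda S)^{-1}$; `predictFit()` reports
standard errors from it (so doubling all counts at fixed effective
smoothing halves the variance exactly).

# Why read noise alone is not enough: finite pools

A sequenced pool is not an infinite population: it is DNA from $N$ (here
58) recombinant genomes.  Its realised allele-frequency curve wanders
around the population expectation with variance $p(1-p)/N$ per marker and
strong spatial correlation -- under a no-interference (Haldane) crossover
model the correlation between markers at genetic distance $d$ Morgans is
$e^{-2d}$.  Because this wander is *smooth* on the scale the spline
resolves, a fitted curve faithfully tracks it, and confidence bands built
from read-sampling variance alone are far too narrow: in our null
simulations (two pools of 58 segregants, coverage 100) such bands covered
the true zero contrast in 0% of replicate genomes and flagged spurious
"QTLs" in more than half of them.  Pool composition noise, not read depth,
is the dominant uncertainty of 58-segregant BSA-seq.

The inference layer therefore uses the sampling covariance of the
penalised estimator with both noise sources (a sandwich form):
$$V_{\text{tot}} = V_m\,\bigl(X^\top W X + X^\top W K W X\bigr)\,V_m,
\qquad
K_{ij} = \frac{e^{-2\rho\,|x_i - x_j|}}{N\sqrt{p_iq_ip_jq_j}},$$
where $\rho$ is a genome-averaged recombination rate in Morgans per bp
(config `morgansPerBp`; default $4\times10^{-6}$, i.e. 0.4 cM/kb, a
yeast-like value) and $p_i$ the fitted frequencies.  For a parent sample
($N = \infty$) the composition term vanishes.  Measured on null
simulations, simultaneous bands built from $V_{\text{tot}}$ cover the zero
contrast in ~97% of genomes at the nominal 95% -- mildly conservative,
never anticonservative.

# Simultaneous inference and threshold testing

For a selected pool $q$ against pool 0 the contrast is
$\hat c(x) = \hat\eta_q(x) - \hat\eta_0(x)$ (a log odds ratio), with
$\operatorname{Var}\hat c = \operatorname{Var}_q + \operatorname{Var}_0$
(independent pools).  Simultaneous bands are sup-t Monte-Carlo bands:
draw `nSims` coefficient-error vectors from
$N(0, V_{\text{tot},q}) \oplus N(0, V_{\text{tot},0})$, form the sup over
the evaluation grid of $|\text{simulated } \hat c|/\mathrm{SE}$, and take
the $(1-\alpha)$ quantile $z^*$; the band is $\hat c \pm z^*\mathrm{SE}$.
On a single-point grid $z^*$ reduces to the two-sided pointwise normal
critical value.  The default is $10^6$ draws for publication-grade
profiles and $10^4$ for desk-scale analyses and the test-suite; with
$10^4$ draws the $z^*$ Monte-Carlo error is ~1%.

Statistical significance alone does not establish biological relevance,
so p-values are computed relative to a threshold $\delta$ on the log odds
ratio (the TREAT idea): the observed statistic is
$t(x) = \max(0,\,|\hat c(x)| - \delta)/\mathrm{SE}_0(x)$ and its adjusted
p-value is the Monte-Carlo probability that the *genome-wide* null sup
statistic (the per-draw maximum over chromosomes, computed in the same
Monte-Carlo pass as the bands) exceeds $t(x)$.  Inside the threshold
region the p-value is 1 by definition.  The default
$\delta = 0.4088$ is the conventional printed constant for an odds ratio
outside $[2/3, 3/2]$ -- equivalently a pool frequency outside
[40%, 60%] against an unselected pool at 50% -- although
$\ln(3/2) = 0.4055$; the constant is config-exposed and the 4th-decimal
discrepancy between the two conventions is documented rather than
resolved.

Two standardisations appear above, deliberately:

* the *band* uses each pool's own (Wald) variance -- it estimates the
  contrast;
* the *p-value* uses the variance under the random-segregation null
  ($\mathrm{SE}_0^2 = 2\times$ the unselected pool's variance, both pools
  behaving like pool 0), a score-type convention.  At a strongly selected
  locus the pool frequency saturates and the Wald variance of a
  near-infinite log odds ratio diverges, which would erase power exactly
  where the signal is strongest; under the null the two standardisations
  coincide, so familywise error control is unaffected.  This assumes
  comparable read depth across pools, as in the emulated design.

QTL calls are maximal runs of grid points with $p < \alpha$ and constant
contrast sign; runs separated by a single non-significant grid point
merge; optional masked intervals (e.g. subtelomeric repeat regions, which
deviate even in unselected pools for mapping reasons) are removed before
calling.  The call direction follows the contrast sign at the peak:
positive means the causative allele comes from the superior parent.

# Fine mapping in individual segregants

Scored SNPs in individually genotyped segregants are summarised by the
association percentage $k/n$ (superior-parent calls among non-missing
calls; missing calls are dropped per SNP, matching designs where $n$
varies by locus), an exact binomial test of $k \sim \mathrm{Bin}(n, 1/2)$
with the symmetric two-sided convention
$p = \min(1,\,2\min(P(X\le k), P(X\ge k)))$, and Benjamini--Yekutieli FDR
adjustment across the scored set (valid under arbitrary dependency;
`fdrAcross = "all"` pools the family across all genotyped SNPs instead).
The printed FDR values of published per-QTL tables depend on the unknown
total number of tests in each experiment, so the package's tests pin the
raw test and the BY formula, not reproductions of printed adjusted values.

# The synthetic cross generator

The generator emulates the two-round design of downgraded-parent QTL
mapping so that recovery of a known architecture is a routine test:

* **Meiosis**: crossovers per chromosome are Poisson with mean equal to
  the genetic length in Morgans, placed uniformly in bp (no interference);
  the leftmost origin is a fair coin.  This matches the Haldane
  correlation assumed by the inference layer.
* **Phenotype**: baseline plus $|e|$ for each QTL whose beneficial allele
  is carried (superior allele for $e > 0$, inferior for $e < 0$), plus
  Gaussian noise.  A QTL with an epistatic mask contributes nothing
  whenever the masking locus carries the superior allele -- complete
  masking, the qualitative allele-specific pattern seen in such crosses.
* **Selection**: the top `poolSize` phenotypes (seeded tie-break), or all
  segregants above a threshold; the unselected pool is a seeded random
  sample, since published designs do not state how unselected pools are
  drawn.
* **Sequencing**: coverage Poisson per marker; each read reports the
  wrong allele with probability `seqError` (default 0.002).
* **Downgrading** neutralises a QTL's *effect* (every segregant behaves
  as if carrying the inferior allele) while marker inheritance is
  untouched -- exactly why a fully downgraded QTL shows ~50% frequency in
  the second round while its flanking markers still segregate.

The default scenario is a stylised 16-chromosome genome (300 kb and 1.2
Morgans per chromosome, 125 evenly spaced markers each, 2,000 markers
total -- a desk-scale stand-in for ~50,000 genome-wide SNPs), with 950
segregants in the first cross, 2,464 in the downgraded-parent cross,
58-segregant pools and 100x mean coverage.  The architecture is one
dominant superior major QTL (effect 2.0, also the epistatic masking
locus), one inferior-linked major (-1.2), and two minors (0.35 and a
masked 0.5-0.8), with noise SD 0.3.  Effect sizes were chosen so that the
major loci reach near-complete association in 58 selected segregants
(mirroring a 100%-association major QTL) while the masked minor is
invisible in round one and unambiguous in round two; a calibrated
58-segregant test genuinely cannot detect QTLs at ~75% association, which
is worth remembering when interpreting weaker published associations.

What the generator does *not* emulate: read-level errors tied to
alignment or repeats (subtelomeric artefacts are handled by masking, not
modelling), crossover interference, segregation distortion unrelated to
the phenotype, and library-preparation biases.  Passing recovery tests on
synthetic data therefore demonstrates the statistical machinery, not
robustness to alignment artefacts in real data.

# Problem sizes used by the checks

The packaged calibration checks run 200 null replicate genomes for band
coverage (one chromosome, 300 markers) and familywise error (four
chromosomes, 150 markers each), both with two pools of 58 segregants at
coverage 100 and $10^4$ Monte-Carlo draws; the mean-frequency check uses
2,000 markers over four chromosomes.  The end-to-end recovery check runs
the full default scenario twice (both crosses) and maps both rounds.
These sizes keep a complete run in minutes on one CPU while leaving the
Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* The composition covariance assumes a uniform genome-averaged
  recombination rate and Haldane's model; real hotspot structure will
  locally mis-scale the correlation length (the variance level, which
  dominates calibration, only depends on pool size).
* Plain binomial read sampling: no overdispersion beyond the composition
  term (e.g. PCR duplicates), no base-quality modelling.
* The score-type p-value standardisation assumes selected and unselected
  pools have comparable coverage designs.
* Each (pool, chromosome) is fitted independently; no information is
  shared across pools, and the two crosses are never modelled jointly.
* `delta`, `alpha`, knot count and the recombination rate are exposed in
  the configuration; all other constants are internal by design.
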