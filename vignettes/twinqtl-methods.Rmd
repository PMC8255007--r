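---
title: "Models and methods behind twinqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind twinqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinqtl)
```

# The trait and the model

Multiple birth in cattle is a rare binary outcome of a calving (a few
percent of calvings produce twins or triplets). Genetically it decomposes
into a *direct* component — the calf's own genotype (`mbd`) — and a
*maternal* component — the dam's genotype acting on the pregnancy (`mbm`).
The maternal component is the larger one, which makes sense biologically:
twinning is mostly driven by the dam's ovulation rate.

`twinqtl` fits the classical direct–maternal animal model to 1/2-coded
birth records:

$$
\mathbf{y} = \mathbf{Xb} + \mathbf{Wh} +
\mathbf{Z_d}\,\mathbf{mb_d} + \mathbf{Z_m}\,\mathbf{mb_m} +
\boldsymbol\epsilon,
$$

with fixed effects $\mathbf b$ (parity capped at "5+", season of birth,
sexed-semen use, and an age-of-dam covariate), a random herd-year effect
$\mathbf h \sim N(0, \mathbf I\sigma^2_h)$, and jointly distributed direct
and maternal breeding values

$$
\begin{pmatrix}\mathbf{mb_d}\\ \mathbf{mb_m}\end{pmatrix}
\sim N\!\left(\mathbf 0,\;
\begin{pmatrix}\sigma^2_a & \sigma_{am}\\ \sigma_{am} & \sigma^2_m
\end{pmatrix}\otimes \mathbf A\right),
$$

where $\mathbf A$ is the pedigree numerator-relationship matrix. Fitting a
linear model to a binary code is a deliberate, field-standard compromise:
it produces usable rankings even though the response is not Gaussian; a
threshold model is out of scope here.

Heritabilities are computed as $h^2 = \sigma^2_g/\sigma^2_p$ with
$\sigma^2_p = \sigma^2_h + \sigma^2_a + \sigma^2_m + \sigma_{am} +
\sigma^2_e$. The covariance enters once: for a record on a non-inbred calf,
the calf's direct value and its dam's maternal value each enter the record
once and their relationship is 1/2 in both directions, so the covariance
contributes $2\cdot\tfrac12\,\sigma_{am}$. The package treats the reported
"correlation animal/dam" figure of the reference component set as the
covariance $\sigma_{am}$: its magnitude (-1.58e-4) is far below any
plausible correlation given the component sizes, and only the covariance
reading keeps the component set internally consistent.

# REML with Monte-Carlo trace estimation

`reml_variance_components()` maximizes the restricted likelihood with
average-information (AI) steps after a short expectation–maximization
warm-up (default 3 iterations; EM is slow but monotone and safe far from
the optimum, AI is quadratically fast near it).

All quantities flow through Henderson's mixed-model equations with sparse
Cholesky factorizations (supernodal CHOLMOD, one symbolic analysis reused
across iterations):

* the restricted log-likelihood is exact:
  $-2\ell = n\log\sigma^2_e + \log|\mathbf G| + 2\log|\mathbf A| +
  \log|\mathbf C| + \mathbf y'\mathbf{Py}$, with $\log|\mathbf C|$ read off
  the sparse factor;
* the AI matrix is exact, built from the five working variates
  $\mathbf V_i\mathbf{Py}$, each requiring one extra solve;
* only the gradient's trace terms $\mathrm{tr}(\mathbf{PV}_i)$ are
  estimated, by a Hutchinson estimator with Rademacher probes
  ($z'\mathbf V_i\mathbf P z$, one multi-right-hand-side solve for all
  probes). The probe set is drawn once per fit from a seed derived from the
  response, so a fit is fully reproducible and invariant to record order,
  while the small Monte-Carlo perturbation is independent across datasets
  and averages out over replicated experiments.

Products $\mathbf A\mathbf x$ (needed for $\mathbf V_i$) are computed by
solving with a cached factor of the sparse $\mathbf A^{-1}$ rather than by
forming the dense $\mathbf A$.

Numerical safeguards: variances are floored at $10^{-10}\,\mathrm{var}(y)$;
the covariance is kept inside $0.99\sqrt{\sigma^2_a\sigma^2_m}$; AI steps
pass through a multiplicative trust region (no variance moves by more than
a factor of five per step) and are halved up to eight times if they do not
improve the likelihood, after which an EM update is taken. Convergence is
declared when the relative change of the exact restricted log-likelihood
of an accepted step falls below `tol` (default 1e-8; the recovery
experiments in this package use 1e-6, which at their likelihood scale is
about 0.05 log-likelihood units — far below the resolution at which the
variance parameters are statistically determined). Two diagnostics are
attached to every fit: the Newton decrement along the feasible step
direction — the likelihood gain the next step could still realize — and
its Monte-Carlo noise floor (estimated by splitting the probe set in
half); a decrement well above the noise floor flags a fit parked on a
flat ridge rather than at a sharp optimum. Non-convergence raises an
error carrying the full iteration trajectory.

`build_a_inverse()` assembles $\mathbf A^{-1}$ directly by Henderson's
rules with exact Meuwissen–Luo inbreeding coefficients (compiled ancestor
tracing), never forming $\mathbf A$; `blup_solve()` solves the same
equations at fixed components and obtains prediction-error variances by
dense inversion of the coefficient matrix, which is exact and affordable at
the scales this package targets (guarded at 8000 equations). Reliabilities
are $r^2 = 1 - \mathrm{PEV}/\sigma^2_g$ clamped into $[0,1]$.

# Standardization, trend, and de-regression

Standardized breeding values put a *base group* — by default the 8- to
10-year-old sires with breed fraction at least 7/8, mirroring routine
practice for calving traits — at mean 100 and standard deviation 12; the
same affine map is applied to all animals, so the contract on the base
group holds exactly by construction. The evaluation year defaults to the
newest birth year in the pedigree. The genetic trend is the per-birth-year
mean of standardized values.

De-regression follows the parent-average/individual two-equation
information system: the parent average carries reliability
$(r^2_s + r^2_d)/4$, effective information contents are solved from the
two reliabilities with $\lambda = (1-h^2)/h^2$, and the de-regressed proof
is the individual equation's right-hand side over its own information. For
founders this collapses to the classical $\mathrm{EBV}/r^2$. The weight
$w = (1-h^2)\,/\,[(c + (1-r^2_{\mathrm{DRP}})/r^2_{\mathrm{DRP}})\,h^2]$
uses $c = 0.5$ by default — the fraction of genetic variance not captured
by markers is not knowable in advance, and 0.5 is the conventional middle
ground; it is configurable. Animals whose reliability does not exceed
their parent-average reliability carry no own information and are excluded
with a report rather than silently kept. The reliability filter for the
association response keeps records at $r^2 \ge 0.35$ (inclusive).

# The genome scans

The single-SNP scan is the standard mixed-model association design: a
VanRaden method-1 genomic relationship matrix on centered dosages, one
REML fit of the polygenic null model through the eigendecomposition of
that matrix, then per-marker generalized least squares in the rotated
space with variance components fixed at the null fit (a single rotation,
no per-marker REML). Per-marker exactness of this approximation is the
usual trade-off; the calibration suite checks the empirical type-I error.
The reported "variance" column is the variance explained on the response
scale, $2p(1-p)\hat\beta^2$, reported for ranking but never used as a test
statistic. Bonferroni significance keeps $p \le \alpha/n_{\mathrm{tests}}$.

The BayesB sampler implements the per-locus mixture prior: with
probability $\pi$ (default 0.989) a locus has zero effect; otherwise its
effect variance follows a scaled inverse chi-square (default degrees of
freedom 4.2, scale derived from an assumed genetic-variance share of the
response and the marker heterozygosity). The locus variance is sampled by
Metropolis–Hastings with the effect integrated out (proposals from the
prior, so the acceptance ratio is a likelihood ratio), the effect from its
conditional normal, and the residual variance from its conditional each
iteration. Window variances are computed per stored iteration as the
variance over animals of the window's genomic value; proportions are
normalized within iteration, so they sum to one exactly, which is what
makes the window statistics well defined: `p_gt0` is the share of
iterations in which the window carries any effect, `p_gt_average` the
share in which it exceeds the equal-split share $1/n_{\mathrm{windows}}$.
Windows are megabase bins by default (the boundaries reported for the real
trait are megabase-aligned); a window of 25 consecutive SNPs is available
as an alternative mode. Significance at 5%/1% is mapped to
`p_gt_average` at 0.95/0.99; this mapping is this package's construction,
chosen to make the published criterion operational.

The sliding-haplotype scan enumerates all odd window lengths (default 9 to
301 SNPs) at every SNP-wise start inside a segment, tallies the distinct
phased haplotype strings per window, and tests each string with frequency
at least `min_freq` (default 0.05 — a GLS fit on a near-singleton
haplotype is degenerate; the floor is configurable down to $1/2n$) using
exactly the same rotated GLS core as the single-SNP scan. Because windows
whose focal haplotypes have identical carrier patterns produce identical
regressors, they produce identical statistics — the mechanism behind the
blocks of tied top rows seen in such scans. Ties are ordered
longer-window-first, then by position, to make the top-K export stable.

# Fine-mapping

Sequence-panel QC applies, in order, each rule counted on the survivors of
the previous one: variant missingness > 0.1, minor allele frequency
< 0.01, sample missingness > 0.1, then Mendelian error rate > 0.02 for
samples and finally variants. Duo errors are opposing homozygotes; trio
errors are child genotypes impossible under one-allele-from-each-parent
transmission. LD between the top haplotype's diplotype (0/1/2 copies) and
each variant is the squared Pearson correlation on dosages over
pairwise-complete samples — a diplotype is a genotype-level object, so
genotypic $r^2$ is the appropriate measure, and it is invariant to allele
relabeling on either side. Per-breed frequencies are reported for breeds
with at least 50 genotyped samples. Coordinates are 1-based inclusive
throughout.

# The herd simulator

The simulator exists so that every stage of the pipeline can be exercised
against planted ground truth:

* **Pedigree** — founder cohort, then breeding cycles mapped onto calendar
  years. An active dam cohort calves once per year and is partially
  replaced by young females each cycle (`dam_replacement_rate`, default
  0.15 — roughly a six-year productive life, a realistic herd turnover);
  this is what gives dams the repeated records that identify the maternal
  variance. Sires are drawn with replacement from the male pool, creating
  large paternal half-sib families. Seasons derive from a uniform birth
  month (Mar–May spring, Jun–Aug summer, Sep–Nov fall, Dec–Feb winter);
  parity is the dam's calving count capped at "5+".
* **Genotypes** — founder haplotypes come from a finite pool with block-LD
  structure (blocks of `block_span` bp, a few allele patterns per block);
  descendants are gene-dropped with Poisson recombination at 1 cM/Mb. A
  planted QTL haplotype is a fixed allele string across a window carried
  by a fixed fraction of pool haplotypes, so its population frequency
  matches the target up to drift and sampling.
* **Phenotypes** — the latent record value is exactly the animal model
  above: Gaussian mode emits it directly (so recovery experiments run
  under a correctly specified model), binary mode thresholds it at the
  empirical quantile matching the target prevalence (3.56% by default).
  Breeding-value pairs are sampled down the pedigree with exact
  inbreeding-adjusted Mendelian-sampling variance. The planted haplotype
  adds its effect to the dam's maternal value per carried copy. The
  default effect (-0.0226 response units per copy at frequency 0.275)
  makes the QTL's share of the maternal genetic variance about 16%,
  matching the scale of the mapped locus.
* **Sequence panel** — "linked" variants copy each gamete's
  planted-haplotype indicator with a per-variant flip rate, which gives a
  directly controllable $r^2$ ladder against the haplotype (flip 0.02
  lands near $r^2$ 0.86, the scale of the real top variant); independent
  variants are unlinked noise. This construction intentionally trades
  Mendelian inheritance of the panel variants for exact LD control:
  Mendelian-error QC is therefore validated on dedicated fixtures with
  planted violations, not on the flip-ladder panel.

What the simulator does *not* model: coalescent genealogy, selection over
generations, genotyping error beyond panel missingness, or multi-breed
admixture beyond static breed fractions averaged down the pedigree.
Passing recovery tests on these data therefore demonstrates correctness of
the estimators under the assumed model, not robustness to the many ways
real herdbook data violate it (non-random mating, preferential treatment,
incomplete pedigrees, imputation error).

# Problem sizes and experiment design

The validation experiments are sized for a desk machine. The REML recovery
experiment uses 10 replicates of 20,000 records (about 50 herds over five
years, some 4,200 dams with 4–5 records each, 24,300 pedigree animals,
and a 48,900-equation mixed-model system): at this size the maternal
heritability is recovered with a per-replicate standard error near 25%,
so it is the replicate mean that is informative — a single replicate is
not. The genome-scan experiments use 1,500–1,900 animals and a few
hundred markers; BayesB validation chains run a few thousand iterations
(the production default is 21,000 with 1,000 burn-in). The haplotype-scan
checks restrict window lengths to the lower end of the 9–301 grid, which
exercises the identical enumeration and testing path at a fraction of the
cost.

# Known limitations

* The linear model on a 1/2 code is a working approximation for a binary
  trait; a threshold or generalized linear mixed model is explicitly out
  of scope.
* Reliabilities use exact prediction-error variances from the inverted
  coefficient matrix; this is exact but dense, so it is deliberately
  capped at desk scale rather than approximated.
* The trace terms of the REML gradient are Monte-Carlo estimates; the
  likelihood, solutions and AI matrix are exact. Near-flat likelihood
  surfaces (tiny components, few records) converge through the EM
  fallback, which is slow; the iteration trajectory is attached to both
  results and error objects for inspection.
* With `pi` near 1 and short chains, BayesB posterior inclusion
  frequencies are noisy; the defaults favour reproducibility (fixed seed)
  over chain-length heroics, and no convergence diagnostics beyond the
  stored samples are provided.
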