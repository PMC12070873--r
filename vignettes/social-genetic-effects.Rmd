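---
title: "Estimating social genetic effects on residual feed intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating social genetic effects on residual feed intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgeRFI)
```

## The problem

In group-housed pigs an animal's feed efficiency depends not only on its
own genes but on the genes of its pen mates: a dominant animal that
monopolises the feeder changes how everyone else in the pen eats. The
heritable part of that influence is the *social genetic effect* (SGE),
also called an indirect genetic effect; the heritable effect of an
animal's genotype on its own phenotype is the *direct genetic effect*
(DGE). Classical animal models estimate only the direct component and can
mis-rank animals for socially affected traits such as residual feed
intake (RFI).

`sgeRFI` implements the full analysis chain for this problem: electronic
feeder-log processing with day-level quality control, trait derivation,
a displacement-based dominance score, RFI with fixed literature
coefficients, the direct+social animal model fitted by REML with BLUP
breeding values, HPD-based selection of socially extreme animals, and
nine-quadrant transcript-protein concordance for downstream omics
comparisons — plus a synthetic-data generator so that every stage is
testable without access to raw farm records.

## The model

For phenotype vector $y$ (RFI, g/day):

$$y = Xb + Z_d a_d + Z_s a_s + Wl + Vg + e$$

* $b$: fixed contemporary-group effects (tested year-month), coded
  intercept + drop-first contrasts;
* $a_d, a_s$: direct and social breeding values over the pedigree with
  $\mathrm{var}\,(a_d', a_s')' = G_0 \otimes A$, where
  $G_0 = \begin{pmatrix}\sigma^2_{Ad} & \sigma_{Ads}\\ \sigma_{Ads} &
  \sigma^2_{As}\end{pmatrix}$
  and $A$ is the additive relationship matrix from the pedigree (tabular
  method; unknown parents are unrelated non-inbred founders);
* row $i$ of $Z_s$ carries a 1 at each of $i$'s pen mates and 0 at $i$
  itself — no dilution by pen size is applied, since the model is used
  with near-constant pen sizes and the reference analysis has no dilution
  term;
* $l, g, e$: litter, pen and residual effects, independent
  $N(0, I\sigma^2)$.

Derived parameters: the direct-social genetic correlation
$r_{Ads} = \sigma_{Ads}/\sqrt{\sigma^2_{Ad}\sigma^2_{As}}$ and the total
genetic variance for a group of size $n$,
$\sigma^2_{TBV} = \sigma^2_{Ad} + 2(n-1)\sigma_{Ads} +
(n-1)^2\sigma^2_{As}$, reported at the mean pen size when pens are
unequal (a per-pen variant is available through the `n` argument).

## Estimation

`reml_fit()` (and the formula front end `sge_reml()`) maximises the
restricted likelihood

$$\ell_R = -\tfrac12\left(\log|V| + \log|X'V^{-1}X| + y'Py +
(n-p)\log 2\pi\right)$$

over the six variance components with average-information (AI) updates.
Numerical choices, in order of consequence:

* **Parameterization.** The genetic block uses a log-Cholesky
  parameterization ($G_0 = LL'$ with $\log$ diagonal), litter/pen/residual
  variances log scale. Every iterate is therefore admissible and
  $|r_{Ads}| \le 1$ holds throughout, with no constrained optimisation.
* **Damping.** AI proposals are damped Levenberg-Marquardt style: the
  ridge on the AI matrix is raised until a step does not decrease
  $\ell_R$ and relaxed after clear improvements. The accepted path is
  monotone in $\ell_R$. When no damped step improves, one derivative-free
  (Nelder-Mead) pass is tried; small problems ($n \le 300$, where a
  likelihood evaluation is cheap and the surface is roughest) always get
  a final derivative-free polish.
* **Standardisation.** The response is divided by its SD internally and
  all reported quantities are mapped back. This conditions the AI matrix
  and makes the fit exactly equivariant under rescaling of $y$ (variance
  estimates scale by $c^2$, $r_{Ads}$ invariant), which the tests check
  at $c = 10$.
* **Initialisation.** Equal split of the phenotypic variance across the
  active variance components with $\sigma_{Ads} = 0$; overridable via
  `init`.
* **Convergence.** Relative $\ell_R$ change below `tol_loglik` (1e-8)
  *and* gradient norm in the unconstrained parameters below `tol_grad`
  (1e-4). A fit that stalls with a flat likelihood but a non-small
  gradient is returned with `converged = FALSE` and its best iterate —
  typical at a variance boundary, which is additionally flagged
  (`boundary`).
* **Standard errors** are inverse-AI-matrix approximations at the
  optimum; at boundaries they are reported as `NA` when the information
  matrix is not invertible. The reference analysis does not state whether
  its published uncertainties are asymptotic SEs or posterior SDs; here
  they are information-matrix SEs by construction.

BLUP solutions are obtained from the REML projection
($\hat u = \mathrm{Cov}(u, y) P y$), which coincides with Henderson's
mixed-model equations; `solve_mme()` builds and solves the MME explicitly
and is cross-checked against a dense GLS oracle in the tests. Dense
algebra is used throughout: the target scale (a few thousand records)
fits comfortably in memory and needs no sparse machinery.

## Feeder logs, traits and the RFI

Day-level quality control retains an (animal, day) iff daily intake lies
in [0.5, 4.5] kg, visit count in [2, 20] and feeder occupation in
[5, 120] min — bounds inclusive, failing *days* are dropped, not animals;
an animal needs two retained days to contribute traits. A visit belongs
to its entry date (days cut at local midnight); the day weight is the
median of the day's visit weights, damping scale noise. Traits follow
from the retained days: `ADFI = 1000 * TFI / test_days` (g/day),
`ADG = 1000 * (W2 - W1) / test_days`, `AFI = ADFI / NVD`.

Displacement success uses the raw (pre-QC) visit stream, since it is
event-based: a succession event is an entry within 2 s (inclusive, ties
count; timestamps at 1 s resolution) of a *different* animal's exit at
the same pen's feeder. `DS = 100 S / (S + B)` with S the events an animal
wins as entrant and B those it loses as exiter; each event contributes to
exactly one S and one B, so pen totals balance — an invariant the tests
enforce against an all-pairs enumeration oracle.

RFI is computed with fixed literature coefficients,
`RFI = ADFI - 1.41 ADG - 2.83 BF - 110.9 AMW`, with ADFI and ADG in
g/day, backfat BF in mm and the average metabolic body weight
`AMW = (W2^1.6 - W1^1.6) / (1.6 (W2 - W1))` (kg^0.6, with the analytic
limit `W1^0.6` at equal weights). The exact unit mix behind these
coefficients is not fully documented in the sources that publish them;
the g/day convention is declared here because it reproduces the reported
magnitudes of the trait, and both coefficients and units are
configuration (`rfi_coefficients()`), not code.

## Selecting extreme animals

Social breeding values are screened against a symmetric HPD interval
$\pm z \sqrt{\sigma^2_{As}} / \sqrt{N}$ with $z = 1.96$ at the default
95% level and $N$ the number of phenotyped animals. The $\sqrt N$
denominator is a deliberate reconciliation: the reference formula as
typed divides by $n$ unqualified, which does not reproduce the published
bound from the published variance and $N$, whereas $\sqrt N$ does; the
literal `/N` and a mean-pen-size reading remain selectable
(`variant = "N"`, `"pen"`). The k highest animals above and k lowest
below the interval form the HS and LS groups (ties broken by animal id,
making the output order-invariant); group trait comparison uses the
pooled-variance two-sided Student's t-test with nominal p-values (Welch
as an option, no multiplicity correction across traits, matching how
such comparisons are conventionally reported).

## Nine-quadrant concordance

Features are classified per axis as up/down/ns via strict thresholds
(FDR < 0.05; |log2FC| > 1 for mRNA). The protein cutoff of "1.2" is
interpreted as a *fold change* (|log2FC| > log2 1.2 ≈ 0.263): published
protein log2 fold changes declared differentially expressed in this
setting lie between 0.266 and 1.082, i.e. none clears 1.2 on the log2
scale while all clear log2(1.2) — the packaged concordant-feature list
makes that check explicit in the tests. The literal reading is available
(`prot_literal_log2 = TRUE`). The (mRNA, protein) status pair maps onto
the 1..9 grid with 3 (both up) and 7 (both down) concordant, 5 neutral,
1/2/4 protein-lower and 6/8/9 protein-higher; the orientation is inferred
from those semantics and an axis swap is a matter of exchanging the two
status arguments. Counting on a curated list (membership = significance)
uses sign concordance only, because published lists can include features
whose printed p-values would not re-pass a mechanical threshold;
re-thresholding from FDR columns is the alternative mode. BH adjustment
delegates to `stats::p.adjust(method = "BH")` and is tested against a
brute-force step-up implementation.

## The synthetic-data generator

`sim_config()` defaults define the simulated study conditions used by the
test suite: 200 unrelated founders (50 sires × 3 dams each), one
offspring generation of 150 litters of 10 — 1500 phenotyped animals
randomly assigned to 150 pens of 10 — variance components set to the
reference estimates for RFI (direct 2594.808, social 1007.688, covariance
206.751, litter 322.848, pen 40354.019, residual 23234.581; g/day
squared), three contemporary-group levels assigned to pens round-robin,
and an 84-day test. Breeding values are sampled by sequential recursion
down the pedigree (founders from $N(0, G_0)$; offspring at half the
parent sum plus a Mendelian-segregation draw scaled by
$\tfrac12 - \tfrac14(F_s + F_d)$), which is exact for
$N(0, G_0 \otimes A)$ at O(q) cost. RNG streams are per purpose
(pedigree, effects, noise, behaviour, pens), so enlarging one stage never
perturbs another, and a seed fully determines the output.

The feeder-visit generator runs one feeder per pen, occupied
sequentially (occupancy intervals are disjoint by construction): each
animal makes a Poisson number of visits a day (default 6) with gamma
durations (10 min) and intakes (0.3 kg), linear growth (0.92 kg/day from
33.6 kg), and a displacement rule in which the next entrant displaces
the previous occupant — entering within 2 s of its exit — with
probability `base * plogis(scale * (dom_next - dom_prev))`.
Non-displacement gaps are at least 3 s so the two event classes cannot
blur at 1 s timestamp resolution. These defaults keep simulated days
inside the QC window, so QC exercises the boundaries rather than
discarding everything.

What the generator does *not* emulate: feed wastage, multi-station pens,
sex and parity structure, seasonal effects, non-linear growth, health
events, or realistic omics correlation structure (the omics generator
produces independent features with a controlled concordant fraction).
Passing tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to the full messiness of farm data.

## Identifiability at the study scale, and test problem sizes

With pens composed at random from 150 full-sib litters, very little
genetic relatedness falls *within* pens, and the social variance is
identified mainly through the contrast between within-pen variance and
covariance against a pen variance an order of magnitude larger. The test
suite quantifies the consequence: the inverse average-information SE of
$\sigma^2_{As}$ at the true parameters of the null design
($\sigma^2_{As} = 0$) is several times larger than 10% of
$\sigma^2_{Ad}$. Parameter recovery in the mean across 20 replicates is
confirmed by the tests, but near-zero seed-by-seed social-variance
estimates under the null are not achievable under randomized pen
composition at this scale — a property of the design, not of the
estimator, and the reason one specificity check in the acceptance suite
is expected to fail. Family-blocked pen compositions would sharpen
identification substantially, but the randomized composition is kept
because it is the design the package emulates.

Monte-Carlo problem sizes in the tests are chosen to make each property
decisive at desk scale: 20 replicates of 1500 animals for recovery,
10,000 founders/trios for sampling-distribution checks, 1e5 gene drops
for the relationship-matrix oracle (with a Bonferroni-calibrated 3-SD
band across the 36 matrix entries), 1000-point random search on a
12-record instance for global-optimum checks, and 200-day visit streams
for dominance recovery.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(n_founders = 40, dams_per_sire = 3, litter_size = 8,
                  n_pens = 30, pen_size = 8, seed = 42)
study <- simulate_sge_study(cfg)
fit <- sge_reml(y ~ batch, data = study$phenotypes,
                pedigree = study$pedigree)
summary(fit)

bv <- breeding_values(fit, phenotyped_only = TRUE)
iv <- hpd_interval(fit$components[["sigma2_as"]], N = fit$n)
groups <- classify_extremes(
  data.frame(animal_id = bv$animal, sge = bv$as_hat), iv, k = 4)
table(groups$group)
```

## Known limitations

* Single trait, single fixed factor in the formula interface; no
  maternal effects, no genomic relationships, no Bayesian posteriors.
* Dense algebra bounds practical size at roughly 5000 records.
* Inverse-AI standard errors are first-order approximations and
  unreliable at variance boundaries (flagged, reported as `NA` when the
  information matrix is singular).
* The HPD screen assumes approximately normal, zero-centred social
  breeding values; it is a screening rule, not a posterior interval.
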