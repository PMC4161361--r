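---
title: "Mapping multiple QTL for discrete traits by iteratively reweighted LASSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping multiple QTL for discrete traits by iteratively reweighted LASSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

In an experimental cross (backcross, doubled haploids, recombinant inbred
lines, F2), a quantitative trait locus (QTL) analysis asks which genomic
positions carry alleles that shift a phenotype. Many phenotypes of interest
are discrete — disease presence/absence, counts of tillers or offspring —
so the linear model behind classical interval mapping is replaced by a
generalized linear model (GLM): for individual $i$ the mean
$\mu_i = E[y_i]$ is tied to a linear predictor through a link function $g$,

$$ g(\mu_i) = \eta_i = \mu_0 + \sum_{j=1}^{k} x_{ij}\, b_j , $$

where $j$ indexes *putative loci* on a genome-wide grid (every marker plus
interior points every `step_cM`), $x_{ij}$ is the genotype indicator at
locus $j$ (coded $\pm 1$ for the two classes of a backcross; $+1/0/-1$
additive and $0/1$ dominance codes for F2), and $b_j$ is the genetic effect
on the link scale. With a 1 cM grid, $k$ far exceeds the sample size and
almost all $b_j$ are zero — a sparse, over-saturated GLM. `qtlasso` fits it
with an L1 (LASSO) penalty solved by coordinate descent inside IRLS, and
then performs post-selection inference on the few surviving loci.

Supported families and links: gaussian/identity; Poisson with log
(default), identity, sqrt; binomial (binary or with a trial count) with
logit, probit, cloglog, log.

## Haley–Knott regressors and heterogeneous over-dispersion

Between markers the genotype is unobserved. Following regression interval
mapping, the unknown indicator is replaced by its conditional expectation
given the nearest informative flanking markers,
$d_{ij} = E[x_{ij} \mid \text{flanks}]$, computed from the no-interference
(Haldane) Markov model along the chromosome; the same computation yields
the conditional variance $c_{ij} = \mathrm{Var}(x_{ij} \mid \text{flanks})$.
At an observed marker $d$ equals the coded genotype and $c = 0$; missing
marker genotypes are handled by searching outward for the nearest observed
flank (one-sided at chromosome ends; the design prior when a chromosome is
entirely missing for an individual).

The substitution $x \to d$ leaves genotype uncertainty in the residual: on
the link scale individual $i$ carries extra variance
$\sum_j b_j^2 c_{ij}$. The model absorbs it as a *heterogeneous
over-dispersion*

$$ \psi_i = 1 + \sum_j b_j^2\, c_{ij} \ge 1 , $$

and standardizes the linear predictor per individual,
$\eta_i^* = \eta_i / \sqrt{\psi_i}$ (every design column, intercept
included, is divided by $\sqrt{\psi_i}$). Under the probit link this is the
exact threshold-model (liability) correction: ignoring it attenuates every
effect estimate by roughly $1/\sqrt{\bar\psi}$.

## The iteratively reweighted LASSO

At fixed $\psi$ the penalized GLM is fit by the standard IRLS device: with
$\mu = g^{-1}(\eta^*)$, working response
$z_i = \eta_i^* + (y_i - \mu_i)\, g'(\mu_i)$ and weight
$w_i = m_i / (V(\mu_i)\, g'(\mu_i)^2)$ ($m_i$ the binomial trial count),
each round minimizes

$$ \frac{1}{2n} \sum_i w_i \big(z_i - \eta_i^*\big)^2
   + \lambda \sum_j s_j\, |b_j| , $$

by cyclic coordinate descent with soft-thresholding (compiled code with an
active-set strategy). The intercept is never penalized. The penalty factors
$s_j$ are the column standard deviations, which is algebraically identical
to running the LASSO on unit-variance columns while keeping coefficients on
the genotype-coding scale. This matters here: between-marker regressors are
variance-attenuated by construction ($\mathrm{Var}(d_j) = 1 - E[c_j]$ for
$\pm1$ coding), and without standardization the selection systematically
snaps to the flanking markers, biasing position estimates onto the marker
grid and splitting one QTL across two markers.

The full procedure alternates selection with over-dispersion updates:

1. initialize $b = 0$, $\psi \equiv 1$;
2. fit the unweighted penalized GLM, choosing $\lambda$ (below);
3. update $\psi_i$ from the nonzero effects;
4. refit the penalized GLM on the $\psi$-standardized design at the same
   $\lambda$;
5. repeat 3–4 until the largest coefficient change falls below `outer_tol`
   (default $10^{-4}$, at most 25 iterations). `mode = "unweighted"` stops
   after step 2.

Near-collinear grid columns (adjacent 1 cM loci inside one marker interval
correlate beyond 0.999) make strict coefficient-change criteria
pathological: coefficients drift along an essentially flat objective. All
loops therefore also accept a stalled penalized objective as convergence,
and the coordinate-descent criterion is the curvature-weighted squared
change $\max_j q_j (\Delta b_j)^2$. If the outer loop still fails to
settle, the iterate with the best penalized deviance is returned and
flagged.

### Choosing the penalty

* `lambda_rule = "cv"`: K-fold cross-validation on held-out deviance over a
  geometric path from $\lambda_{\max}$ (the smallest penalty that zeroes
  everything); the minimizing $\lambda$ is chosen once at step 2 and reused
  in later iterations (re-selection each iteration is available but rarely
  changes the answer).
* `lambda_rule = "bic"` (the fast, cross-validation-free mode used in the
  replication experiments): walk the path, score
  $\mathrm{deviance} + \log(n) \cdot \mathrm{df}$, stop once the criterion
  has clearly passed its minimum. An `"aic"` variant and a fixed
  path-fraction rule (`"ratio"`) exist for comparison; in our calibration
  runs the BIC rule gave the best joint behaviour of selection frequency
  and refit stability, while more liberal rules flooded the refit with
  correlated noise loci.
* `lambda_rule = "fixed"`: supply `lambda`.

## Post-selection inference

The LASSO selects but does not test. The nonzero effects are first pruned
to at most one locus per marker interval: loci are visited in decreasing
$|b_j|$ and kept only if no kept locus of the same effect type lies within
one marker-interval width on the same chromosome (ties toward the smaller
position). This greedy minimum-separation form also merges clusters that
straddle an interval boundary — the common failure mode of a literal
per-interval rule, since the selected cluster around a true QTL at, say,
56 cM regularly spans the 50–60 and 60–70 cM intervals.

The kept loci are refit by unpenalized IRLS on the $\psi$-standardized
design, alternating $\psi$ refreshes from the current (unpenalized)
estimates with IRLS rounds until both stabilize. Starting $\psi$ at the
penalized fit's state matters: the shrunken coefficients understate
$\psi$, and the alternation walks the estimates up to the fixed point that
undoes the imputation-variance attenuation. The alternation is a
fixed-point iteration that need not contract — in data-sparse fits
(small $n$, many selected loci, strongly informative Poisson counts)
$\psi$ and the effects can inflate each other without bound — so a
contraction guard watches the coefficient movement per refresh and, the
moment a refresh moves the coefficients further than the previous one
did, reverts to the last contracting iterate. The covariance of the
estimates is the inverse weighted information matrix
$(X_s' W X_s)^{-1} a(\hat\phi)$, giving per-locus standard errors, $t$
statistics ($t_j = \hat b_j / \mathrm{se}_j$, $n - s - 1$ degrees of
freedom; the reported quantity is $-\log_{10} p$), and heritabilities

$$ h_j^2 = \frac{\hat b_j^2 v_j}{\sum_l \hat b_l^2 v_l + \sigma^2_{res}},
\qquad v_j = \mathrm{Var}(d_j) + \overline{c_j}, $$

with the latent-scale residual variance $\sigma^2_{res}$ equal to
$\pi^2/3$ (logit), $1$ (probit), $\pi^2/6$ (cloglog), the estimated
dispersion (gaussian), or a delta-method value from the fitted means
(Poisson).

### Genome-wide thresholds

Because selection biases the refit $t$ statistics upward, nominal $t$
quantiles are not valid genome-wide. `qtl_threshold()` estimates the
critical value of the genome-wide maximum $-\log_{10} p$ empirically, by
running the *entire* pipeline (fit, prune, refit, test) on replicates of
either (a) the null model with zero genetic effects (simulation studies)
or (b) the observed data with phenotypes permuted against whole genotype
rows, preserving marker linkage (real data). The critical value is the
order statistic $\lceil (1-\alpha) R \rceil$ of the replicate maxima
(replicates that select nothing contribute 0). Loci whose $-\log_{10} p$
exceeds it become QTL calls.

## The simulator and the benchmark scenario

`simulate_cross()` draws genotypes along each chromosome as a first-order
Markov chain whose switch probability is the Haldane recombination
fraction of the inter-locus distance (two independent meioses for F2; map
expansion $r^* = 2r/(1+2r)$ for selfed RIL), with QTL loci embedded in the
chain and withheld from the mapper, then draws phenotypes from the family
distribution at $\mu = g^{-1}(\mu_0 + \sum_j x_{ij} b_j)$.

`backcross_10qtl_spec()` encodes the benchmark design used throughout the
package's replication experiments: a backcross of $n$ individuals on six
100 cM chromosomes with 11 evenly spaced markers each, and ten QTL at
genome-wide positions 23, 56, 148, 193, 267, 332, 390, 478, 522, 574 cM
with effects 1.5, 2.0, 0.72, 1.1, −0.22, 0.70, −0.65, 1.25, 0.35, −0.80
and zero intercept. Three conventions are deliberate choices, documented
here because the benchmark's published power and estimate values depend on
them:

* **Indicator coding** $\pm 1$, so a fully informative locus has
  $\mathrm{Var}(x) = 1$ and effects are half-differences between genotype
  class means on the link scale.
* **Binary traits use the probit link** for both simulation and analysis —
  the threshold-model reading of a binary trait, where effects act on a
  latent liability with unit residual variance. With the logit alternative
  the identical effect sizes carry less information per observation
  ($\sigma_{res} = \pi/\sqrt{3}$), and in our calibration runs detection
  power fell well short of the benchmark values, while probit reproduces
  them; probit is also the link a threshold-trait geneticist would pick
  first.
* **Poisson traits use the log link.**

What the simulator does *not* emulate: genotyping errors, missing-data
patterns of real platforms, crossover interference, epistasis,
QTL-by-environment interaction, segregation distortion. Passing the
replication experiments therefore demonstrates correctness of the
machinery under the stated genetic model, not robustness to those
real-data complications.

## Numerical choices

* Binomial means are clipped to $[10^{-10}, 1 - 10^{-10}]$ and Poisson
  means to $\ge 10^{-10}$ inside the solver so IRLS weights stay finite at
  extreme linear predictors (the simulator uses unclipped means and raises
  an error on genuine domain violations, e.g. identity-link Poisson with a
  negative mean).
* Path: 30 geometric $\lambda$ values down to $0.05\,\lambda_{\max}$
  ($0.01$ when $n > k$), truncated early by the information criterion or by
  a degrees-of-freedom cap of $n/4$.
* Coordinate descent: curvature-weighted tolerance $10^{-14}$ in the
  exported solver (about $10^{-7}$ coefficient changes on unit-variance
  columns), $10^{-7}$ inside the IRLS path; at most $10^5$ sweeps, with an
  exceeded cap reported as a warning, never an error.
* Refit rank deficiencies drop collinear columns with a warning; IRLS
  divergence triggers step-halving.
* Ties in pruning break toward the smaller position; equal-magnitude
  effects are ordered deterministically, so runs are bit-reproducible from
  the seed.

## Desk-scale experiment sizes

The replication experiments in `scripts/acceptance.R` and the test suite
run the full pipeline at reduced Monte-Carlo sizes chosen to keep a
complete run on one CPU comfortable: genome-wide thresholds from 150–300
null-model replicates (the reference protocol uses 1000) and 60–200
scenario replicates per trait/sample-size cell (reference: 500). At these
sizes a power estimate carries a binomial standard error of 3–5 percentage
points and mean-estimate comparisons carry their observed Monte-Carlo
standard errors; the test tolerances account for that.

## Known limitations

* Conditioning uses the nearest informative flank on each side, not full
  multipoint hidden-Markov probabilities; with dense markers and moderate
  missingness the difference is negligible, with very sparse data it is
  not.
* The one-locus-per-interval rule cannot separate two true QTL inside a
  single marker interval.
* Ordinal/multinomial traits and epistatic models are out of scope; the
  binomial family with a trial count covers proportion data.
* The refit's $\psi$ alternation assumes the selected model is roughly
  correct; under gross misspecification (many missed QTL) the attenuation
  correction is partial, which is visible in the unweighted variant's
  systematic underestimates.
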