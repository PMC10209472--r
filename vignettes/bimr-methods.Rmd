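---
title: "Methods and design choices in bimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in bimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`bimr` implements bidirectional two-sample Mendelian randomisation (MR)
from GWAS summary statistics. This vignette records the statistical model,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, the numerical choices, and the design
decisions taken where reasonable alternatives existed. It states no
empirical result that the test suite does not itself compute.

## Model and assumptions

Two-sample MR treats genetic variants as instrumental variables. For
variant $j$, $\hat\gamma_j$ (SE $\sigma_{xj}$) is the gene–exposure log
odds ratio from the exposure GWAS and $\hat\Gamma_j$ (SE $\sigma_{yj}$)
the gene–outcome log odds ratio from an independent outcome GWAS. Under
the instrumental-variable assumptions (association with the exposure, no
association with confounders, no effect on the outcome except through the
exposure) each variant identifies the causal slope $\beta$ through
$\Gamma_j = \beta\,\gamma_j$, estimated per variant by the Wald ratio
$\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$.

The bidirectional design runs the analysis twice with the trait roles
swapped, each direction drawing instruments from its own exposure GWAS at
genome-wide significance ($p < 5\times10^{-8}$ by default). The two
instrument sets are disjoint by construction; the package does not enforce
or verify sample non-overlap, which is a property of the input studies.

## Estimators

* **IVW-FE** (main analysis): inverse-variance weighted mean of the Wald
  ratios with first-order weights $w_j = \hat\gamma_j^2/\sigma_{yj}^2$.
  Algebraically identical to weighted least squares of $\hat\Gamma$ on
  $\hat\gamma$ through the origin; the test suite asserts this identity to
  1e-10. Most powerful, but biased by any directional pleiotropy.
* **IVW-RE**: multiplicative overdispersion; the fixed-effect SE is
  inflated by $\max(1, \sqrt{Q/(k-1)})$, so homogeneous data reproduce
  IVW-FE exactly. An additive DerSimonian–Laird variant is available
  (`mode = "RE-DL"`) since "random effects" alone does not pin down a
  model; the multiplicative form is the default because it preserves the
  point estimate and is the common choice in summary-data MR.
* **Weighted median**: order statistics placed at cumulative-weight
  positions $p_j = \sum_{i\le j} w'_i - w'_j/2$, linear interpolation to
  0.5; a tie at exactly 0.5 returns that order statistic. Consistent when
  valid instruments carry ≥ 50% of the weight.
* **Weighted mode**: argmax of the weighted normal-kernel density of the
  ratios. The bandwidth rule is not specified in the source analyses, so
  the package uses the modified Silverman rule
  $h = \phi \cdot 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,k^{-1/5}$
  with $\phi = 1$ by default, maximised on a ≥ 512-point grid spanning
  $[\min - 3h, \max + 3h]$. All-identical ratios (zero bandwidth) return
  the common value.
* **MR-Egger**: weighted least squares of $\hat\Gamma_j$ on
  $\hat\gamma_j$ with a free intercept, weights $\sigma_{yj}^{-2}$, after
  orienting every pair so $\hat\gamma_j \ge 0$. The slope is consistent
  under InSIDE (instrument strength independent of direct effects); the
  intercept estimates the average directional pleiotropic effect.
  Coefficient SEs carry the same multiplicative overdispersion with
  $k - 2$ denominator; inference uses $t_{k-2}$ by default (normal
  reference optional).

Bootstrap SEs for the median and mode estimators are parametric: ratios are
redrawn as $N(\hat\beta_j, se_j)$, $B = 1000$ times by default, from a
user-supplied seed. All confidence intervals use the 1.96 multiplier (95%).

### SIMEX correction of MR-Egger

Measurement error in $\hat\gamma_j$ violates Egger's NOME assumption and
attenuates the slope (regression dilution). The degree of violation is
quantified by $I^2_{GX}$, the I² of the oriented gene–exposure estimates;
values below 0.9 trigger the correction in the pipeline (it is always
computable on demand). SIMEX re-estimates the fit after adding noise
$\sqrt\lambda\,\sigma_{xj} z$ to $\hat\gamma_j$ for
$\lambda \in \{0, 0.5, 1, 1.5, 2\}$, averages the coefficients over $B$
draws per $\lambda$, fits a quadratic in $\lambda$ and extrapolates to
$\lambda = -1$.

Two deliberate choices here:

* **Orientation is fixed from the observed data.** Re-orienting each
  perturbed dataset (flipping pairs whose perturbed $\hat\gamma$ goes
  negative) makes the estimator's expectation non-smooth in $\lambda$ and
  degrades the quadratic extrapolation; a 100-replicate probe during
  development showed clearly worse bias reduction with per-draw
  re-orientation. The perturbed fits therefore reuse the naive fit's
  orientation.
* **The SE extrapolates the mean model-based variance** of the coefficient
  across draws, with the naive Egger SE as a fallback when the
  extrapolated variance is non-positive. This is a pragmatic choice: the
  extrapolated variance understates the extra variability introduced by
  the correction itself, so SIMEX intervals should be read as approximate.
  The acceptance criterion for SIMEX concerns point-estimate bias, which
  this choice does not affect.

## Pleiotropy diagnostics

Cochran's $Q = \sum_j w_j(\hat\beta_j - \hat\beta)^2$ against the IVW-FE
estimate, referred to $\chi^2_{k-1}$; $I^2 = \max(0, (Q - df)/Q)$, with the
Higgins–Thompson test-based CI on $\ln H$ (both SE branches, $Q > k$ and
$Q \le k$; back-transformed, clamped to $[0, 1)$; no CI at $k = 2$).
Negative $I^2$ is clamped to zero. Which CI method produced the published
intervals is not stated in the source; the test-based method is the
standard default and is what the package reports.

Per-variant contributions $q_j = w_j(\hat\beta_j - \hat\beta)^2$ sum to $Q$
(asserted to 1e-8) and are flagged against the $\chi^2_1$ upper 0.05 and
Bonferroni upper $0.05/k$ quantiles — the two reference lines of the usual
outlier figure. Outlier handling is a **single pass**: all Bonferroni
exceeders are removed at once and IVW-FE plus heterogeneity are refitted
(the published analysis removed its five outliers once; an iterative mode
exists behind `iterate = TRUE`). The identification is thresholded rather
than "graphical": the Bonferroni rule is taken as the operational meaning
of the published figure's extreme group. Leave-one-out refits IVW-FE $k$
times and reports the most influential variant.

Heterogeneity is always computed on first-order Wald-ratio weights,
consistent with the estimator module. A known consequence: with noisy
$\hat\gamma_j$ the first-order weights slightly understate ratio
dispersion, so Q runs marginally hot for very heterogeneous instrument
strength; the type-I-error acceptance test is run in the generator's
strong-instrument default world where the effect is negligible.

## Harmonisation

Variants are matched by identifier only (no positional liftover; indels
and multi-allelics are out of scope). Outcome records with swapped
effect/other alleles are sign-flipped; palindromic variants (A/T, C/G) are
resolved by effect-allele frequency after letter alignment — if the two
frequencies disagree about the minor allele the outcome beta is negated,
and the variant is dropped when either frequency is missing or both lie in
the 0.42–0.58 ambiguity window (symmetric about 0.5; common practice, the
source analysis is silent). Non-palindromic variants with incompatible
allele sets are dropped as `allele_mismatch`; strand-complement rescue
(A/G vs T/C) is deliberately not attempted, since silent strand inference
is a known source of harmonisation errors and the contract keeps
letter-level matching explicit. Every exposure variant ends up in exactly
one of `pairs` or the exclusion log, which the pipeline writes as TSV.

Proxy substitution happens **before** harmonisation: an accepted proxy
(r² ≥ 0.8 by default) has its outcome record relabelled to the target
identifier with alleles translated through the stated correspondence, and
the resulting pair carries `proxy_used`. The proxy's allele frequency is
retained as-is, which is an approximation valid at high r²; palindromic
targets substituted this way still face the frequency check.

Weak instruments (F ≤ 10) are warned about but not removed — the published
analysis screened on F and reported no removals, so the screen is
diagnostic, not a filter.

## Synthetic data: what it emulates, what it does not

The generator produces per-variant summary statistics directly on the
(beta, SE) scale — the object the analysis consumes — with
$\hat\gamma_j = \gamma_j + N(0, \sigma_{xj})$,
$\hat\Gamma_j = \beta\gamma_j + \alpha_j + N(0, \sigma_{yj})$ and
independent noise between samples. Defaults:
$\gamma_j \sim |N(0, 0.1^2)| + 0.1$ (instruments never null),
$\sigma_{xj} \sim U(0.02, 0.04)$, $\sigma_{yj} \sim U(0.05, 0.15)$, which
puts per-variant F roughly in the 10–100+ band of genome-wide significant
instruments for a common trait, with the outcome side noisier, as when the
outcome GWAS is much smaller. Pleiotropy scenarios: `none`
($\alpha_j = 0$), `balanced` ($N(0, \tau^2)$), `directional`
($N(\mu_\alpha, \tau^2)$), `correlated`
($\rho\gamma_j + N(0, \tau^2)$, violating InSIDE).

Planted outliers are given a direct effect of `outlier_alpha` (default 15)
gene–outcome SEs, making each contribution $q_j \approx$
`outlier_alpha`² — far above any Bonferroni threshold by construction.
Their signs are assigned greedily, largest pooled-estimate influence
first, so the planted set is near-neutral for the IVW estimate. Without
this balancing, high-weight outliers drag the pooled estimate far enough
that clean variants genuinely exceed the Bonferroni threshold, and "the
flagged set equals the planted set" stops being the estimand; the
balancing makes the planted world one where single-pass flagging is the
right tool, which is the scenario the detection test is about.

One root seed drives everything; replicate $r$ of an experiment uses the
stream seed $(s \cdot 48271 + r) \bmod (2^{31}-1) + 1$.

The generator does **not** emulate: linkage disequilibrium between
instruments (the design assumes independent SNPs), sample overlap between
the two GWAS, allele-frequency-dependent power, palindromic/strand
ambiguity (generated alleles are uniformly A/G), case–control imbalance,
or winner's curse. A green recovery test therefore establishes estimator
correctness under the stated sampling model — not robustness to
harmonisation pathologies, which are tested separately with constructed
tables, and not behaviour under correlated instruments, which is out of
scope.

## Numerical choices and degenerate inputs

* Wald-ratio SE is first order ($\sigma_{yj}/|\hat\gamma_j|$) by default,
  matching the IVW/regression equivalence; the second-order delta-method
  SE is available via `order = 2`. Pairs with $\hat\gamma_j = 0$ are
  excluded with reason `zero_gx`.
* `p` values are clamped into $(0, 1]$; $I^2$ into $[0, 1)$.
* Degenerate Egger designs (all oriented $\hat\gamma$ equal) error
  explicitly rather than returning an unstable solve.
* `i2_gx` floors $\sigma_{xj}$ at 1e-12 so exact-zero measurement error
  reports $I^2_{GX} \to 1$ (SIMEX not needed) instead of dividing by zero.
* Q contributions at exactly the threshold are not flagged (strict
  inequality), matching the "exceeds" reading.
* Odds-ratio output keeps full precision; the published convention of
  printing near-null ORs to 3 decimals is a formatting concern left to the
  caller.

## Reproduction status and limitations

The headline numbers of the motivating analysis (forward OR 1.61, 95% CI
1.04–2.49, p = 0.032; null reverse direction with I² = 63% and five
removed outliers) depend on per-variant instrument tables that are not
redistributable here and have no programmatic accession, so the package
cannot re-derive them offline. What it does verify, in
`tests/testthat/test-acceptance.R`: the printed forward OR, CI and p are
mutually consistent under the package's own odds-scale arithmetic (p
reconstructed from OR and CI within ±0.003; CI geometric mean within
±0.01 of the OR); every estimator matches an independent oracle; the Q
test and IVW coverage are calibrated on nulls; the Egger intercept
recovers planted directional pleiotropy; planted outliers are flagged
exactly; and SIMEX beats naive Egger under heavy dilution in ≥ 80% of
replicates. Supplying the real instrument tables as TSVs to
`run_bidirectional()` would reproduce the published pipeline end to end.

Known limitations: no multivariable MR, MR-PRESSO, Steiger filtering or
contamination-mixture methods; no LD computation (proxy maps are inputs);
no funnel-plot asymmetry tests beyond the Egger intercept; SIMEX intervals
are approximate as discussed above.
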