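---
title: "Methods: family history versus polygenic risk under a liability-threshold pedigree model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family history versus polygenic risk under a liability-threshold pedigree model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famprs)
```

## The problem

Family history (FH) and polygenic risk scores (PRS) both summarize
inherited disease liability, and clinical guidelines often treat them as
substitutes. Registry-based biobank studies compare them directly:
deriving FH from relatives' hospital, cancer and cause-of-death records,
estimating FH and per-SD PRS effects with logistic regression,
cross-adjusting each for the other, testing their interaction, stratifying
cumulative incidence by FH and PRS group, and asking how often a relative
of a high-PRS index person also has a high PRS. `famprs` implements that
entire comparison as a tested pipeline, with a family-structured
liability-threshold simulator standing in for registry data that cannot be
shared. Every analysis runs identically on user-supplied cohort and pair
tables in the documented TSV formats.

## The generative model

Liability for each disease is

$$L = G + C + E, \qquad \operatorname{Var}(L) = 1,$$

with $G$ the total additive genetic component
($\operatorname{Var} = h^2$), $C$ a shared-family environment
($\operatorname{Var} = c^2$) and $E$ unique environment
($\operatorname{Var} = 1 - h^2 - c^2$). Disease occurs when $L$ exceeds
$T = \Phi^{-1}(1 - K)$, so lifetime prevalence is $K$ by construction.

The PRS is modeled on the liability scale as an additive sub-component of
$G$ with variance $\rho^2 \le h^2$; the standardized PRS therefore
correlates $\sqrt{\rho^2}$ with liability. Modeling the score as fully
additive is deliberate: it makes the correlation of two relatives' PRSs
exactly twice their kinship coefficient (0.5 for first-degree, 0.25 for
second-degree pairs), which is the premise of the bivariate-normal
concordance theory below. No genotypes are simulated — the sensitivity of
every analysis to score quality is explored through $\rho^2$ (and the
nested `rho2_small` sub-score), not through variant panels.

Each three-generation family consists of two founder couples, their
children (the father, the mother, and their full siblings) and the
index-generation children. Founders draw each additive component from
$N(0, v)$; a child receives the midparent value plus an independent
Mendelian-sampling deviation $N(0, v/2)$, which preserves the variance in
every generation. Full siblings share $C$ fully; a parent's natal family
environment enters their children's with weight `c_parent_share`
(default 0.5), reflecting that siblings share a rearing household while
parents and children share it only partly. Diseases are generated
independently given the pedigree: no pleiotropy.

Ages at onset are truncated normal on (0, 100], optionally shifted
earlier in proportion to the liability excess over the threshold
(`onset_shift`, default 0 — onset carries no liability information unless
asked for). Background death ages are truncated normal (default mean 76,
SD 12, on [20, 105]); when `survival_after_onset_mean` is finite, a case
dies no later than onset plus a truncated-normal survival time, linking
disease — and, with `onset_shift > 0`, high liability — to early death.
That chain (high liability, early onset, early cause-positive parental
death) is exactly what the parental age-at-death tertile analysis is
designed to detect, and it is off by default. A deceased case's record
lists the disease among its causes with probability
`cause_of_death_prob` (default 0.7); immediate, contributing and
underlying causes are not distinguished.

## Registries and family-history definitions

Registry windows default to the Finnish configuration: cause-of-death
records from 1964 through 2018, hospital discharges from 1968, cancer
registry from 1953, follow-up through 2019. Events outside a window are
invisible to FH derivation — a parent dead in 1950, or in 2019, con-
tributes no observable cause-of-death record.

* **FH_1st / FH_2nd**: an index person is FH-positive if at least one
  first- (respectively second-) degree relative *present in the cohort*
  is observably affected — diagnosed inside the diagnosis window
  (cancer-registry diseases use the earlier start) and before their own
  death, or with the disease among registered causes of death. No
  imputation of unobserved relatives; individuals without relatives of
  the required degree are FH-negative with `n_rel = 0`, flagged as
  low-information. The two exposures are independent: an affected sibling
  never contributes to FH_2nd.
* **FH_P**: positive if any observable parental death record lists the
  disease. Individuals whose parents both died before the registry start,
  or whose parental records are both missing, are ineligible and excluded
  — the rule is applied literally, so a person with one missing and one
  pre-registry parent remains eligible (with no informative record).
  Among FH_P-positive individuals the cause-positive parent's age at
  death (the younger one, if both) is split into tertiles per disease,
  boundary ties to the lower tertile.
* Sex-restricted diseases (breast, prostate cancer) restrict both the
  index set and the relatives considered to the relevant sex.

Association analyses use the lifetime threshold status as outcome, while
registry windows act on the *ascertainment of relatives*: that separation
keeps the simulated prevalence identities exact and puts the registry
realism where the FH definitions live. Real registry outcomes are
themselves window-censored; with user-supplied data the outcome column is
whatever the user derived.

## Estimation

Effects are estimated by maximum-likelihood logistic regression (IRLS with
an iteration cap; separation and non-convergence raise explicit errors,
never silent fallbacks), adjusted for sex and birth year — the covariates
that exist in simulation; genotyping array, cohort and principal
components are accepted as extra columns on real data. Continuous
exposures are standardized within each analysis set, so PRS effects are
per SD. Confidence intervals are Wald on the log-odds scale,
$\exp(\beta \pm 1.96\,\mathrm{SE})$.

Cross-adjustment fits exposure-alone and mutually adjusted models with the
same covariates and reports the proportional change in log odds:
`ratio` $= \beta_\text{adj}/\beta_\text{unadj}$ and
`decrease` $= 1 - \text{ratio}$. **Sign convention:** a positive decrease
means attenuation. Means and SDs across diseases are unweighted, on the
log-odds scale. The FH-by-PRS interaction is the Wald test of the product
of the FH indicator with the standardized PRS, flagged against a
Bonferroni threshold $\alpha / n_\text{tests}$ (0.05/39 displays as
0.0013 at two significant digits).

PRS percentile bands are computed within each disease's analysis set
(after sex restriction), with rank-based ties and boundary values
assigned to the lower band; schemes are top decile vs rest, the seven
bands 0–10/10–20/20–40/40–60/60–80/80–90/90–100 with 40–60 as reference,
and the three groups low < 33rd percentile, average 33rd–90th, high >
90th.

## Concordance of high PRS in relatives

Under the additive model, two relatives' standardized PRSs are bivariate
normal with correlation $r = 2\varphi$ ($\varphi$ = kinship). The
theoretical probability that the relative exceeds the $q$-quantile given
that the index person does is

$$P = \frac{1}{1-q}\int_{z_q}^{\infty} \phi(x)\,
  \bar\Phi\!\left(\frac{z_q - r x}{\sqrt{1-r^2}}\right)\,dx,$$

evaluated by adaptive quadrature with relative tolerance below $10^{-6}$
(no installed package provides the bivariate normal orthant probability,
so the conditional tail is integrated directly; the tests validate it
against a brute-force two-dimensional Riemann sum). At $q = 0.9$ this
gives 32.4% for first-degree ($r = 0.5$) and 19.3% for second-degree
($r = 0.25$) relatives. The observed estimator counts pairs whose
relative exceeds the within-cohort 90th percentile among pairs whose
index person exceeds it; each unordered pair contributes both directions,
matching the conditional-probability framing, and stratification
conditions on the relative's disease status only.

```{r concordance}
theoretical_concordance(c(0.5, 0.25), q = 0.9)
```

## Cumulative incidence

Kaplan-Meier product-limit estimation (via the survival package) on the
age scale with entry at birth: cases contribute onset age, non-cases are
censored at death or at their age when registry follow-up ends. Strata
are the FH flag crossed with the three PRS groups; strata with fewer than
10 events are flagged and omitted rather than estimated. No competing-
risks estimator is used, matching the plain product-limit convention of
the analyses this package mirrors; left truncation (registry entry after
birth) is an extension point for real data, not needed for simulated
lifetime onsets.

## Randomness and reproducibility

One root seed governs a run. Families are simulated in fixed-size blocks
(default 1000), each from a substream derived deterministically from the
root seed and block index; a block is always generated in full and
truncated afterwards, so enlarging `n_families` appends families without
reshuffling existing ones. Truncated distributions are drawn by inverse
CDF from a single uniform, and conditional quantities (onset, cause
listing, post-onset survival) consume a uniform for every individual
regardless of status, so the draw layout — and hence byte-level output —
depends only on the plan. This is a coarsened version of per-family
substreams: same invariance, vectorized speed.

## Design choices on genuinely open points

* **Per-disease latent structure.** Each disease carries its own
  $G, C, E$ and PRS, since heritabilities, capture fractions and
  prevalences differ by disease; diseases are conditionally independent
  given the pedigree.
* **Independence in calibration experiments.** Monte-Carlo checks of the
  interaction test's type-I error and of CI coverage analyze one
  index individual per family: family members share liability, and
  ordinary logistic Wald inference assumes independent rows.
* **FH from within-cohort relatives only**, with no correction for family
  size; family size is a plan knob (`n_children`, sibling counts), not a
  modeled distribution, since the emulated registries do not publish one.
* **Percentile cut-points per analysis subset** (after sex restriction)
  rather than on the full cohort; documented because the emulated studies
  leave it ambiguous.
* **Tertile age**: when both parents are cause-positive the younger death
  age is used, consistent with the early-onset emphasis of the tertile
  analysis.

## Problem sizes used by the test suite

The property and acceptance tests simulate 12,000 three-generation
families (~120,000 individuals; 180,000 unordered first-degree and
144,000 second-degree pairs), sized so that Monte-Carlo error on pair
correlations and concordances is well below the 1-percentage-point
tolerances being asserted. The interaction type-I error uses 1,000
replicates of 1,000 independent index individuals; CI coverage uses 100
replicates of 800. The configuration grid for the attenuation-asymmetry
property spans $h^2 \in \{0.2, 0.4, 0.6\}$,
$\rho^2/h^2 \in \{0.1, 0.5\}$, $c^2 \in \{0, 0.2\}$.

## What the simulator does and does not emulate

It reproduces the statistical structure the analyses assume: additive
transmission, prevalence-calibrated thresholds, registry-window
censoring, pedigree-derived pair sets. It does not model assortative
mating, dominance or epistasis, pleiotropy across diseases, secular
trends in incidence or diagnosis, variable family sizes, ascertainment
into a biobank, or non-European-ancestry score portability. Passing tests
therefore demonstrate that the pipeline's estimators recover the effects
implied by this generative model — not that any particular real-world
cohort satisfies it. Empirical constants from specific registries
(per-disease odds ratios, exact attenuation percentages, observed
concordance ranges) are data-dependent and are reported by the pipeline,
never asserted by it.
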