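---
title: "Familial concordance of circle of Willis variants: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial concordance of circle of Willis variants: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowfam)
```

## The question and the design

Intracranial aneurysms cluster in families and arise at the circle of
Willis, whose configuration itself varies: segments may be hypoplastic or
absent, the A1 segments asymmetric, the posterior circulation fetal-type.
If CoW configuration is heritable, the first-degree relatives of a family
proband should share the proband's variation more often than the
relatives of an unrelated family. `cowfam` implements that comparison as
a matched events/trials design:

1. classify every imaged individual into variant categories from six
   vessel diameters;
2. per family, count how many of the proband's FDRs share each variant
   (events/trials);
3. match each *index* family, uniformly with replacement, to a
   *comparison* family whose proband's configuration is different, and
   score the comparison family's FDRs against the **index** proband;
4. compare the paired counts with a conditional logistic events/trials
   model; repeat the random matching 1001 times and report medians;
5. pool independent study groups by fixed-effects meta-analysis.

## Classification rules

The four categories and their thresholds (`cow_rules()`):

| rule | definition | default |
|---|---|---|
| hypoplasia | vessel "present" means diameter strictly above threshold | 0.8 mm |
| A1 asymmetry | relative A1 difference strictly above fraction | 33% |
| fetal PC | PcomA strictly more than fraction larger than same-side P1 | 10% |

All three cuts are strict inequalities. Two choices deserve comment.

*The asymmetry denominator.* A ">33% difference" needs a reference; we
use the **larger** A1, so the measure is symmetric in the two sides,
bounded by 1, and a unilaterally absent A1 is a 100% difference. (With
the smaller A1 as denominator a unilateral absence would be undefined.)
Bilateral A1 absence fits none of the four categories and is rejected as
unclassifiable rather than silently coerced.

*Fetal PC and the PcomA calibre.* The fetal rule compares the PcomA only
to its P1; it does not additionally require the PcomA to exceed the
hypoplasia threshold. Whether the source classification imposed such a
requirement is unknown; the rule is applied exactly as stated, so a
hypoplastic P1 beside a normal PcomA is fetal PC. Configurations matching
no rule (for instance, symmetric sub-threshold A1s with an otherwise
normal circle) flow through the pipeline as empty profiles: they are
discordant with everybody, and a family whose *proband* has an empty
profile is excluded from analysis with a warning, since no concordance
column can be anchored on it.

## Concordance and the comparison-proband exclusion

For a single-variant outcome an FDR is concordant when they carry that
variant; the outcome must be one the reference proband carries. For the
"any variation" outcome an FDR is concordant when the two profiles share
**at least one** variant — sharing, not set equality, so a relative with
a strict subset of the proband's variants counts.

When a comparison family is scored against an index proband, its own
proband is never among the trials: the matching constraint makes that
proband discordant by construction, so counting it would only bias the
comparison concordance downward.

Group-level concordance proportions are pooled ratios Σevents/Σtrials
(FDR-weighted), matching the data entering the regression; the unweighted
per-family mean is available via
`pooled_concordance(per_family_mean = TRUE)` but is not the default.

## The matching constraint

"Different configuration" is implemented as **disjoint** variant sets
between the index and comparison probands (`pool_rule = "disjoint"`),
because only disjointness guarantees the comparison proband is discordant
with the index proband for every outcome at once. A weaker
`"not_identical"` rule (sets differ but may overlap) is provided for
sensitivity analysis. An index family whose pool is empty is a hard
error, surfaced with the family id, not silently skipped: an empty pool
means the design's constraint is unsatisfiable for that cohort. One
matching is drawn per iteration and shared by all outcomes.

## The conditional likelihood

Stratum *i* contributes index events/trials $a_i/n_{1i}$ and comparison
events/trials $b_i/n_{2i}$. Treating FDRs within an arm as exchangeable
Bernoulli trials and conditioning on the stratum total $t_i = a_i + b_i$
eliminates the stratum's baseline parameter, leaving the extended
(noncentral) hypergeometric likelihood for the log odds ratio $\beta$:

$$\ell_i(\beta) = \log \frac{\binom{n_{1i}}{a_i}\binom{n_{2i}}{t_i-a_i}
e^{\beta a_i}}{\sum_{u=\max(0,t_i-n_{2i})}^{\min(n_{1i},t_i)}
\binom{n_{1i}}{u}\binom{n_{2i}}{t_i-u} e^{\beta u}}.$$

Strata with $t_i = 0$ or $t_i = n_{1i}+n_{2i}$ contribute exactly zero
and are ignored. No overdispersion correction is applied within arms.

### Numerical policy

- All combinatorial terms are kept in log space; the normaliser uses a
  log-sum-exp with the support midpoint as the stabilising shift, which
  keeps every exponent in range without per-stratum max scans.
- Newton–Raphson on the score $\sum_i (a_i - E_\beta[U_i])$ with the
  conditional information $\sum_i \mathrm{Var}_\beta[U_i]$; start at
  $\beta = 0$, steps clamped to $\pm 5$, convergence when the score drops
  below $10^{-8}$ or the step below $10^{-10}$, at most 50 iterations.
- Complete separation is detected *before* iterating: the score can only
  vanish when $\sum a_i$ lies strictly inside the summed support bounds;
  otherwise the fit is flagged non-converged with the drift direction
  ($\pm\infty$) recorded. Non-converged iterations are excluded from the
  resampling medians; an outcome losing more than half its iterations is
  an aggregation error rather than a silently thin median.
- The standard error is $1/\sqrt{\text{information}}$ at the optimum and
  the 95% CI is Wald on the log scale with $z = 1.959964$ throughout.
  A profile-likelihood CI would be a documented extension; Wald matches
  the conventional output of conditional logistic routines.

The test suite checks the likelihood against naive direct summation, the
optimum against two-stage grid maximisation over $[-10, 10]$ (step
$10^{-4}$ at the fine stage; exact for this log-concave likelihood),
exact arm-swap antisymmetry, degenerate-stratum invariance, the score
equation at the optimum, and agreement with `survival`'s exact
conditional logistic estimator on expanded binary data.

## Resampling and aggregation

The matching is redrawn `n_iterations = 1001` times (odd, so every median
is the middle order statistic). Per outcome we report medians over
iterations of the OR, of each CI bound **componentwise**, and of the
comparison concordance; the index arm never changes across iterations, so
its concordance is a constant. Reproducibility: all randomness flows from
one integer seed, from which per-iteration sub-seeds are pre-drawn, so
results do not depend on evaluation order. Only families whose proband
carries outcome $v$ contribute strata to the $v$-specific model (every
analysable family contributes to "any"); an outcome carried by no proband
is reported as an all-`NA` row rather than an error.

## Meta-analysis

Two groups are pooled on the log-OR scale with inverse-variance weights,
the group standard errors back-derived from the reported median CIs as
$(\log \mathrm{hi} - \log \mathrm{lo}) / (2 \times 1.959964)$ — the
reading under which the published pooled columns are reproducible from
the published group columns. Cochran's $Q$, $df = k-1$ and Higgins
$I^2 = \max(0, (Q-df)/Q) \times 100$ follow, with the ≤60% / >60%
banding. Note that pooling *rounded* group values can move a pooled bound
by up to about its input rounding error; recomputations agree with
published pooled cells to one decimal except where that effect bites,
which the acceptance tests annotate explicitly. No CI for $I^2$ and no
random-effects model are provided.

## The synthetic cohort generator

`sim_params()` defaults encode the study conditions the pipeline is
validated under:

- **122 families** with FDR counts drawn from the printed group-1
  distribution (76 families with one imaged FDR, 25 with two, 6/4/4/3/2
  with three to seven, one with 11, one with 14 — 237/122 ≈ 1.94 expected
  FDRs per family); the group-2 distribution is available as
  `cowfam:::GROUP2_FDR_COUNTS`.
- **Prevalences** classical 0.18, A1 asymmetry 0.22, incomplete PcomA
  0.62, fetal PC 0.26.
- **Aggregation** `familial_sd = 0` for every variant by default: the
  null. Aggregation is opt-in per variant as a family-level normal random
  intercept $b_{fv} \sim N(0, \sigma_v^2)$ on the logit of the member
  carriage probability — the simplest mechanism giving tunable
  within-family concordance without committing to a genetic model.
- **Classical is derived, not drawn**: a member carrying no variant is
  classical with probability $p_c / q_0$, where
  $q_0 = \prod_v (1-p_v)$ is the baseline no-variant mass, so mutual
  exclusion holds by construction and the marginal classical prevalence
  equals $p_c$ exactly at $\sigma = 0$ (feasibility $p_c \le q_0$ is
  checked at construction). For $\sigma > 0$ the family-specific
  no-variant mass varies and the classical marginal drifts slightly below
  target; conditioning on the family-specific mass instead would make the
  acceptance probability exceed one in extreme families, so the
  deterministic baseline form is used.
- `emit_diameters = TRUE` additionally generates six diameters per member
  by constrained draws (normal arteries 1.5–3.0 mm) verified to
  round-trip through `classify_cow()` exactly, with rejection resampling
  capped at 100 attempts.

What the generator does *not* emulate: pedigree-structured transmission
(parents and siblings are exchangeable), co-occurrence correlation among
the non-classical variants beyond what the shared family effect induces
(true cross-variant correlations are unknown; independence given the
family effect is assumed), measurement error in diameters, and
modality/quality patterns (exclusion flags are generated clean). Passing
calibration on synthetic cohorts therefore shows the estimator and design
behave correctly under the stated generative model — not that real
cohorts satisfy that model.

## Validation problem sizes

The calibration and recovery checks run at sizes chosen to keep
Monte-Carlo error well below the effects being asserted while remaining
quick: null calibration uses 200 replicate cohorts of 122 families with
61 matching iterations each (the median OR and CI are already stable at
that depth, and the Monte-Carlo error of the coverage estimate,
$\sqrt{0.95 \times 0.05 / 200} \approx 1.5\%$, sits inside the ±3%
acceptance band); parameter recovery uses 500 strata per true OR
$\psi \in \{1, 2, 3\}$, asserted within three standard errors;
aggregation monotonicity uses a $\sigma \in \{0, 0.8, 1.6\}$ grid with
five replicate cohorts per point, rank-checked on geometric means.

## Known limitations

- Only the two-arm matched events/trials design is supported — no
  covariates (the design cannot adjust for, e.g., sex), no more than two
  arms per stratum.
- Exact-conditional, Wald-CI inference; small-sample disagreement with
  unconditional or Mantel–Haenszel-type estimators is expected and
  documented rather than reconciled.
- The four-category classification omits rarer configurations (incomplete
  A1/P1, azygos ACA); bilateral A1 absence is unclassifiable.
- Input is CSV (a schema-mapping argument covers foreign column names);
  no spreadsheet reader is bundled.
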