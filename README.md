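# cowfam

Familial concordance analysis of circle of Willis variants.

The circle of Willis (CoW) — the arterial ring at the base of the brain
where intracranial aneurysms arise — varies widely in configuration:
hypoplastic or absent segments, asymmetric A1 segments, fetal-type
posterior circulation. `cowfam` asks whether those variations aggregate in
families: are the first-degree relatives (FDRs) of a designated family
proband more likely to share the proband's CoW variation than the
relatives of an unrelated family? The package is aimed at
neuro-epidemiologists running family studies of vascular anatomy, and at
methodologists who need the matched events/trials machinery on its own.

## What it computes

**Variant classification.** From six vessel diameters (both A1, both P1,
both PcomA, in mm) each individual is assigned a set of variant
categories:

- *classical circle*: all six diameters > 0.8 mm, no A1 asymmetry, no
  fetal PC (exclusive of every other category);
- *A1 asymmetry*: |A1L − A1R| / max(A1L, A1R) > 33%;
- *incomplete PcomA*: either PcomA < 0.8 mm;
- *fetal posterior circulation*: a PcomA > 10% larger than the
  ipsilateral P1.

The three non-classical variants may co-occur; a configuration matching
none of the rules carries an empty profile.

**Concordance.** For family *i* and outcome *v*, the concordance count is
(events *aᵢ* / trials *n₁ᵢ*): the number of the family's FDRs sharing *v*
with the proband over the number imaged. Each index family is matched at
random (with replacement) to a comparison family whose proband's
configuration is *disjoint* from the index proband's; the comparison
family's FDRs are then scored against the **index** proband (*bᵢ*/*n₂ᵢ*),
its own proband never counted.

**Model.** Index and comparison arms are compared with a conditional
logistic events/trials model. Conditioning each matched pair on its total
event count *tᵢ = aᵢ + bᵢ* eliminates the pair's nuisance parameter and
leaves the extended hypergeometric likelihood

```
L(β) = ∏ᵢ  C(n₁ᵢ,aᵢ) C(n₂ᵢ,tᵢ−aᵢ) exp(β aᵢ) / Σᵤ C(n₁ᵢ,u) C(n₂ᵢ,tᵢ−u) exp(β u)
```

maximised by Newton–Raphson; `exp(β̂)` is the common odds ratio of
within-family over between-family concordance, with a Wald 95% CI. The
matching is redrawn 1001 times and medians of the OR, CI bounds and
pooled concordance proportions are reported. Two study groups are pooled
by inverse-variance fixed-effects meta-analysis with Higgins I²
(Q-clamped at 0; ≤60% mild/moderate, >60% substantial heterogeneity).

A synthetic-cohort generator (`sim_params()` / `generate_cohort()`)
produces family cohorts with realistic size distributions and
prevalences and a tunable per-variant familial aggregation (a
family-level logit-normal random intercept), so the whole pipeline is
testable and calibratable without patient data.

## Worked example

```r
library(cowfam)

# one individual: left PcomA hypoplastic, asymmetric A1s, fetal PC right
classify_cow(c(a1_left = 2.1, a1_right = 1.2, p1_left = 1.8,
               p1_right = 1.7, pcom_left = 0.5, pcom_right = 2.0))
#> [1] "a1_asymmetry"    "incomplete_pcom" "fetal_pc"

# a synthetic 122-family cohort with familial aggregation of
# incomplete PcomA, analysed end to end
g1 <- generate_cohort(sim_params(n_families = 122,
        familial_sd = c(incomplete_pcom = 0.8), seed = 101), "group1")
st <- run_full_study(list(g1), outcomes = c("incomplete_pcom", "any"),
                     n_iterations = 1001, seed = 11)
print(st, digits = 2)
#> Resampled familial concordance ('group1', 1001 iterations, seed 11, pool rule disjoint)
#>          outcome n_index_families median_index_concordance
#>  incomplete_pcom               75                     0.72
#>              any              117                     0.59
#>  median_comparison_concordance median_or median_ci_low median_ci_high
#>                           0.48         3           1.7            5.3
#>                           0.42         2           1.3            3.2
#>  n_iterations_used
#>               1001
#>               1001
```

Read: among the 75 families whose proband has an incomplete PcomA, 72%
of FDRs share it, against 48% of the FDRs of randomly matched unrelated
families — a median odds ratio of 3.0 (95% CI 1.7–5.3) for within-family
concordance. With two cohorts `run_full_study()` adds the fixed-effects
pooled OR and I² per outcome; `write_results()` exports the tables with
full-precision round-trip and a seed/configuration provenance header.

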