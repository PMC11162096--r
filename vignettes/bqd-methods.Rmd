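---
title: "The Bayesian quasi-likelihood dose-ranging design: models, decisions, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Bayesian quasi-likelihood dose-ranging design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bqdesign)
```

`bqdesign` implements an adaptive, group-sequential dose-ranging design
for phase II trials with `J` arms (`d_1` the placebo/control), a binary
toxicity endpoint and an efficacy endpoint that may be binary, ordinal,
semi-continuous or continuous. This vignette explains the probability
model, the decision rules, the defaults and the numerical choices, and
what the package's simulation-based tests do and do not establish.

## The probability model

**Toxicity.** At each dose the toxicity indicator is Bernoulli(`π_j`) with
a conjugate `Beta(α_T, β_T)` prior, so with `m_j` toxicities among `n_j`
patients the posterior is `Beta(m_j + α_T, n_j − m_j + β_T)`. The default
prior is the vague `Beta(1, 1)`; with no data at a dose the posterior is
the prior.

**Efficacy.** Instead of separate likelihoods per endpoint type, the
outcome is standardized to the unit interval,
`y* = (y − η_min)/(η_max − η_min)`, and treated as a fractional
pseudo-event under a *quasi-Bernoulli* likelihood. Within the stratum of
patients at dose `j` with toxicity outcome `k ∈ {0, 1}`, the pseudo-event
sum `s_jk = Σ y*` (not necessarily an integer) yields the conjugate
posterior `θ_jk | D ~ Beta(s_jk + α_E, n_jk − s_jk + β_E)`. For a binary
endpoint this is exactly the beta-binomial; for bounded endpoints it is a
working likelihood that gives consistent mean estimates with closed-form
updates. Modelling `y | x` in two toxicity strata keeps the joint
distribution available, so outcome-level utility scores remain a possible
extension even though the shipped utilities only use the marginal means.

**Marginal efficacy.** Posterior draws of the mean efficacy on the
original scale mix the strata:
`μ_j(t) = π_j(t) g⁻¹(θ_j1(t)) + (1 − π_j(t)) g⁻¹(θ_j0(t))`, with
`g⁻¹(θ) = θ (η_max − η_min) + η_min`. All draws are sampled independently
across doses and strata from their conjugate posteriors; dependence across
doses enters only through the isotonic transform below.

**Standardization bounds.** For binary and ordinal endpoints the bounds
are the declared endpoint boundaries (defaults `[0, 1]` and `[0, 4]`). For
continuous endpoints they are the observed per-dose minimum and maximum,
recomputed from all accumulated data at each analysis, so `g` is a single
fixed map per dose per interim. Two degenerate cases need a rule the model
itself does not supply: a dose with fewer than two distinct efficacy
values falls back to the pooled observed range across doses (preserving a
valid map while borrowing the only scale information available), and if
even the pooled range is a single point the `θ` draws are set to the
uninformative 0.5. These cases essentially only arise in the first
patients of a trial.

**Monotonicity.** Dose–toxicity curves are almost always monotone, and
dose–efficacy curves usually are; the design imposes monotonicity not on a
point estimate but on the whole posterior, by applying the weighted
pool-adjacent-violators algorithm to every posterior draw vector
`(π_1(t), …, π_J(t))` (always) and `(μ_1(t), …, μ_J(t))` (by default;
`isotonic_efficacy = FALSE` turns it off). Weights are the reciprocal
empirical variances of the unconstrained draws, fixed across draws; the
efficacy transform operates on the marginal `μ` draws computed from the
*unconstrained* toxicity draws, not on the stratum `θ`s. PAVA is exact
(stack-based pooling, implemented in C++ since it runs once per draw per
interim) and is validated in the tests against brute-force enumeration of
all contiguous-block partitions.

## Decision rules

**Utility.** The benefit–risk tradeoff is `U_j = μ_j − w π_j`: one unit of
toxicity rate costs `w` units of mean efficacy (`w = 2` by default; larger
`w` for safety-critical settings). The extended form
`U_j = μ_j − w_1 π_j − w_2 π_j I(π_j > ρ)` adds a penalty once toxicity
exceeds the placebo rate by more than `ρ`, and reduces to the simple form
at `w_2 = 0`. Utility estimates are posterior means of the per-draw
utility, which for the linear form coincides with `μ̂_j − w π̂_j`.

**Admissibility.** Dose `j ≥ 2` stays in the trial only while
`Pr(π_j > π_1 + π̄ | D) < C_T` (safety, default `π̄ = 0.3`, `C_T = 0.9`)
and `Pr(μ_j ≤ μ_1 | D) < C_E` (futility, default `C_E = 0.7`, deliberately
low so futile doses drop early). Probabilities are proportions of matched
posterior draws with strict inequalities and no continuity correction —
relevant because PAVA pooling creates exact ties between arms, which count
against `μ_j > μ_1` and toward `μ_j ≤ μ_1`. The admissible set is
recomputed from all accumulated data at every interim, so a dropped dose
can re-enter if later data exonerate it. The control is always enrolled
but never a member of the set.

**Proof-of-concept, MED and MUD.** PoC is declared when some arm has
`Pr(μ_j > μ_1 | D) > C_PoC` at the final analysis. The MED is the
admissible dose whose posterior mean efficacy is closest to
`μ̂_1 + Δ` (default `Δ = 0.4` on the continuous scale) — the rule is used
exactly as written, without additionally requiring `μ̂_MED > μ̂_1`, since
the futility screen already removes ineffective arms. The MUD maximizes
`Û_j` over the admissible set. Exact ties take the lowest dose index
(conservative and deterministic). An optional flag restricts the MUD to
doses at or above the MED.

**Adaptive randomization.** `p1_j` and `p2_j` — the posterior
probabilities that dose `j` is the MED / MUD — are computed by applying
the MED and MUD rules *draw by draw*, restricted to the current
admissible set, and counting the proportions of draws electing each dose.
(This draw-wise construction is the one consistent with reading the
probabilities as proportions of posterior draws; it is a design choice of
this package.) Stage cohorts after the first are assigned by independent
multinomial sampling from
`p_j ∝ τ p1_j^ν + (1 − τ) p2_j^ν` over the admissible set (`τ = 0.5`,
`ν = 1` by default; `ν = 0` gives equal randomization), with two
adjustments applied to the unnormalized scores before normalizing: the
argmax-`p1` and argmax-`p2` doses are each boosted to
`p_max = max(p1, p2)` so both putative target doses keep high allocation
(at `τ = 1` or `τ = 0` only the relevant vector is used), and the control
receives `min(p_max, 1/(J − 1))` — enough patients to anchor the PoC
comparison without overfeeding the placebo arm. Stage 1 uses near-exact
equal allocation (floor counts plus a uniformly random remainder) rather
than multinomial sampling, honoring "equally randomize"; within a stage
the probabilities are frozen (a group-sequential reading — outcomes are
assumed observed by the next interim, and no refresh happens mid-stage).

## Calibrating the PoC cutoff

`C_PoC` must be calibrated so that, under a null with flat efficacy, the
probability that *any* arm passes the PoC criterion equals a target
familywise type I error (0.05 conventionally). Because the rejection rule
is monotone in the cutoff, one simulation pass suffices:
`calibrate_cpoc()` simulates null trials, records each trial's
`max_j Pr(μ_j > μ_1 | D)` (zero for early-stopped trials, which can never
reject), and returns the empirical `1 − α` quantile (inverse-ECDF type).
This avoids a grid search over cutoffs, at the cost that the returned
cutoff is a step-function statistic of the calibration sample; with 2000
calibration trials the induced error in the re-estimated rejection rate
is well inside binomial noise. A fresh-sample validation of the
calibrated cutoff is part of the test suite.

## The outcome generator

Scenarios specify true per-dose toxicity rates `π_j`, an efficacy profile,
and a latent bivariate normal: `(x̃, ỹ) ~ N((0, μ_j), [[1, ρσ], [ρσ, σ²]])`.
Toxicity is `x̃ > Φ⁻¹(1 − π_j)` — thresholding the *latent* variable, the
only construction that makes the marginal toxicity rate exactly `π_j`;
binary efficacy analogously thresholds the standardized latent
`(ỹ − μ_j)/σ` at `Φ⁻¹(1 − π_{E,j})`; ordinal efficacy bins `ỹ` at shared
cutoffs `γ_1 < … < γ_{K−1}`. The library ships 10 continuous, 6 ordinal
and 6 binary five-arm scenarios plus the flat null, all with `ρ = 0.3`,
`σ = 1`. The ordinal scenarios are stored with target means but without
cutoffs: `calibrate_ordinal_cutoffs()` least-squares fits a shared cutoff
vector to the targets, and the fit is intrinsically approximate — the
achievable spread of binned means is bounded by `Σ_k φ(γ_k − μ)` times the
latent-mean spread, which for these targets is smaller than the printed
spread, so ordinal scenarios are supported for user exploration but
excluded from the package's quantitative acceptance checks. Scenario
metadata records the utility weight and MED target difference implied by
each endpoint type's utility rows (`w = 2, Δ = 0.4` continuous;
`w = 4, Δ = 0.75` ordinal; `w = 1, Δ = 0.2` binary).

What the generator emulates — marginal rates, means, SDs and the latent
correlation — it reproduces exactly by construction, and tests verify it
at `n = 10^5`. What it does not emulate: patient heterogeneity and
covariates, accrual dynamics and delayed outcomes, non-normal efficacy
distributions, and dose–response shapes outside the scenario library. A
design that performs well here may still misbehave under, say, heavy-tailed
outcomes (which stress the observed-range standardization) — the
quasi-likelihood's robustness is an asymptotic mean property, not a
small-sample guarantee.

## Numerical choices and reproducibility

- **Posterior draws:** `T = 4000` per analysis by default, making the
  Monte-Carlo standard error of tail probabilities near a 0.9 cutoff about
  0.005 — small relative to the decision cutoffs' granularity.
- **RNG:** each trial derives two independent L'Ecuyer-CMRG substreams
  from its seed (outcomes vs posterior sampling), and simulation batches
  derive per-trial seeds arithmetically from the master seed, so serial
  and parallel execution, and re-running a single trial of a batch, give
  identical results.
- **Degenerate inputs:** empty strata return priors; constant draw columns
  get variance floored at `1e-12` before weights are formed; an empty
  admissible set stops the trial immediately (no MED/MUD).
- **Ties:** strict inequalities throughout; argmin/argmax ties take the
  lowest dose index.
- **Problem sizes in the shipped tests:** operating-characteristics
  checks use 2000-trial batches (error-control validation at the full
  N = 200 five-stage design), 200 replicates per scenario for true-curve
  recovery at 500 patients/arm, and `10^5` draws for generator fidelity;
  these sizes keep Monte-Carlo tolerances (3 binomial SEs; Bonferroni
  z = 3.5 where many statistics are checked jointly) meaningful.

## Known limitations

- Time-to-event efficacy endpoints and delayed-outcome imputation are out
  of scope; outcomes are assumed observed by the next interim.
- The outcome-score utility over joint `(x, y)` outcomes is an extension
  point, not implemented; only the two marginal utility forms ship.
- `PCS` metrics count trials without PoC or stopped early as incorrect
  selections, which is the strict reading of "percentage of simulated
  trials correctly selecting" — conditional-on-PoC rates can be derived
  from the per-trial records in `tidy()`.
- The weighted-PAVA coupling fixes weights from unconstrained marginal
  variances; alternatives (e.g. re-estimated variances after pooling)
  exist in the isotonic-inference literature and would change posteriors
  slightly.
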