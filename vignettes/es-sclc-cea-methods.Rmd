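---
title: "Methods: cohort cost-effectiveness modelling of first-line tislelizumab in ES-SCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort cost-effectiveness modelling of first-line tislelizumab in ES-SCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

Extensive-stage small cell lung cancer (ES-SCLC) is treated first line with
four induction cycles of platinum–etoposide chemotherapy; adding the PD-1
inhibitor tislelizumab (200 mg every 21 days, continued as maintenance from
cycle 5) prolongs progression-free and overall survival. The package asks
whether that survival gain is worth the drug's price from the Chinese
healthcare system perspective: it computes discounted lifetime costs (CNY),
life-years (LYs) and quality-adjusted life-years (QALYs) per arm, and the
incremental cost-effectiveness ratio (ICER) against a willingness-to-pay
(WTP) threshold of CNY 268,074 per QALY (three times 2023 per-capita GDP).

Two standard cohort engines are implemented over the same three health
states — progression-free (PFS), progressed disease (PD), dead:

* **Partitioned survival (PSM)**: occupancy is read directly off the
  extrapolated curves, `pfs(t) = S_PFS(t)`, `dead(t) = 1 - S_OS(t)`,
  `pd(t) = S_OS(t) - S_PFS(t)` (clamped at zero if the extrapolations
  cross, with a warning).
* **Markov cohort**: time-inhomogeneous per-cycle transition probabilities
  are derived from the same curves. For cycle k,
  `q_d = 1 - S_OS(t_{k+1})/S_OS(t_k)` and
  `q_e = 1 - S_PFS(t_{k+1})/S_PFS(t_k)`; then
  `p(PFS→dead) = min(q_d, q_e)`, `p(PFS→PD) = max(0, q_e - q_d)`,
  `p(PD→dead) = q_d`.

No state-specific mortality is available, so both alive states share the
marginal OS conditional hazard. This choice makes the Markov dead series
reproduce `1 - S_OS` exactly and the two engines agree on occupancy to
numerical precision — the PSM trace is the test oracle for the Markov
engine. Published two-engine analyses of this comparison report slightly
different results per engine; those gaps stem from internal conventions of
the original modelling software that are not recoverable, and we prefer a
self-consistent derivation over reverse-engineering them.

## Survival extrapolation

Trial curves are extrapolated with parametric laws fitted to reconstructed
individual patient data (IPD). Seven candidate families are supported
(exponential, Weibull, Gompertz, gamma, generalized gamma, log-logistic,
log-normal), fitted by maximising the right-censored log-likelihood
`sum_events log f(t) + sum_censored log S(t)` and ranked by AIC (ties by
BIC, then name). `fit_mle()` uses the closed-form exponential maximiser and,
for the other families, Nelder–Mead with three starts on log-transformed
positive parameters followed by a BFGS polish — the multi-start guards
against the generalized gamma's multimodal likelihood. The numeric Hessian
supplies the covariance of the transformed parameters, which the PSA reuses.

The base case uses the published log-logistic fits, in the
(scale α, shape β) parameterisation `S(t) = 1/(1 + (t/α)^β)` with t in
months (α is the median; the fitted OS medians, 16.5 and 15.0 months, sit
next to the trial medians). Time is converted at 365.25/12 days per month,
so a 21-day cycle is 0.6899 months. A Gompertz law with negative shape
plateaus above zero survival; it is allowed for extrapolation but flagged
with a warning, and the fitter does not enter that region.

## Cycle and accrual conventions

The published analysis states a 21-day cycle, a 10-year horizon
(`floor(10 * 365/21) = 173` cycles) and 5% annual discounting of costs and
outcomes, but not its accrual conventions. Those are exposed as documented
switches (`default_conventions()`), and the shipped defaults are the
package's calibrated base case — chosen once so that the base-case
life-years and ICER reproduce the published Table-2-level results, then
frozen:

* **Outcomes at cycle end, no half-cycle correction** (`half_cycle =
  "none"`): LYs and QALYs accrue over cycles 1..173 on end-of-cycle
  membership, each cycle contributing `occupancy × 21/365 years ×
  (1.05)^(-k·21/365)`. Including a full cycle-0 term would add ~0.06 LYs
  per arm and overshoot the published values; a `"standard"`
  (trapezoid) rule is available.
* **Costs at cycle start** (`cost_timing = "start"`): drugs are dispensed
  on day 1 of each cycle, so cycle k's cost is charged on the state at
  `t_{k-1}` (discounted at cycle k).
* **Induction charged per protocol** (`induction_costing = "alive"`):
  every patient alive at the start of induction cycles 1–4 receives that
  cycle's regimen (study drug + etoposide + platinum). From cycle 5 the
  study drug (tislelizumab CNY 2,507.06; placebo 0) is charged while
  progression-free only.
* **Platinum partner cisplatin** (`platinum = "cisplatin"`, CNY 102.81 per
  cycle). The trial allowed cisplatin or carboplatin without reporting the
  mix; `"carboplatin"` and `"mix"` are available. The choice moves the
  ICER by well under 2% because induction chemotherapy is (near) symmetric
  across arms.
* **Subsequent chemotherapy as a one-off course at progression**: 55%
  (tislelizumab) / 67% (placebo) of new PD entrants receive
  `n_sub_cycles = 6` cycles of platinum–etoposide, the conventional upper
  bound of a re-challenge course. New entrants in cycle k are
  `max(0, pd_k - pd_{k-1} + (dead_k - dead_{k-1}) · pd_{k-1}/(pd_{k-1} + pfs_{k-1}))`
  — the net PD increase plus PD deaths replaced within the cycle; under
  the Markov engine the algebraically identical `pfs_{k-1} · p(PFS→PD)` is
  used.
* **Care costs**: best supportive care (CNY 2,467.00/cycle) in PD until
  death; routine follow-up (CNY 600.58/cycle) for all alive patients
  (`followup_states = "alive"`; a PFS-only variant exists).
* **Adverse events once at model entry**: grade ≥3 AE costs
  (`sum incidence × unit cost`) are charged undiscounted at cycle 0, and a
  QALY decrement `sum incidence × disutility × ae_duration_cycles ×
  21/365` (default one cycle) is subtracted. The published AE "utility"
  rows are read as decrements, the only reading consistent with QALY
  magnitudes. Utilities: PFS 0.804, PD 0.321.

With these defaults the package computes (deterministically) 1.91/1.64
discounted LYs, an incremental 0.188 QALYs and an ICER of CNY ~196,200 per
QALY — within the published values' tolerance for both engines. The
absolute per-arm QALY totals remain higher than the published 0.76/0.56,
which are too low to be any utility-weighted occupancy of these curves
(placebo's implied PFS time would be ~1 month against a 4.9-month median);
the original accrual of absolute QALYs is not recoverable, and the
incremental results are the decision-relevant quantities.

## One-way sensitivity analysis

`owsa()` re-evaluates the ICER at each parameter's published low/high bound
(highest/lowest bid price for drug costs, otherwise ±20% for costs and ±10%
for utilities and probabilities), holding all else at base, and sorts by
spread. By default the tornado covers the sampled (gamma/beta) parameters;
the discount rate — a methodological setting, fixed in the PSA, with a
guideline range of 0–8% — is reported as a scenario range and joins the
tornado only with `include_structural = TRUE`. On the default inputs the
top drivers are the PFS utility, the tislelizumab price and the etoposide
price, consistent with the published tornado narrative.

## Probabilistic sensitivity analysis

`run_psa()` performs second-order Monte Carlo (default 1,000 iterations):
costs are drawn from moment-matched gamma distributions, probabilities and
(dis)utilities from moment-matched betas, with standard errors
reconstructed from the published ranges as `se = (high - low)/(2·1.96)`
(ranges read as ≈95% intervals; no SEs are published).

The published inputs carry no uncertainty for the fitted survival
parameters, yet the published cost-effectiveness acceptability curve spans
draw-level ICERs from roughly CNY 125k to 350k — far wider than economic
parameters alone can produce (they yield ~±6% ICER spread and ~100%
acceptability at the WTP). The package therefore samples the four
(log α, log β) pairs from a multivariate normal on the log scale
(`psa_survival = TRUE`): means are the published point estimates;
covariances come from `survival_vcov()`, which refits the log-logistic to
synthetic IPD reconstructed at the trial's sample size (457 patients,
~40-month follow-up). This is the standard propagation of estimation
uncertainty at first-order trial information, and it reproduces the
published CEAC's qualitative shape (50% crossing near the base-case ICER,
2.5–97.5% draw-ICER span ≈ 144k–390k) and acceptability near 90% at the
WTP. `acceptability()` attaches a Wilson 95% interval: at 1,000 draws and
p ≈ 0.9 its half-width is ~1.9 percentage points, the resolution limit of
the published 93.60%/86.70% figures.

## Synthetic trial data

`generate_ipd()` emulates the reconstructed trial IPD: 229/228 patients
per arm; per subject, OS and PFS uniforms are linked by a Gaussian copula
(ρ = 0.5) before inverse-CDF sampling, and PFS is capped at OS so
progression cannot follow death. Observed times are censored by an
exponential loss to follow-up (0.005/month) and administratively at 40
months, mimicking the trial's curve horizon. The copula correlation does
not affect marginal fits (which is all the pipeline consumes); it exists
so subject-level records are internally coherent. What the generator does
*not* emulate: number-at-risk attrition patterns, digitisation error of
the published figures, or any covariate structure — so passing
recovery tests show the fitting stage is correct on clean log-logistic
data, not that digitised-curve reconstruction error is negligible.

## Numerical choices and limitations

* Trace validation enforces the occupancy simplex to 1e-12 per cycle,
  non-decreasing death, and the `(1, 0, 0)` start.
* Quantiles invert the survivor functions to better than 1e-8 across all
  seven families (closed forms where they exist).
* Discounting is discrete at cycle boundaries; continuous compounding
  differs by <0.1% over this horizon.
* Problem sizes in the test-suite simulations (e.g. n = 10,000 parameter
  recovery, 1,000-draw PSA, 3-seed model-selection checks) were chosen as
  the smallest sizes at which the checked properties are statistically
  sharp.
* The engines are three-state by construction: no tunnel states, no
  microsimulation, no correlated PSA sampling across parameters, no
  EVPI. Currency is CNY at 2023 prices with no inflation or conversion
  layer.
* The tislelizumab price range (2,507.06–2,755.00) has its low bound equal
  to the base value; it is stored as published, so its one-way range and
  PSA distribution are asymmetric around the base case.

## Reproducing the headline numbers

```{r, eval = FALSE}
inp <- default_inputs()
cmd_run(inp, engine = "both")
owsa(inp, "markov")[1:3, ]
psa <- cmd_psa(inp, "psm", n_iter = 1000, seed = 1)
psa$summary
```
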