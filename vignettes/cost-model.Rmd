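---
title: "A decision-analytic cost model of fluorescence-guided breast-conserving surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic cost model of fluorescence-guided breast-conserving surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifmicost)
```

## The model

Breast-conserving surgery aims to remove the tumour with tumour-free
(negative) resection margins. When the pathological report finds
malignant cells at the resection edge (positive margins), the patient is
re-excised. Intra-operative fluorescence molecular imaging (IFMI) — a
fluorescent agent such as Bevacizumab-IRDye800CW imaged during surgery —
promises to lower the proportion of positive margins relative to
standard techniques with frozen section analysis (ST), avoiding
follow-up surgeries and the waiting time for frozen sections.

`ifmicost` implements this comparison as a decision tree. A patient's
first surgery leaves positive margins with probability $p_1$ (0.30 for
ST, 0.10 for IFMI at base case); positive margins always trigger a
second surgery, whose margins are positive with probability $p_2 = 0.10$
in either arm; a third surgery is final. The expected number of
surgeries is therefore

$$E[N] = 1 + p_1 (1 + p_2),$$

1.33 for ST and 1.11 for IFMI, an incremental
$\Delta N = (p_1^{IFMI} - p_1^{ST})(1 + p_2) = -0.22$ surgeries per
patient. The effectiveness of IFMI is summarized by the relative risk
$RR = p_1^{IFMI} / p_1^{ST}$ (1/3 at base case); both endpoints are
affine in $RR$, so results over the whole range $RR \in [0, 1]$ follow
by exact linear interpolation of the point estimates.

Every surgery costs the DRG lump sum plus lost productivity
(3{,}508 + 521 = 4{,}029 EUR). IFMI patients additionally pay a one-time
add-on during the first surgery:

$$A = \underbrace{500}_{\text{agent}} + \underbrace{182}_{\text{device}}
    + \underbrace{23}_{\text{draping}} + \underbrace{107}_{\text{staff}}
    + \underbrace{(t_{prol} - s \cdot t_{FSA})\,c - F}_{\text{time delta}},$$

where $t_{prol} = 10$ min of fluorescence inspection, $t_{FSA} = 27$ min
of avoided frozen-section waiting, $s = 0.64$ is the staff time saving
factor (the fraction of FSA waiting time whose staff cost is actually
saved — the senior physician must stay), $c$ is the surgical cost per
minute and $F$ a fixed saving per avoided FSA procedure. The device term
amortizes a 150{,}000 EUR system over 7 years and 200 surgeries/year
plus 10% annual maintenance (182.14 EUR per surgery).

```{r base}
params <- parameter_set()
strategy_table(params$margins, params$costs)
incremental(params$margins, params$costs)
```

Reported euro amounts truncate to whole euros; this reproduces the
published 5,358 / 4,695 EUR pair from the exact 5,358.57 / 4,695.57.
Internally everything is full precision.

## The calibrated time-cost parameters

The source cost model derives the per-minute cost $c$ by dividing a
weighted DRG cost matrix — which is not published — by the expected
surgery duration. We therefore treat $(c, F)$ as explicit parameters and
default them to the unique pair for which the deterministic model
reproduces the two published incremental-cost results simultaneously:
$-663$ EUR at $s = 0.64$ and $+516$ EUR at $s = 0$. Solving the
2×2 linear system ([`calibrate_time_cost()`]) gives $c = 68.229$ EUR/min
and $F = 92.05$ EUR:

```{r calibration}
calibrate_time_cost(margin_model(), cost_parameters())
```

Reassuringly, $c$ is numerically close to the principled non-calibrated
value $(3{,}508 + 521)/59 = 68.29$ EUR/min
(`derive_cost_per_minute()`) — the lump sum per minute of a standard
surgery — which supports the interpretation of $c$ and is used wherever
$c$ must respond to changed inputs: deterministic one-way analyses
rescale $c$ proportionally to `(drg + lost productivity)/st_duration`
(so the base case stays exactly calibrated), and the probabilistic
analysis recomputes it per draw from the sampled values. The small
fixed saving $F$ may absorb, e.g., the pathology procedure cost of the
avoided frozen section; the calibration is agnostic about its
composition.

## Probabilistic sensitivity analysis

`run_psa()` propagates parameter uncertainty by Monte Carlo (10,000
draws by default). Distribution families follow the parameter table:
beta for proportions, gamma for costs, triangular for the three
durations, all fitted from the published mean and standard error by the
method of moments; the staff time saving factor has no published
distribution and stays fixed.

One parameterization choice was genuinely open: a triangular law given
a point estimate and support bounds can put its *mode* or its *mean* at
the point estimate. The two coincide for every symmetric support in the
table, but the FSA duration (27 min on [13, 53]) is asymmetric:
anchoring the mode would give the sampled duration a mean of 31 min,
and Monte-Carlo means of the cost endpoint would then converge to a
value visibly left of the deterministic estimate, breaking the
mean-consistency on which the model's linear-interpolation logic rests.
We therefore parameterize triangular laws by their **mean** (the mode is
derived as $3 \cdot \text{mean} - \min - \max$), keeping the published
support. Every fitted law is thus mean-matched, and PSA means converge
to the deterministic point estimates for quantities affine in the
sampled inputs.

Two sampling modes address another open point: the parameter table
gives the IFMI margin proportion its own beta law, while the
relative-risk sweep ties it to the ST proportion. The default
`fixed_rr` mode samples $p_1^{ST}$ and sets
$p_1^{IFMI} = RR \cdot p_1^{ST}$; it reproduces the published surgeries
interval $[-0.30, -0.15]$, which the `independent` mode (separate beta
draws, wider interval) does not — evidence that the published intervals
were computed under the fixed-RR coupling.

```{r psa}
run_psa(params, n = 10000, seed = 1)
```

The cost interval is close to, though not exactly, the published
$[-1{,}584, 50]$: its bounds depend on unpublished details (the
correlation structure of the draws and the per-draw treatment of $c$),
and the acceptance tests check them as tolerance bands of ±15% of the
interval width rather than as point targets.

## Deterministic sensitivity machinery

* `rr_sweep()` evaluates both endpoints on the seven-level relative-risk
  grid $0, 1/6, \dots, 1$ (IFMI margins 0–30%), with a seeded PSA per
  node; `interpolate_sweep()` interpolates linearly between nodes —
  exact for the affine point estimates, approximate for interval
  bounds.
* `tornado()` perturbs each of the twelve uncertain inputs by ±25% of
  its mean, one at a time, and ranks the induced incremental-cost
  ranges. The endpoint is the incremental cost at the base relative
  risk.
* `run_scenario()` applies named overrides (alternative DRG levels,
  durations with their own triangular bounds, agent price, a lower ST
  margin proportion, staff factor 0 or 1 — see `scenario_presets()`)
  and re-runs the deterministic and probabilistic analyses.
* `threshold_staff_factor()` finds where IFMI starts to save cost as a
  function of the staff time saving factor: the `point` criterion
  solves the linear model exactly ($s^* = 0.280$ at base case); the
  `significance` criterion bisects (tolerance 0.005, fixed seed per
  evaluation, hence a deterministic bracketing function) for the
  smallest $s$ at which the 97.5th percentile of the PSA cost
  distribution reaches zero — about 0.72 under this model's
  distributional assumptions, consistent with the published
  "about two thirds".

## Structural variants and the microsimulation oracle

Variant A acknowledges that re-excision practice is imperfect: after
the first surgery, patients with positive margins are re-excised with
probability $r_+ < 1$ and patients with negative margins with
probability $r_- > 0$; later surgeries follow the base rules. At
$(r_+, r_-) = (1, 0)$ the variant reduces to the base tree to machine
precision, a tested identity. Variant B replaces the margin-driven tree
with an observed distribution of total surgery counts (1–4, allowing
fourth surgeries). The variant probabilities are configuration inputs
with illustrative synthetic defaults in the analysis scripts; the
source study does not print the values it used, so variants are
property-tested, not value-tested.

`simulate_cohort()` is the package's brute-force oracle: it pushes
individual patients through the tree with Bernoulli margin draws and
accumulates each realized path's cost deterministically (the cohort
model is an expectation; the microsimulation's role is verification,
not added realism). Cohort means at $n = 50{,}000$–$100{,}000$ agree
with the closed forms within three standard errors across 20 random
parameterizations — the problem sizes used throughout the test suite,
chosen to keep Monte-Carlo error well below the tested tolerances while
the whole suite runs in seconds.

## Numerical and design notes

* **Seeds.** Every stochastic routine takes an explicit seed; sweeps
  derive per-node seeds as `seed + node index`. Identical seeds give
  bit-identical results.
* **Percentile intervals** use linear interpolation between order
  statistics (R quantile type 7), not a normal approximation.
* **Tie-breaks.** Equal tornado ranges order alphabetically by
  parameter name.
* **Degenerate inputs.** Margin probabilities at 0 or 1 are valid tree
  inputs; their beta laws are infeasible there and degenerate to fixed
  specs. A triangular mean outside the central third of its support has
  no valid mode and is rejected.
* **Truncation.** Displayed euro values use `floor()`; tests compare
  full-precision values wherever a published figure allows it.

## Limitations

The model covers the time from first surgery to return to work after
the last margin-clearing surgery: no recurrence, survival or
quality-of-life modelling, and no currency conversion or DRG grouping —
the DRG lump sum, lost productivity per episode and the staff time
saving factor enter as parameters, not derivations. Costs reflect the
German reimbursement context. The synthetic patient trajectories
emulate Bernoulli margin outcomes with path-deterministic costs; real
patient-level data would add cost heterogeneity within paths,
correlated margin risks, and margin-status-dependent third-surgery
probabilities, none of which the passing tests speak to.
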