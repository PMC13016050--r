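---
title: "A probabilistic cost model for mobile integrated health visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A probabilistic cost model for mobile integrated health visits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mihcost)
```

## The problem

Mobile integrated health (MIH) programs send community paramedics, backed by
a telehealth physician, to deliver acute care in patients' homes. Programs
are typically grant- or institution-funded, and establishing reimbursement
requires knowing what one visit actually costs. The difficulty is that a
program's cost lines — salaries, equipment, fuel, diagnostics, medications —
are each uncertain, and visits differ in complexity: a *basic* visit is a
paramedic evaluation with a telehealth consult and referral, using at most
one diagnostic modality (laboratory **or** radiology) and no intravenous
therapy; an *advanced* visit uses two or more diagnostic modalities and/or
any IV therapy (including fluids). `mihcost` estimates the per-visit cost of
each stratum as a probability distribution rather than a point value.

## The model

Each cost element $i$ carries a beta-PERT distribution specified by a
minimum $a_i$, most-likely $m_i$, and maximum $b_i$:

$$X_i = a_i + (b_i - a_i)\,B_i, \qquad
  B_i \sim \mathrm{Beta}\!\left(1 + \lambda\frac{m_i-a_i}{b_i-a_i},\;
                               1 + \lambda\frac{b_i-m_i}{b_i-a_i}\right),$$

with shape $\lambda = 4$ by default, giving the classical mean
$(a + 4m + b)/6$ and variance $(\mu-a)(b-\mu)/7$. The PERT form weights the
most-likely estimate and damps the extremes relative to a triangular
distribution, which is why it is the standard elicitation distribution in
health-economic probabilistic sensitivity analysis. A degenerate triple
($a = b$) is a point mass, so deterministic cost lines — and exact oracle
tests — are expressible in the same schema.

One Monte Carlo iteration proceeds as:

1. **Sample** every element's value and the annual visit volume $N$ (itself
   PERT-distributed; a point-mass triple fixes it).
2. **Split** $N$ into $n_b = \mathrm{round}(N p_b)$ basic and
   $n_a = N - n_b$ advanced visits ($p_b = 0.60$ by default).
3. **Allocate** the pooled fixed costs $F$ proportionally to the visit
   distribution: the basic stratum receives $F\,n_b/(n_b+n_a)$, the rest
   goes to advanced. Per-period *variable* costs (fuel, vehicle
   maintenance) scale with operations rather than with a single visit; they
   are split by the same rule but stay in the variable totals.
4. **Accumulate** per-visit variable costs: an element with unit cost $c$
   applying to a stratum with $n$ visits contributes $c \cdot n$.
5. **Divide** each stratum's fixed-plus-variable total by its visit count.

Repeating this 1,000 times (the default) yields per-visit cost
distributions summarized by the median (the reported central estimate), the
mean, and a 90% *probabilistic interval* — the 5th and 95th percentiles of
the simulated distribution, computed with linear-interpolation (type 7)
quantiles. We interpret the interval as a percentile interval of the
simulated per-visit cost, not as a confidence interval on the median
estimator; the two differ, and only the former is computed here.

```{r}
cfg <- mih_template()
sim <- mih_simulate(cfg, iterations = 1000, seed = 1)
summary(sim)
```

### Allocation: a deliberate design choice

"Proportionally allocated based on the distribution of visits" is read as
*proportional to visit counts*, which makes the per-visit fixed share
identical in the two strata — the basic/advanced cost gap then comes
entirely from variable costs. Published MIH estimates in which the full-cost
gap between strata is much larger than the unreimbursed-cost gap are also
consistent with *resource-weighted* allocation (e.g. by visit duration), so
`allocate_pooled()` and the configuration accept per-stratum
`allocation_weights`; the default weight of 1 is the pure count-proportional
reading.

### Common random numbers across scenarios

The unreimbursed scenario removes the payor-reimbursed elements (laboratory
analysis; radiology studies and interpretation) via `filter_unreimbursed()`
and re-runs the simulation. Every element draws from an RNG substream keyed
by `(master seed, element id)`, so the two scenarios share draws for every
element they have in common. Consequently the unreimbursed cost is weakly
lower than the full cost *in every iteration*, not merely in expectation,
and scenario contrasts are not polluted by Monte Carlo noise. The
substream-per-element design also makes draw order insensitive to element
position: deleting an element never shifts another element's draws.

```{r}
sc <- mih_scenarios(cfg, iterations = 1000, seed = 1)
summary(sc)
```

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `pert_shape` ($\lambda$) | 4 | — | The universal PERT convention, and the default of the commercial risk-analysis tools practitioners use. Exposed because "modified PERT" analyses vary it. |
| `iterations` | 1000 | — | Standard practice for cost PSA; the convergence test shows the 1,000-iteration median sits within bootstrap error of a 100,000-iteration run. |
| `interval_level` | 0.90 | — | The 5th–95th percentile interval conventionally reported for cost PSA. |
| `annual_visits` | PERT(700, 800, 900) | visits/yr | A mature single-agency acute-care MIH program; point-mass to fix the volume. |
| `prop_basic` | 0.60 | — | Observed complexity mix of acute-care MIH encounters (60% basic / 40% advanced). |
| `allocation_weights` | basic 1, advanced 1 | — | Count-proportional allocation (see above). |
| `seed` | configuration field | — | Everything stochastic is seeded; identical `(config, iterations, seed)` gives bit-identical results. |

## The synthetic program generator

The paper-grade inputs to a model like this (a program's actual dollar
figures) are accounting data and are generally not published. The package
therefore ships:

* **`mih_template()`** — a structurally faithful cost taxonomy: personnel
  (6.5 FTE paramedics, 1.0 FTE administrator, 0.5 FTE physician medical
  direction), administrative costs, annualized non-disposable clinical
  equipment, fuel, vehicle maintenance, laboratory analysis, radiology
  (both flagged reimbursable), and stratum-specific medication/IV elements.
  Its dollar ranges are *placeholder orders of magnitude* from public
  salary and equipment figures, clearly labeled synthetic in the file.
* **`generate_encounters()`** — constraint-first encounter simulation: each
  record's stratum is drawn first (basic with probability 0.60), then
  service usage is sampled *within that stratum's defining constraints*, so
  `classify_visit()` provably recovers the generating stratum and the
  generator and classifier test each other. Per-stratum utilization rates
  (diagnostic probabilities, Poisson medication counts) are plausible
  placeholders — real per-visit utilization is not published — and are
  documented as such.
* **`calibrate_config()`** — a deterministic coordinate search over three
  multiplicative scales (shared cost pool; basic-only variable elements;
  advanced-only variable elements) that rescales the template until its
  simulated medians hit target values. Because each median is nearly linear
  in each scale, each coordinate is updated by a secant step fitted from
  two simulation evaluations; convergence to 2% typically takes ~15
  evaluations. The result is a *demonstration fixture* whose outputs match
  published per-visit medians — a reconstruction, not recovered accounting
  data.

What passing tests on these synthetic inputs shows: the distributional
machinery, allocation arithmetic, scenario logic and summaries are correct,
and the pipeline can reproduce a stated cost profile. What it does not
show: that the template's dollar ranges describe any real program, or that
real encounter-level utilization follows the generator's rates.

## Numerical choices

* **Visit rounding** — `round()` (round-half-to-even) on $N p_b$, remainder
  to advanced, so the counts always sum to $N$ and no systematic bias
  toward either stratum accumulates over iterations.
* **Exact conservation** — the advanced share of any pooled cost is
  computed by subtraction, so shares sum to the pool exactly in floating
  point; the suite checks $n_b c_b + n_a c_a$ against the sampled total at
  $10^{-9}$ relative tolerance.
* **Zero-visit strata** — report `NA` for that stratum's per-visit cost
  rather than dividing by zero; both-strata-empty is an error.
* **Degenerate PERT** — $a = b$ is a point mass handled before the beta
  reparameterization; a mode at an endpoint is allowed (one beta shape
  parameter equals 1).
* **Currency** — binary floating point internally; rounding to cents only
  at the serialization boundary (these are simulation summaries, not
  ledgers), and to whole dollars in printed tables.
* **Quantiles** — type 7 (linear interpolation), fixed and documented so
  results reproduce across platforms.

## Problem sizes used in the test suite

Moment oracles draw $10^6$ samples per parameter triple; the
linearity-of-expectation and convergence checks run $10^5$ iterations;
calibration and scenario checks use the 1,000-iteration default. These
sizes give the 4-standard-error margins used in the assertions while
keeping the whole suite around a quarter of a minute.

## Known limitations

* Costs are modeled independently across elements; real cost lines
  (e.g. fuel and vehicle maintenance) co-move. With independent PERTs the
  per-visit variance is, if anything, understated.
* The model covers operating costs only: overhead, training, taxes,
  utilities and vehicle purchase are out of scope, as are
  cost-effectiveness, billing-code mapping, discounting and multi-year
  horizons.
* The 60/40 complexity mix is a deterministic configuration constant;
  only the annual volume is sampled. A binomial mix would add little
  variance at ~800 visits but could be emulated by widening the volume
  triple.
* Per-visit costs, not annual or per-capita program costs, are the output;
  extending the arithmetic would be straightforward but is deliberately
  not done here.
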