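---
title: "Methods: a microsimulation life expectancy table for type 1 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a microsimulation life expectancy table for type 1 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(let1d)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical conventions, and the
design choices that were genuinely open.

## The estimand and the pipeline

The quantity tabulated is remaining life expectancy (LE): the expected
number of years from a stated baseline age to death, conditional on
having survived to that age with a stated combination of six risk
factors — sex, current age (20/30/40/50 years), current smoking status,
BMI (20/25/30/35 kg/m²), eGFR (30/60/90/120 ml min⁻¹ [1.73 m]⁻²) and
HbA1c (42/64/86/108 mmol/mol, i.e. 6/8/10/12 % NGSP). The Cartesian
product gives 1024 table cells. The pipeline estimates each cell's LE by

1. generating a registry-style reference population
   (`generate_registry_population()`),
2. counting the joint distributions of its binary covariate combinations
   (`build_combination_distribution()`),
3. building one synthetic cohort per cell (`build_synthetic_cohort()`),
4. simulating every member until death, with replications
   (`simulate_cohort()`), and
5. aggregating, assembling and colour-grading the table
   (`aggregate_cell()`, `assemble_table()`, `colourise()`).

`run_pipeline()` orchestrates all stages with hierarchical seeding so the
whole bundle is reproducible from one master seed.

## Event equations

Event risks are parametric proportional hazards on the *age* time scale:
`h(t) = h0(t) exp(lp)` where `lp` sums coefficient × predictor terms plus
age-interaction terms `γ · (x · current age)`. Because a cycle is a full
year, the per-cycle event probability uses the exact cumulative-hazard
increment,

$$p = 1 - \exp\{-[H_0(a{+}1) - H_0(a)]\,e^{lp}\},$$

not the `h × Δt` approximation; this stays a valid probability for
arbitrarily large hazards and is exact for PH models with predictors
frozen at their start-of-cycle values (the package's explicit, testable
convention for time-varying covariates). Three baseline families are
supported per equation — exponential, Weibull (`H0 = rate · t^shape`) and
Gompertz (`H0 = rate/shape · (e^{shape·t} − 1)`, evaluated through
`expm1` for numerical stability near `shape = 0`). The three families
span the standard parametric survival baselines without committing to a
single unpublished choice.

The event list has 14 equations: fatal and non-fatal MI, fatal and
non-fatal stroke, heart failure, angina, peripheral vascular disease,
amputation, hypoglycaemia, hyperglycaemia, ESRD, PCI, CABG and all-cause
death. Within a cycle every equation is drawn as an independent
Bernoulli from start-of-cycle state, in the model's
`event_evaluation_order`; multiple non-fatal events may co-occur, and any
fatal draw (all-cause death by definition; fatal MI/stroke via their
`fatal` flag) dominates the cycle. Whether fatal MI/stroke should be
additive to, or nested within, all-cause death is not determinable here;
both wirings are expressible through the `fatal` flags and the
evaluation order, with additive fatal equations as the shipped default.
Drawn non-fatal events set monotone history flags and reset the
corresponding `t_since_*` auxiliary counters (event "at baseline" = 0
years; counters increment each later cycle), which gives the generic
representation for auxiliary variables like time since last
hyperglycaemia.

## Progression equations

Ten equations update the risk factors once per cycle, after event draws
(so progression is effective the *next* cycle). Continuous targets
(HbA1c, BMI, SBP, triacylglycerols, HDL, LDL, eGFR) use a linear rule —
next value = linear predictor + optional Gaussian noise — clamped below
at 0 to forbid non-physical negatives; no upper clamp is applied. Binary
targets use logistic transitions: micro- and macroalbuminuria are
absorbing (never revert), while smoking status may move both ways, a
quitter becoming a former smoker so current/former remain mutually
exclusive. All linear predictors in one progression step are evaluated
on the incoming state snapshot (simultaneous update), which makes the
update order-free and the zero-noise case exactly deterministic. These
minimal standard forms were chosen because the source system's
functional forms are unpublished; they are configuration-swappable.

HbA1c is stored in IFCC mmol/mol; the NGSP percent scale is available to
every equation as the derived predictor `hba1c_ngsp` through the linear
master equation `NGSP% = 0.09148 · IFCC + 2.152` and its exact inverse.

## The synthetic registry population

`population_summary()` declares the reference population: marginal
proportions of 16 binary characteristics, mean ± SD of 9 continuous
factors (e.g. 55.6 % male, 13.6 % current smokers, BMI 24.90 ± 3.71
kg/m², HbA1c 65 ± 13 mmol/mol, n = 27,841 at registry scale), and a
pairwise log-odds-ratio matrix for binary co-occurrence. The generator
realises it as follows.

* **Continuous factors** are drawn from normals truncated below at 0 via
  the inverse-CDF map, with age-at-onset additionally truncated above at
  the individual's age. For most factors truncation is numerically
  negligible; for triacylglycerols (mean 1.16, SD 0.85) it raises the
  realised mean visibly, so moment-recovery tests compare against the
  analytic truncated-normal mean rather than the parent mean. Continuous
  factors are sampled independently of each other: the summary carries
  no covariance information, and declaring none is more honest than
  inventing one.
* **Binary histories** (11 complications plus micro/macroalbuminuria)
  come from a Gaussian copula: each variable is a threshold indicator
  `Z > Φ⁻¹(1−p)`, and each nonzero pairwise log odds ratio is converted
  to a latent correlation by numerically inverting the 2×2 table induced
  by the bivariate normal (tail probabilities via adaptive quadrature,
  root-finding bracketed on the half-interval matching the target's
  sign). Infeasible requests fail naming the offending pair. The default
  dependence places log OR 1.0 among the macrovascular complications
  (MI, stroke, CHF, PCI, CABG, angina, PVD) and between micro- and
  macroalbuminuria, zero elsewhere — a declared, qualitative stand-in
  for "complications beget complications", not an estimate.
* **Smoking** is drawn as one three-category multinomial
  (current 13.6 % / former 4.3 % / never), which preserves both
  marginals *and* mutual exclusivity exactly. Folding former-smoker into
  the copula with a conflict-resolution rule would distort its marginal;
  the multinomial keeps it independent of the other binaries, as
  intended, without that distortion.

What the generator does **not** emulate: longitudinal visit structure,
follow-up time, calendar effects, continuous–continuous correlation, or
any joint structure beyond the declared pairwise log odds ratios. Tests
passing on this population therefore demonstrate correctness of the
pipeline's machinery, not fidelity to any real registry's full joint
distribution.

## Synthetic cohorts

Each cell's cohort (default 1000 members) sets covariates by category:
table factors at the cell's levels; hidden binaries sampled jointly —
complication histories from their empirical combination distribution,
albuminuria from a second one, former smoker as an independent Bernoulli
forced to 0 in smoker cells; hidden continuous factors pinned at the
population means (age at onset 15.01, SBP 127.30, TG 1.16, HDL 1.59,
LDL 2.72); age interactions derived afterwards and recomputed every
cycle. Combination identifiers are ordered lexicographically on the 0/1
vector, making them invariant to row permutations of the source
population; sampling is by inverse transform (first identifier whose CDF
reaches the uniform). `t_since_*` for sampled positive histories
defaults to 0 ("event at baseline"), configurable, since no values for
these auxiliaries are published. Because table factors consume no
randomness, cohorts for different cells built from the same seed share
identical hidden-covariate streams — deliberate support for
common-random-numbers contrasts between cells.

## Simulation, replication and seeding

Each member is simulated to death in annual cycles, with survival
recorded as completed cycles plus a half-cycle credit in the death year
(the standard discrete-time correction, toggleable via
`half_cycle_correction`); death is forced at `max_age` = 120 years,
which guarantees termination and caps survival at `120 − baseline age`.
Per-individual LE is the mean over replications (default 100), which
suppresses first-order (stochastic) uncertainty — the variability
between identical individuals due to random event draws.

Random streams follow a counter-based contract: the stream for
(individual *i*, replication *r*) of a cell is seeded by
`mix_seed(master_seed, cell_key, i, r)`, a 32-bit splitmix-style hash.
Streams are therefore independent across triples, reconstructible
without stored state, and identical across models run with the same
master seed — which is what makes the monotonicity property testable:
raising the death equation's HbA1c coefficient under shared streams can
only shorten (never lengthen) any individual's simulated life.

## Aggregation, colour grading and output

Cell LE is the mean of per-individual LEs; the SD is the sample standard
deviation (n − 1) across the cohort's members, describing between-
individual spread; the SE is SD/√n, describing precision of the cell
mean. Both are emitted because both are legitimate summaries and the
choice between them is presentational; age at death is baseline age +
LE, an exact identity. Colour grading normalises the chosen metric
within each age–sex stratum (or the whole table) to [0, 1] and
interpolates linearly in Lab space between dark red `#A50026` (minimum)
and green `#006837` (maximum); a constant group maps to the midpoint
colour, ties get identical colours, and a greyscale variant maps the
same normalised value to lightness. Displayed values are rounded to one
decimal, half away from zero. The CSV writer serialises numerics as
`%.17g`, so `read_life_table(write_life_table(x))` is lossless; the HTML
rendering (default layout rows = eGFR × HbA1c, columns = age × sex ×
smoking × BMI, configurable) is self-contained with no external assets.
The exact row/column arrangement is presentation only; any lossless
arrangement carries the same information.

## Ground-truth models

The fitted coefficients of the source equation system are not published,
so the package ships `generate_ground_truth_model()`: a seeded generator
producing a complete, valid 14 + 10 equation model whose coefficient
signs follow a declared effect configuration (HbA1c and smoking harmful,
eGFR protective, BMI U-shaped with the hazard minimum at 25 kg/m² via
paired `bmi`/`bmi_sq` terms, positive history-of-complication effects on
death). Each equation's linear predictor is centred at a reference
20-year-old male at registry-mean covariates, making baseline rates
directly interpretable; the death baseline is Gompertz
(rate 5.24 × 10⁻⁵, shape 0.1), solved so the reference individual's
annual-cycle LE from age 20 is 50 years before complication burden —
realised LE with complications and progression lands near 37, inside
the plausible 25–60-year band for the disease. These models exist to
make every downstream stage testable and to demonstrate qualitative
behaviour; their outputs are not estimates of any population's life
expectancy.

## Numerical conventions and degenerate inputs

* Gompertz increments use `expm1`; `shape = 0` degenerates exactly to
  the exponential.
* Event probabilities are clamped to [0, 1] after the closed form; a
  non-finite probability aborts with the equation name and cycle.
* Copula tail probabilities integrate to relative tolerance 1e−11;
  latent-correlation roots to 1e−9; non-positive-definite latent
  matrices are an error, not silently repaired.
* `n = 1` populations, single-level grids, single-replication runs and
  constant-metric strata are all defined (not errors).
* Uniform draws at exact CDF step values select that step's identifier
  (intervals closed on the right).

## Problem sizes

The shipped scales are the package's two presets: `"full"` (1024 cells
× 1000 members × 100 replications, registry n = 27,841) and `"demo"`
(16 cells × 200 × 10, registry n = 20,000), the latter chosen so a
complete end-to-end run with every code path takes minutes on a single
CPU. The test suite exercises the oracles at the sizes their error
bounds need (10⁵ draws for the geometric engine oracle, 10⁵–10⁶ for
sampler fidelity, the full registry n = 27,841 for marginal recovery)
and smaller cohorts elsewhere.

## Known limitations

* All equation content is configuration; absolute LE values produced
  with generated models are illustrative only.
* The copula reproduces pairwise dependence, not higher-order joint
  structure; the combination distributions downstream are exactly
  empirical, so this limitation applies only to the generated reference
  population, not to the cohort-building machinery.
* Progression forms are the minimal linear/logistic conventions; real
  risk-factor trajectories (nonlinear drift, treatment effects,
  measurement error) are out of scope.
* The engine is single-threaded by design; determinism of the seeding
  contract, not parallel throughput, is the guarantee.
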