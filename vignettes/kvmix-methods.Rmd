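---
title: "Models and methods in kvmix"
author: "kvmix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in kvmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

kvmix analyzes how gain-of-function (GoF) mutant subunits reshape the
gating of heteromeric Kv10 (ether-à-go-go) potassium channels, and how
that reshaping shows up in the resting membrane potential of cells that
express the channels. This vignette documents the models, the
estimation choices, what the synthetic-data generators do and do not
emulate, and the known limitations.

## 1. Steady-state activation

Whole-cell steady-state currents of a homomeric channel population are
described with a linear single-channel characteristic and a single
Boltzmann activation gate:

$$I(V) = \Gamma\,(V - E_{rev})\,\bigl[1 + e^{-(V - V_n)/k_n}\bigr]^{-1}$$

with total conductance $\Gamma$ (nS), reversal potential $E_{rev}$
(mV), half-maximal activation voltage $V_n$ (mV) and slope factor $k_n$
(mV). Units are fixed package-wide (mV, pA, nS, s); the identity
1 nS × 1 mV = 1 pA makes $\Gamma (V - E_{rev})$ a current. A single
gate is deliberately minimal — tetrameric channels have more than one
voltage sensor — but it yields $V_n$ and $k_n$ values that are directly
comparable across constructs, which is the point of the analysis.

$E_{rev}$ is treated as known: with 140 mM external / 130 mM internal
K⁺ the Nernst potential at 20–25 °C rounds to +2 mV
(`nernst_potential(140, 130)`), and `fit_wildtype_iv()` therefore fixes
it by default (`fix_e_rev = FALSE` frees it).

### The binomial heteromer mixture

Coexpression of wild-type and mutant subunits is modeled with four
assumptions: (i) the mutation's main effect is a left shift of $V_n$;
(ii) a hypothetical all-mutant channel has half-activation voltage
$V_{ns}$ (hypothetical because homomeric mutant channels conduct no
current); (iii) the slope factor is unaffected ($k_{ns} \equiv k_n$,
the default; `fix_k_ns = FALSE` unties it, in which case the
per-composition slope factor is interpolated linearly like $V_n$);
(iv) subunits assemble binomially, each of the four positions being
mutant with probability $p_s$. Compositions with $m = 0..3$ mutant
subunits contribute Boltzmann gates centered at
$V_n + (m/4)(V_{ns} - V_n)$ with binomial weights
$\binom{4}{m} p_s^m (1-p_s)^{4-m}$; the $m = 4$ term carries no
current. The weights are implemented with these explicit closed-form
polynomials, which are exact at the dyadic $p_s$ values used in the
checks. `mixture_iv()` reduces exactly to `hh_current()` at $p_s = 0$
and vanishes at $p_s = 1$; a Monte-Carlo tetramer-assembly oracle
(10⁶ sampled channels) agrees with it within 3 standard errors at
every test voltage.

### Fitting

Because published IVs are normalized to the current at +30 mV,
$\Gamma$ is not identifiable from them; the fits replace it with a free
dimensionless scale (`amp`), reported separately. The reference match
is exact — no interpolation; normalizing at a voltage absent from the
protocol is an error.

All fits are bounded least squares (Levenberg–Marquardt,
`minpack.lm::nls.lm`, `ftol` 1e-12 / `ptol` 1e-10) run from five start
points: the supplied guess and four fixed ±20% perturbation patterns.
The perturbations are deterministic rather than random so that fitting
never consumes the caller's RNG stream; the multi-start matters because
the mixture model's $(V_{ns}, p_s)$ surface has shallow valleys.
Convergence requires a successful optimizer status and no free
parameter at its bound; non-convergence is flagged, never thrown.
95% confidence half-widths come from the linearized covariance
$(J^\top J)^{-1}\,\mathrm{RSS}/(n - p)$ with a $t$ quantile
(profile-likelihood intervals are out of scope). When $J^\top J$ is
singular, an eigen pseudo-inverse is used and parameters with weight in
the null space are reported with infinite intervals; any parameter
whose interval covers at least half its search range is flagged
unidentifiable. That is exactly what happens to $V_{ns}$ when the data
contain no mutant signature ($p_s \to 0$).

The wild-type slope factor is never printed in the source reports for
these constructs; the package uses a documented default of
$k_n = 12$ mV in its presets (`preset_params()`). This is a choice,
not a published value, and recovery tests treat it as such.

### Leak subtraction

Linear (ohmic) leak is estimated offline by regressing the
steady-state current against step voltage over sweeps at or below
−100 mV — below the activation range of wild-type Kv10 channels — and
subtracted pointwise using each segment's command voltage. Caveat:
GoF heteromers are already partially activated at −120 mV, so no leak
window free of channel activity exists for coexpression data; there,
use generator-known leak or skip subtraction. The regression window is
configurable because the original offline procedure is not specified
further.

## 2. Tail-current deactivation

Upon repolarization (to −120 mV in the emulated protocol), each
composition closes with its own time constant: homomeric wild type
with $\tau_{fast}$ (milliseconds), and the mutant-containing
compositions 1:3, 2:2, 3:1 (wild-type:mutant) with $\tau_{slow}$,
$\tau_{slow}/f$, $\tau_{slow}/f^2$ — a geometric ladder with scaling
factor $f$. The tail current is

$$I(t) = A \sum_{m=0}^{3} w_m(p_s)\, e^{-t/\tau_m},$$

where $p_s$ is now the probability of a mutant subunit among the
channels *open at the end of the test pulse*. The 0:4 weight is absent
(no current), and the remaining weights are deliberately not
renormalized — the per-trace amplitude $A$ absorbs the constant.
At $t = 0$ the model equals $A(1 - p_s^4)$, and its area
$A \sum_m w_m \tau_m$ matches numerical integration to better than
0.1%.

`global_fit_tails()` fits a whole voltage family jointly: one shared
$\tau_{fast}$, $\tau_{slow}$, $f$; one free positive amplitude per
trace; and $p_s$ either shared or per test voltage. Per-voltage $p_s$
is the default: channels built mostly of wild-type subunits only open
at strong depolarizations, so the open-channel subunit mix is voltage
dependent even though assembly is not. Fitting is in linear current
space with uniform weights — tails span decades only at long times,
where noise dominates anyway. Bounds: $\tau_{fast} \in [10^{-4}, 1]$ s,
$\tau_{slow} \in [10^{-2}, 100]$ s, $f \in [1, 100]$. Initialization:
$\tau_{fast}$ from the log-slope over the initial 10%-amplitude drop
of the most depolarized trace (scaled down for the slow-component
admixture), $\tau_{slow}$ from a log-linear fit of the final third of
the least depolarized trace, $f = 3$. Traces shorter than three slow
time constants fit with a warning; expect widened intervals. Whether
$\tau_{fast}$ should be fixed from wild-type-only recordings or co-fit
is not prescribed; both are supported and co-fitting is the default.
The model assumes a zero asymptote, i.e. baseline-subtracted tails.

With data generated at the reported kinetics ($\tau_{fast} = 8$ ms,
$\tau_{slow} = 5$ s, $f = 5$) and 1% noise, the linearized 95%
intervals for the three kinetic constants cover the truth 90–99% of
the time over 200 replicates — provided the noise SD is shared across
traces, which is how the generator defines its noise fraction (of the
family's largest amplitude), consistent with the fit's uniform
weights.

## 3. Ratiometric voltage imaging

The optical pipeline converts per-cell green/red fluorescence ratios
of a genetically encoded voltage indicator (a voltage-sensitive green
fluorophore fused to a voltage-insensitive red partner) into resting
membrane potentials.

**Calibration curve.** The published constants ($R_{max} = 2.86$,
$\Delta R = -2.39$, $V_{half} = -31.8$ mV, $k_s = 25.3$ mV) are
combined in a single Boltzmann,

$$R(V) = R_{max} + \Delta R\,\bigl[1 + e^{-(V - V_{half})/k_s}\bigr]^{-1},$$

chosen here as the minimal monotone form consistent with the constant
names and with hyperpolarization increasing $R$ ($\Delta R < 0$). The
exact functional form of the original calibration is not restated in
the source report; this is a documented assumption of the package, not
a quoted equation. The analytic inverse `ratio_to_voltage()` round
trips to 1e-9 mV; ratios outside the open gamut
$(R_{max} + \Delta R,\, R_{max})$ error, or clamp on request.

**Segmentation.** Nuclei are found in the blue (Hoechst) channel:
rolling-ball style background subtraction — implemented as a grayscale
morphological opening with a disc of the configured radius (default
74 µm; the ImageJ paraboloid variant is not reproduced) — then a
threshold (Otsu by default, manual override supported), watershed on
the distance transform to split touching nuclei, connected components,
and exclusion of border-touching particles and particles outside
7.5–19 µm². The default pixel size is 0.73 µm/px (configurable; the
effective camera pixel size at 10× is not stated in the source).
Coordinates are 0-based, row-major; areas use pixel-size². Green
fluorescence is read from the **fourth** of four frames so that the
photoswitchable indicator is measured only after complete
photoswitching. The blue channel is used for segmentation only, never
for gating.

**Adaptive background.** Residual medium autofluorescence adds a
constant $b$ to F_green that biases the ratio of weak expressors. The
estimate $b^*$ minimizes the squared slope of the linear fit of median
$(F_{green} - b)/F_{red}$ against $F_{red}$ over 8 equal-count bins
(golden-section search on $[0,\,0.9\min F_{green}]$). Two practical
points discovered during development: (a) the estimate is made **per
dish** in `analyze_imaging()` — background is a property of the dish's
medium, and pooling dishes of different constructs makes the ratio
distribution multimodal, which destabilizes the bin medians; (b) shot
noise on the red channel produces a spurious $1/F_{red}$ ratio
component of size $\mathrm{gain}\cdot R\cdot\sigma^2$ that is exactly
degenerate with the background term, so the method presumes the red
(normalizer) channel is acquired at low noise — as it is in the
emulated acquisition, where the red camera gain is 5.1 versus 64 for
green. The generator models this per-channel noise ratio.

**Gating.** Cells with very high F_red are excluded (camera dynamic
range), as are low-F_red cells (largest background-subtraction error).
The source states no numbers; defaults are the per-dish 5th percentile
(low) and the dataset 98th percentile capped at 90% of full scale
(high), all configurable.

**One-point anchor.** Gramicidin depolarizes cells to ~0 mV; the mean
of the per-dish median ratios of gramicidin dishes defines the
measured 0-mV ratio, and all experimental ratios are rescaled so that
it maps onto $R(0)$. Rescaling is multiplicative by default (ratio
errors from gain drift are multiplicative); an additive mode exists.
When several imaging sessions exist, anchoring is per batch.

**Summaries.** Per-dish median and mean voltages, with the
dataset-level mean of dish medians — dishes, not cells, are the unit
of replication.

## 4. Synthetic data

The generators produce every input the analysis consumes, with a
ground-truth attribute sufficient to score downstream estimates; they
never call fitting code. All randomness flows from a single seed per
generator, applied without disturbing the caller's RNG state; the same
seed reproduces identical output.

* `gen_iv_curve()` / `gen_iv_dataset()`: steady-state IVs and full
  step-trace families from the activation models, with optional
  single-exponential activation kinetics (a realism device for testing
  window placement only — no Markov gating scheme), linear leak, an
  appended deactivating tail segment, and Gaussian noise scaled to the
  per-sweep maximum (default 1%).
* `gen_tail_dataset()`: binomial multi-exponential tails sampled at
  1 kHz by default — the sampling must resolve the millisecond-scale
  wild-type deactivation.
* `gen_imaging_dataset()`: per-cell tables (true voltage drawn per
  construct, log-normal F_red expression,
  $F_{green} = \mathrm{gain}\cdot F_{red}\cdot R(V) + b$, camera
  offset, gain-scaled Poisson-like noise per channel, gramicidin
  dishes forced to 0 mV) or rendered positions (nuclear disks, a
  4-frame green photoswitching ramp saturating by frame 3–4, green and
  red over circular soma masks). Soma morphology realism is explicitly
  not a goal, and membrane fluorescence is rendered across the nucleus
  footprint, as in real wide-field images, so that nuclear ROIs sample
  it.

What passing recovery tests on these data does **not** show: that real
recordings satisfy the single-gate simplification, that real assembly
is exactly binomial, that activation reaches steady state within 5-s
pulses at all voltages (it does not for slowly activating channels),
or that real cameras have exactly Poisson noise. The generators encode
the models' own assumptions; recovery demonstrates estimator
correctness, not model truth.

## 5. Problem sizes and reproducibility

The shipped checks use: 100 seeded replicates for IV parameter
recovery (16 voltages, 1% noise); one five-trace tail family at 1 kHz
× 16 s plus a 200-replicate coverage study on a reduced three-trace
family (400 Hz × 12 s); and a table-level imaging experiment of
6 dishes × ~1000 cells per condition across four constructs plus two
gramicidin dishes. `scripts/acceptance.R` re-runs the IV recoveries
from scratch and writes the mean recovered $V_n$ (Kv10.1, Kv10.2) and
$V_{ns}$ (coexpression) as JSON.

## 6. Known limitations

* No Markov-state kinetic scheme, no Mg²⁺-dependent activation
  slowing, Ca²⁺/calmodulin inhibition, or PIP₂ modulation; no p/4
  online leak protocol; no series-resistance correction (voltages are
  command voltages).
* The calibration functional form and the $k_n$ preset are documented
  assumptions (see above).
* Linearized confidence intervals can undercover in strongly nonlinear
  regimes (short tails, boundary $p_s$); the unidentifiability flags
  are heuristics, not tests.
* The adaptive background estimator is variance-limited below a few
  thousand cells per dish and biased when the normalizer channel is
  noisy (Section 3).
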