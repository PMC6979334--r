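---
title: "Deriving photosynthetic traits from gas exchange and fluorescence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving photosynthetic traits from gas exchange and fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photrait)
```

## The measurement problem

High-throughput phenotyping of photosynthesis pairs a single steady-state
gas-exchange measurement with simultaneous chlorophyll fluorescence, so
that each leaf yields one record of net assimilation $A$, stomatal
conductance $g_{sw}$, intercellular CO$_2$ $C_i$ and PSII operating
efficiency $\Phi_{PSII}$ at saturating light. photrait turns such records
into the biochemical traits breeders and ecophysiologists screen on:
electron transport rate $J$, mesophyll conductance $g_m$, maximum
carboxylation rate $V_{cmax}$ and intrinsic water-use efficiency
$A/g_{sw}$, plus nonrectangular-hyperbola summaries of full
light-response curves.

## Per-record trait derivation

Electron transport is estimated from fluorescence as
$$J = \Phi_{PSII} \cdot \mathrm{PPFD} \cdot \alpha\beta,$$
with $\alpha\beta = 0.44$ by default — the product of leaf absorptance
and the fraction of absorbed quanta reaching PSII, a standard rice
calibration. Only the product is identifiable from this design, so the
two factors are deliberately not stored separately.

Mesophyll conductance uses the variable-J inversion
$$g_m = \frac{A}{C_i - \dfrac{\Gamma^*\left(J + 8(A + R_d)\right)}{J - 4(A + R_d)}},$$
whose second term is the chloroplast CO$_2$ mole fraction $C_c$ implied
by RuBP-regeneration-limited demand. Defaults $\Gamma^* = 40\;\mu$mol
mol$^{-1}$ and $R_d = 1\;\mu$mol m$^{-2}$ s$^{-1}$ are typical rice
values. The estimate is reliable only in an intermediate sensitivity
window of
$$\frac{dC_c}{dA} = \frac{12\,J\,\Gamma^*}{\left(J - 4(A+R_d)\right)^2},$$
implemented as the acceptance window $10 \le dC_c/dA \le 50$
(configurable via `qc_low`/`qc_high`). The inequality chain is sometimes
typeset with both comparisons pointing the same way, which is
unsatisfiable; the closed interval is the reading consistent with the
sensitivity analysis the criterion comes from. Note that $C_c$ — and
hence $g_m$ — is strictly *decreasing* in $J$ at fixed $A$, $C_i$,
$R_d$: more electron transport for the same assimilation implies more
photorespiratory demand and a lower implied drawdown.

One-point $V_{cmax}$ assumes a Rubisco-limited, light-saturated leaf
with $R_d = 0.015\,V_{cmax}$:
$$V_{cmax} = A\left(\frac{C_i + K_m}{C_i - \Gamma^*} - 0.015\right),
\qquad K_m = K_c\left(1 + \frac{O_i}{K_o}\right).$$
$K_c = 404.9\;\mu$mol mol$^{-1}$, $K_o = 278.4$ mmol mol$^{-1}$ and
$O_i = 210$ mmol mol$^{-1}$ are the usual 25 °C calibration; they are
explicit in `kinetic_constants()` and overridable. The formula above
(`form = "printed"`) is the common field form, but it is *not* the exact
algebraic inversion of the Rubisco-limited demand equation under the
1.5 % respiration assumption; the exact inversion is
$$V_{cmax} = \frac{A}{\dfrac{C_i - \Gamma^*}{C_i + K_m} - 0.015}$$
(`form = "inverted"`). The two differ by the factor
$(1 - 0.015f)(1 - 0.015/f)$ with $f = (C_i-\Gamma^*)/(C_i+K_m)$, several
percent at typical $C_i$. The package exposes both: `"printed"` is the
default for comparability with published population screens, while
`"inverted"` is the self-consistent form that recovers the true
$V_{cmax}$ exactly on simulated Rubisco-limited leaves and is what the
recovery tests use.

No leaf-temperature adjustment is applied anywhere: measurements at the
28 °C cuvette setpoint are processed with 25 °C-calibrated constants,
exactly as the screening protocol itself does. Temperature response
functions are out of scope by design.

CO$_2$-basis stomatal conductance uses the binary diffusivity ratio
$g_{sc} = g_{sw}/1.6$. Singular or unphysical computations
($J \le 4(A+R_d)$, $C_i \le \Gamma^*$, nonpositive denominators) yield
flagged missing values with reason codes, never exceptions, so one bad
record cannot abort a several-hundred-line batch; QC-passing and failing
counts always reconcile to the input count.

The steady-state detector implements the acquisition rule "record once
$A$ changes by less than 0.5 % over one minute": a sample qualifies when
every point in its trailing 60 s window lies within the relative
tolerance of it.

## Light-response curves

The four-parameter nonrectangular hyperbola is
$$A(Q) = \frac{\phi Q + A_{gmax} -
\sqrt{(\phi Q + A_{gmax})^2 - 4\theta\,\phi Q\,A_{gmax}}}{2\theta} - R_n.$$
With the $2\theta$ denominator the model satisfies all of its documented
limits: $A(0) = -R_n$, initial slope $\phi$, asymptote
$A_{gmax} - R_n$, Blackman response at $\theta = 1$ and the rectangular
hyperbola as $\theta \to 0$ (handled by the limit formula, not division
by zero). A $4\theta$ denominator variant circulates in print; it halves
every one of those limits, so the package treats it as a typographic
slip, defaults to `denominator_mode = "standard2theta"`, and retains
`"printed4theta"` for exact reproduction of published parameter sets.

$R_d$ in the variable-J equation and $R_n$ here are conceptually related
(daytime vs dark respiration) but are kept as separate configurable
parameters; the protocol never states they are the same quantity.

Fitting follows the orthogonal (total) least-squares tradition for AQ
curves: each observation is given a foot point on the curve and the
parameters and foot abscissae are optimised jointly by
Levenberg–Marquardt (`minpack.lm::nls.lm`) on the stacked residual
vector, warm-started from an ordinary least-squares fit. Numerical
choices that matter:

* **Axis scaling.** Orthogonal distances are measured after scaling PPFD
  and $A$ by their data maxima, so a 0–2000 light axis does not swamp a
  0–40 assimilation axis.
* **Foot-point extrapolation.** Foot abscissae may move below
  $Q = 0$; clamping them at zero puts the dark point on a kink of the
  objective and systematically inflates the fitted $R_n$.
* **Multi-start over convexity.** Box-constrained LM can stall on the
  $\theta = 1$ boundary for near-Blackman curves, so the warm-start OLS
  stage is multi-started over $\theta_0 \in \{0.3, 0.6, 0.9, 0.99\}$ and
  the lowest-RSS solution kept.
* **Initialisation.** $R_n = \max(-\min A, 0.1)$,
  $A_{gmax} = \max A + R_n$, $\phi$ from the two lowest-light points,
  $\theta = 0.8$.
* **Degenerate curves.** Fewer than 4 points: returned unfitted,
  flagged `insufficient_points`. No near-dark (PPFD < 100) or
  near-saturating (PPFD ≥ 1000) point: fitted but flagged
  `poor_identifiability`. Non-convergence: flagged, last iterate kept.

Derived quantities: $A_{sat} = A_{gmax} - R_n$ (the net asymptote —
adopted over net $A$ at a finite light level, which the protocol leaves
ambiguous), the light compensation point as the bracketed root of
$A(Q) = 0$, and the saturating light LSP as the root of
$A(Q) = 0.75\,A_{sat}$ — 75 % of *net* saturation, matching how such
thresholds are read off net light-response plots. Both roots are
verified to a residual below $10^{-8}$.

Duplicate PPFD steps within a curve are averaged on read (deterministic
and order-independent), and curves are always sorted by increasing
light.

## The coupled leaf simulator

Every stage is validated by parameter recovery against a forward model:
Farquhar–von Caemmerer–Berry demand
$$A = \min\!\left(\frac{V_{cmax}(C_c - \Gamma^*)}{C_c + K_m},\;
\frac{J(C_c - \Gamma^*)}{4C_c + 8\Gamma^*}\right) - R_d$$
coupled to the diffusion supply chain
$A = g_{sc}(C_a - C_i) = g_m(C_i - C_c)$. The steady state is found by
bracketed root-finding on $C_c \in (\Gamma^*, C_a]$ (tolerance
$10^{-12}$); an independent damped fixed-point iteration on
$C_c \leftarrow C_a - A(C_c)/g_{tot}$, with damping set from the local
demand slope, serves as a cross-check solver. When no assimilatory
solution exists the dark state $A = -R_d$ is returned with consistent
fluxes and a `no_solution` flag. Records inherit
$\Phi_{PSII} = J/(\mathrm{PPFD}\cdot\alpha\beta)$, so the fluorescence
equation inverts exactly on noise-free data; the variable-J $g_m$
round-trip is exact (to solver tolerance) precisely when the leaf is
RuBP-regeneration-limited, which is the regime the recovery tests
construct. Under Rubisco limitation the one-point $V_{cmax}$ estimator
is biased low — a known limitation of the method that the simulator
makes quantifiable.

Light dependence of $J$ uses a nonrectangular hyperbola in $J$ with its
own $\phi_J = 0.36$ (incident-photon basis, i.e.
$\alpha\beta \times$ a maximum PSII yield near 0.83), $J_{max} = 190$
and $\theta_J = 0.9$. The point-measurement protocol only ever uses $J$
at one light level, so this law is a simulator construct; the defaults
give a realistic $J_{max}/V_{cmax}$ ratio (~1.8) and an AQ curve that is
effectively saturated by 2000 µmol m$^{-2}$ s$^{-1}$, so the fitted
$A_{sat}$ agrees with the simulated plateau to within a couple of
percent.

Measurement noise is additive Gaussian on $A$, $g_{sw}$ and
$\Phi_{PSII}$ only; $C_i$ noise arises implicitly because the record's
$C_i$ is back-computed from the noisy $A$ and $g_{sw}$. No instrument
noise magnitudes are published for this protocol, so the defaults
(SD 0.5, 0.03, 0.005 respectively) are stated assumptions chosen to be
of the order of LI-COR-class repeatability; they exercise the QC paths
without overwhelming the signal.

## The synthetic population

`population_spec()` describes an F2-like population of 568 lines.
Marginals follow the documented shapes — approximately normal
$V_{cmax} \sim N(107.8, 26)$, right-skewed lognormal $g_{sw}$ (mean
0.69, sdlog 0.5) and $g_m$ (mean 0.21, sdlog 0.45) — linked by a
Gaussian copula whose default latent correlations (0.3–0.6 among
$V_{cmax}$, $J$, conductances and SPAD) produce the expected positive
$A$–conductance couplings. $R_d$ is fixed at 1 across lines. The one
free centre is the electron-transport mean at measurement light,
$J \sim N(160, 22)$: it was calibrated once so that the coupled model's
realized mean $A$ lands near the 21 µmol m$^{-2}$ s$^{-1}$ anchor at the
default cuvette conditions (C$_a$ 400, PPFD 1500, RH 65 %, 28 °C), and
then frozen. With these defaults the simulated population also shows the
documented qualitative structure: decisively non-normal, right-skewed
conductances, approximately normal $A$ and $V_{cmax}$, and an
$A$-on-$g_{sc}$ regression slope close to published population screens.

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real data: temperature and humidity dynamics,
triose-phosphate limitation, diurnal or post-excision decline, leaf-age
and canopy-position effects, instrument drift, or genetic linkage
structure (lines are exchangeable draws, not a mapped cross).

## Pipeline and reproducibility

`run_pipeline()` chains simulate (or read) → derive → fit → summarise,
writing canonical CSVs plus a JSON manifest (configuration, seed,
per-stage counts, file digests). Every stochastic function takes an
explicit seed and restores global RNG state (`withr`); identical
configuration and seed give byte-identical outputs. The group contrast
stage simulates two equal-truth sets of light curves ("excised" vs
"in situ") and compares fitted $A_{sat}$ by Welch's unequal-variance
test — chosen because the protocol's own group comparison is unnamed and
Welch is the robust default; at the default noise level its type-I rate
sits at the nominal 5 %.

Problem sizes used by the test-suite and the acceptance script — 568
lines for population structure, 200 leaves for $g_m$ recovery, 100
curves for fit recovery, 100 seeded replicates for the type-I rate —
were chosen as the smallest sizes at which the distributional assertions
are stable across seeds.

## Worked example

```{r example, eval = FALSE}
pop <- generate_population(population_spec(), seed = 1)
derived <- derive_traits(pop$records)
summarize_traits(derived)

curve <- simulate_light_curve(sim_leaf_params())
fit <- nrh_fit(curve[, c("ppfd", "A")])
glance(fit)
autoplot(fit)
```

## Known limitations

* The variable-J inversion is only exact under RuBP-regeneration
  limitation with consistent $\Gamma^*$ and $R_d$; the dC$_c$/dA window
  flags, but cannot fully exclude, Rubisco-limited records.
* One-point $V_{cmax}$ inherits both the limitation-state assumption and
  the fixed 1.5 % respiration fraction; its `"printed"` form carries an
  additional few-percent algebraic bias relative to the exact inversion.
* Orthogonal fitting assumes comparable (range-scaled) error in light
  and assimilation; when noise is purely vertical the orthogonal and
  ordinary fits differ slightly, with small residual bias in $R_n$.
* Constants are not temperature-corrected; records far from the 28 °C
  setpoint should be derived with user-supplied constants.
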