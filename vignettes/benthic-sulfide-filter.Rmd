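---
title: "Methods: quantifying the benthic sulfide filter"
author: "benthifilter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the benthic sulfide filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthifilter)
```

# The problem

In seasonally euxinic basins, sulfate reduction loads sediment porewater
with dissolved sulfide. Steep, millimetre-scale concentration gradients at
the sediment–water interface decide how much of it escapes to the bottom
water: under hypoxic bottom waters, mats of sulfide-oxidizing bacteria
consume the entire upward flux within the top millimetres (a *benthic
filter*), while under permanently anoxic waters sulfide effuses freely.
`benthifilter` implements the measurement-to-budget chain for such
studies: voltammetric microprofile processing, diffusive and chamber-based
flux estimation, and regional upscaling, validated end to end against a
synthetic generator with known ground truth.

A single depth convention is fixed package-wide and stamped into every
output file: depths in mm, **positive downward**, 0 at the sediment–water
interface; overlying-water points carry negative depths.

# Voltammetric signal processing

A gold-amalgam microelectrode is scanned cyclically from −0.1 V to −1.8 V
and back at 1000 mV s⁻¹. Analytes appear as peaks on the forward sweep:
HS⁻/H₂S near −0.7 V (drifting toward −0.9 V at high concentration),
FeS(aq) near −1.1 V, Fe²⁺ and Mn²⁺ at more negative potentials. On the
backward sweep all dissolved sulfide species (HS⁻, H₂S, Sₓ²⁻, labile metal
sulfides) merge into one sigmoidal wave proportional to total dissolved
sulfide (ΣH₂S) over 2–1200 µM. The forward sulfide peak is more sensitive
(0.2 µM detection limit) but saturates near 250 µM.

Processing choices, where the field protocol leaves them open:

* **Baseline.** A straight line drawn between the window edges (anchored
  on the mean of the three outermost points per edge). This matches how
  sharp peaks on sloping backgrounds are treated by eye and has a trivial
  oracle: a constructed Gaussian on a known baseline must return its
  amplitude.
* **Wave height.** Plateau minus baseline — the median current at the
  shallow-potential end of the return sweep minus the median at the deep
  end — rather than a half-wave fit. It is robust to noise and exact for
  the sigmoid model.
* **Peak tie-breaks.** Two maxima in the sulfide window count as a double
  peak (a polysulfide candidate) only if separated by ≥ 0.05 V; closer
  shoulders merge into one peak. Secondary maxima below 10% of the tallest
  peak in a window are treated as flanks of that peak — the tail of a
  large peak otherwise registers as a spurious companion.
* **Replicates.** Four scans per depth; the first is discarded
  (conditioning artifacts) and the remaining three averaged. A replicate
  relative SD above 5% raises a QC flag but does not reject the value —
  it is an observed quality property, not a validity bound.
* **Saturation switch.** Sulfide uses the forward peak below 250 µM and
  the backward wave above, with a 5% guard band: a saturated peak reads
  at, or after baseline correction slightly below, the ceiling, so a hard
  threshold at exactly 250 µM would misroute genuinely saturated scans.
* **Censoring.** Means below the detection limit (20 µM O₂, 10 µM
  Mn²⁺/Fe²⁺, 0.2 µM H₂S forward, 2 µM ΣH₂S wave) are reported *at* the
  limit with a `below_dl` flag, never as smaller numbers.

**Polysulfide speciation.** At fast scan rates a polysulfide molecule
Sₓ²⁻ produces two forward peaks: the more negative one measures its
(x − 1) zerovalent sulfur atoms, the more positive one free sulfide plus
the terminal S(−II). With both peaks quantified on the shared free-sulfide
slope *s*:

* zerovalent = peak₋ / s, polysulfide = zerovalent / (x − 1),
* free sulfide = peak₊ / s − polysulfide (floored at 0),
* fraction of total = polysulfide / ΣH₂S(wave).

The chain length defaults to x = 5, the dominant species at porewater pH
7–8. A fraction above 1 is reported as an error, not clipped: it means the
peak assignment or calibration is inconsistent.

# Diffusive fluxes

Fick's first law with tortuosity correction:

$$J = \varphi(0)\, D_s\, \frac{dC}{dz}, \qquad
  D_s = \frac{D}{1 - 2\ln \varphi(0)}$$

With depth positive downward, a concentration increasing with depth gives
a positive J, i.e. a flux **out of the sediment** — the reporting
convention in all outputs (equivalently, on a depth-negative-down axis the
same flux is −φDₛ·slope). O₂ profiles, which decrease downward, give
negative fluxes (uptake).

* **Gradient.** OLS over a closed depth window (endpoints included;
  default 0–5 mm, deeper windows configurable per station and analyte).
  Censored points are *excluded*, with a warning, rather than substituted
  at DL/2: substitution visibly biases a 3-point window. At least three
  uncensored points are required. Windows may include overlying-water
  (negative) depths, as used for O₂ across the diffusive boundary layer.
* **Uncertainty.** Reported as exactly ±2·SE of the slope, propagated
  linearly — not a t-quantile — matching the convention of the underlying
  field protocol.
* **Porosity.** φ(0) is a required physical input with no substitute in
  the data; when not supplied, the constructor assumes **0.9**
  (organic-rich mud) and says so with a logged message. Because surface
  porosities of real stations are rarely published, absolute flux values
  carry this assumption; flux *ratios* between stations with similar
  sediments do not.
* **Diffusion coefficients.** Computed from seawater correlations
  (Boudreau's compilation): Millero's (1974) dynamic viscosity µ(S, t, P);
  O₂ and CO₂ from dedicated linear fits in T/µ; other gases (H₂S, CH₄,
  NH₃) from the Hayduk–Laudie relation with LeBas molar volumes; ions
  (Fe²⁺, Mn²⁺, HS⁻, …) from linear infinite-dilution temperature fits
  rescaled by the Stokes–Einstein viscosity ratio µ(0, t, 1 atm)/µ(S, t, P).
  Published formulations of these coefficients differ by a few percent
  among software implementations and data compilations; values returned
  here should be read with a ~2–3% formulation uncertainty, which
  propagates linearly into fluxes.

# Chamber fluxes

A benthic lander chamber (651.4 cm² standard area) encloses a known
sediment-free water height *h* (measured volume / area; it must be
supplied per deployment, synthetic defaults 0.1–0.2 m). Six syringe
samples over a 30–36 h incubation give a concentration series; the flux is
the OLS slope (mmol m⁻³ day⁻¹) times *h*. A result is *bdl* (below
detection) when every sample is censored, or when — with at least four
quantified samples — the slope fails a two-sided t-test at α = 0.05. The
underlying protocols report bdl without a stated rule; the t-test is this
package's explicit choice, and syringe-replacement dilution is ignored
(the replacement protocol is unreported; over six small samples the bias
is well under the slope uncertainty).

# Regional budget

Annual sulfur loads per depth stratum:

$$\mathrm{load\ [kton\ S\ yr^{-1}]} =
  J\ \mathrm{[mmol\ m^{-2}\ day^{-1}]} \times 10^{-3}
  \times \mathrm{area\ [km^2]} \times 10^{6} \times 365 \times
  \frac{32}{10^{9}}$$

The hypoxic-transition-zone (HTZ) stratum retains its load in the mats;
the anoxic stratum releases its load to the water column; the retained
fraction is the HTZ share of the total. Constants are configurable but
default to the conventional rounded 32 g mol⁻¹ and 365 day yr⁻¹ (the
exact molar mass 32.065 shifts kton-scale loads by ~0.2%, i.e. a few kton).
The default HTZ flux is the mean of the *mat-station* fluxes only; a
station with weak, patchy sulfide enrichment and no consistent mat
gradient is not an HTZ filter observation and is excluded from that mean.
Computed loads are compared against printed (rounded) figures by rounding
half away from zero (`round_half_up()`), since spreadsheet-style reporting
rounds that way, while base R rounds half to even.

# The synthetic generator

The generator is first-class, tested code: it defines the conditions under
which the estimators are validated.

**Model.** Steady-state 1-D diffusion–reaction per analyte,

$$D_s C'' - k(z)\,C + R(z) = 0,$$

with piecewise-constant coefficients: a constant volumetric sulfide source
R over the production zone; a first-order mat sink over the mat layer; an
Fe(II) source spread over 5 mm below its nominal depth; FeS precipitation
as a first-order sink on sulfide below the Fe source and on Fe(II)
wherever sulfide persists (> 1 µM). Boundary conditions are Dirichlet at
the top (bottom-water concentration) and zero-gradient at the bottom.

**Numerics.** Second-order central finite differences on a uniform grid
(step ≥ 0.25 mm, the instrument's minimum), solved by the Thomas
tridiagonal algorithm. The scheme is exact for the piecewise-linear and
quadratic segments of the true solution, so discretization error is
confined to the thin reaction layers. Negative concentrations in the
noiseless field abort with an error (none can occur for valid scenarios by
the maximum principle). The mat rate default k = 10⁵ day⁻¹ gives a
consumption length scale √(Dₛ/k) ≈ 0.03 mm, far below any mat thickness,
so consumption is effectively total and the concentration at the mat top
falls below 0.1 µM, while the discrete flux budget over the mat closes to
machine precision.

**Ground truth.** With a zero-gradient bottom, all production must exit
through the top of the source-free diffusive zone (the mat base when a mat
exists, else the interface), so the true flux is the analytic
φ·R·(zone thickness) — independent of the solver. When a deep FeS sink
intercepts part of the production the analytic shortcut no longer holds
and the truth is evaluated from the noiseless field's surface gradient.

**Sampling.** Additive Gaussian noise (default 2 µM), truncated at zero at
sampling time (concentrations are non-negative). Synthetic voltammograms
add Gaussian peaks (σ = 0.025 V) at the characteristic potentials, the
concentration-dependent sulfide peak drift, amplitude clipping at the
250 µM equivalent, the proportional backward wave, and a +15% amplitude
bias on the first replicate — giving the first-scan discard something real
to discard. Chamber series rise at flux/height with truncated noise.

**Recovery scenarios.** Random validation scenarios draw the target flux
log-uniformly over 0.1–10 mmol m⁻² day⁻¹ and then derive the
gradient-zone thickness from a measurable concentration span drawn from
150–400 µM (clamped to 3–80 mm). This mirrors practice: fit windows track
the linear region of the profile, which is ~5 mm for steep mat gradients
and tens of mm for the weak gradients below deep subsurface maxima. Fixing
a 5 mm window for all fluxes would make the smallest fluxes statistically
unresolvable at 2 µM noise (a 0.1 mmol m⁻² day⁻¹ gradient spans ~5 µM over
5 mm) — a property of the measurement, not of the estimator under test.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about field data: transient (time-dependent) diagenesis
and the diel variability of bottom-water O₂; bioturbation and
bioirrigation; multi-species reaction kinetics, carbonate/pH chemistry and
thermodynamic polysulfide speciation across chain lengths; electrode
physics (fouling, drift beyond the first-scan bias); lateral seafloor
heterogeneity (the reason chamber and microprofile fluxes can differ
severalfold in the field); and non-steady-state diffusive boundary-layer
effects on O₂ profiles in open cores.

# Problem sizes and runtime choices

The validation suite uses grids of at most ~600 nodes (150 mm at 0.25 mm),
100 recovery scenarios in the end-to-end check (20 in the unit-level
property test), 1000 random datasets for the OLS-against-closed-form
oracle, and 4-replicate scan sets at ~850 potential points per sweep.
These sizes keep each solve in the millisecond range while exercising
every code path; all generator defaults above are scientific choices fixed
before validation, not tuning knobs.

# Known limitations

* Absolute diffusive fluxes inherit the porosity assumption and the
  ~2–3% diffusion-coefficient formulation uncertainty.
* The steady-state assumption fails for rapidly changing bottom waters;
  sulfide fluxes are more robust to this than O₂ fluxes.
* Polysulfide quantification assumes a single chain length (x = 5) and a
  shared calibration slope with free sulfide; both are conventions, not
  measurements.
* FeS(aq) is reported as signal intensity only — no aqueous standards
  exist for calibration.
* The budget treats each stratum as homogeneous (single flux × area); no
  hypsometric weighting or error propagation on areas is attempted, and
  flux uncertainty is carried only linearly as ±2·SE.
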