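---
title: "Methods: diffusion analysis in carbonated water-ethanol mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion analysis in carbonated water-ethanol mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fizzdiff)
```

# The system and the model

A sparkling beverage is, to first order, a three-component liquid: water,
dissolved CO~2~, and ethanol at an alcoholic degree between 0 and ~15 % by
volume. Two transport coefficients dominate its behaviour in the glass: the
bulk diffusion coefficient of CO~2~ (bubble nucleation and growth) and that
of ethanol (evaporation and aroma release). `fizzdiff` implements the
analysis chain that turns particle trajectories and viscometry data into
these coefficients and their comparison.

The package rests on a small set of physical assumptions:

* **Fickian, isotropic diffusion.** Water dominates the mixture (95 % of
  the molecules), the liquid is homogeneous and unreactive on the
  nanosecond scale, so the solutes obey a simple Fick law: the probability
  density of displacements is Gaussian and
  $\mathrm{MSD}(t) = \langle |\mathbf r(t)-\mathbf r(0)|^2\rangle = 6Dt$
  at long times. Multicomponent (Maxwell–Stefan/Onsager) couplings are
  deliberately out of scope; they matter only at solute concentrations
  well above this regime.
* **Periodic cubic box.** Trajectories come from (or emulate) a cubic box
  with periodic boundaries, so measured diffusivities carry a known
  finite-size bias that must be corrected.
* **Effective hydrodynamic radii.** The Stokes–Einstein relation
  $D = k_BT/(6\pi\eta R)$ is applied to non-spherical molecules through an
  effective radius $R$ — either NMR-derived, or a structural proxy.

# Mixture composition

`ethanol_count()` solves the volume bookkeeping: with $r$ the ratio of total
mixture volume to ethanol volume ($r = 100/\mathrm{pct_{vol}}$),

$$N \;=\; \frac{N_{H_2O}\,\rho_{EtOH}\,M_{H_2O}}{\rho_{H_2O}\,(r-1)\,M_{EtOH}}.$$

Defaults are the 285 K reference densities ($\rho_{H_2O}=999.49$,
$\rho_{EtOH}=796.06$ kg m^-3^) and standard molar masses (18.015,
46.068 g mol^-1^; the molar masses are overridable because sources differ in
the last digit). Three numerical decisions live here:

* **Rounding** is half-away-from-zero. The 12 %vol box sits at
  $N = 1698.7$ and the 15 %vol one at $2198.5$; truncation would
  miss both reference values (1699, 2199), so `floor(N + 0.5)` is used and
  tested against all six reference compositions.
* **Box sizing** (`box_side_estimate()`) supports two volume models:
  `water_density_only` divides the water + CO~2~ mass by the water density;
  `ideal_volume_mixing` adds the ethanol partial volume at its own density.
  CO~2~ mass is included in both — its ~1.2 % contribution is within the
  precision of the target range either way, and including it is the
  physically consistent choice. The two models bracket the expected
  ~10.6 nm (0 %vol) to ~11.2 nm (15 %vol) span.
* **Densities at other temperatures are user input.** The package ships
  reference densities only at 285 K and refuses to guess elsewhere.

`build_box_structure()` produces geometric fixtures only: random sequential
insertion with a cell-grid minimum-image separation check, random rigid
orientations, no energetics. Its purpose is exercising the GRO I/O and
giving downstream tools realistically shaped input, not preparing
simulatable systems.

# Synthetic trajectories: what they emulate and what they do not

`brownian_trajectory()` generates the data the estimators are validated on:
each tracer is a molecular centre of mass performing an ideal random walk
with per-step displacement variance $2D_{\mathrm{true}}\Delta t$ per
Cartesian component (units: 1 nm² ps^-1^ = 10^-6^ m² s^-1^). Defaults
mirror a production run — 10^4^ frames stored every 1 ps (10 ns), 200
CO~2~-like tracers, up to 2199 ethanol-like ones, boxes of ~10.6–11.2 nm,
diffusivities of order 10^-9^ m² s^-1^.

This emulates exactly the regime the MSD estimator assumes, which is the
point: the generator provides a known ground truth, so estimator bias and
variance can be measured. It does **not** emulate several features of real
MD output: the ballistic/caging regime at sub-picosecond lags, hydrodynamic
self-interaction across periodic images (the physical origin of the
finite-size bias — synthetic walkers have none, so the correction is tested
against its closed form, not against box-size scans), crowding, rotational
dynamics, or correlated solvent motion. Passing the recovery tests
therefore demonstrates the correctness of the estimation pipeline, not the
accuracy of any force field.

The random source is R's default Mersenne–Twister; the seed is recorded in
the trajectory's metadata (and in the TSV sidecar written by
`write_trajectory_tsv()`), and identical seeds reproduce bit-identical
trajectories.

# MSD estimation and the finite-size correction

`msd()` averages $|\mathbf r(t_0+\tau)-\mathbf r(t_0)|^2$ over all
particles and every admissible origin (`origin_stride = 1` uses each stored
frame, i.e. 10^4^ origins for a default run). Two implementations coexist:
a direct vectorised sum (supports origin strides) and an FFT path using the
autocorrelation identity, $O(N\log N)$ per particle. Both are tested to
agree with an explicit $O(N^2)$ double-loop oracle; `method = "auto"`
picks FFT when the work justifies it.

Wrapped trajectories must be unwrapped first (`unwrap_trajectory()`):
minimum-image frame-to-frame displacements are accumulated, which is exact
while true displacements stay below $L/2$ per frame — at 1 ps storage and
$D\sim 10^{-9}$ m² s^-1^ the margin is enormous (rms step ~0.06 nm vs
$L/2 > 5$ nm). A displacement component at the $L/2$ limit is ambiguous and
triggers a warning or error (`on_ambiguity`).

`fit_diffusion()` fits an unweighted least-squares line and reports
slope/6. Defaults: `max_lag` is half the trajectory duration, and the fit
window spans 10–50 % of `max_lag`. "Long times" fixes no unique window;
this one excludes the short-lag regime while avoiding the noisiest long
lags (few origins), and it is an explicit knob reported in every output.
Unweighted (rather than variance-weighted) least squares is the simplest
defensible choice and is documented as such. At the default production
scale the pipeline recovers the generator ground truth to within 5 %
(tested across seeds); per-block standard errors (`block_uncertainty()`,
default 5 contiguous blocks) quantify the remaining noise. Note that with
the default window — which scales with the block length — the per-block
relative error is nearly independent of block length; the uncertainty
shrinks with more data only at a fixed lag window, and the tests check
exactly that.

Periodic-boundary estimates are then corrected (`finite_size_correction()`):

$$D_0 = D_{PBC} + \frac{\xi k_B T}{6\pi\eta L} \;\approx\;
  D_{PBC}\left(1 - \frac{\xi R}{L}\right)^{-1},\qquad \xi = 2.837297,$$

where the second form follows by substituting the Stokes–Einstein
viscosity and is the default (it needs no viscosity, only a radius). The
package uses $R = R_{rms}$ of the species by default. The approximate form
diverges at $\xi R = L$ and is refused there; the two forms agree exactly
when $\eta$ is itself Stokes–Einstein-consistent, which the tests verify
algebraically.

# Radii: structural proxies vs NMR references

Two structural radii are computed on static geometries:
$R_{rms}$ (unweighted rms atomic distance to the mass-weighted centre of
mass) and $R_{gyr}$ (mass-weighted). For rigid linear CO~2~ they bracket
0.94–0.99 Å depending on the bond length (1.149 Å model vs 1.162 Å
experimental structure); for ethanol the shipped all-atom anti conformer
gives $R_{rms}\approx 1.60$ Å and $R_{gyr}\approx 1.19$ Å. Mass-weighting
explains the orderings: CO~2~'s heavy peripheral oxygens push
$R_{gyr} > R_{rms}$, ethanol's peripheral hydrogens pull
$R_{gyr} < R_{rms}$ — which is why $R_{gyr}$ badly underestimates an
effective hydrodynamic size for ethanol (50 %+ below the NMR radii, vs
~15 % for $R_{rms}$; `radius_discrepancy()` quantifies this, with the
structural radius as denominator).

The NMR-based reference radii (CO~2~: 0.95/1.03/1.03 Å, EtOH:
1.81/1.85/1.80 Å at 277/285/293 K) are tabulated in
`hydrodynamic_radii("nmr")`. Radii at unlisted temperatures are a lookup
error by design — there is no reliable interpolation basis, and failing
loudly beats silently guessing. The ethanol conformer is built from
standard bond parameters, not fitted to anything; its radii are validated
loosely (±0.05 Å) and conformer flexibility is a known limitation.

# Experimental diffusivities and the viscosity table

`experimental_diffusion_table()` applies Stokes–Einstein row-by-row to a
viscosity table, holding the radius fixed across the alcoholic degree at
each temperature (the radius data exist only near one composition; the
approximation is stated, not hidden). Viscosities are accepted in mPa·s or
Pa·s with explicit unit handling. The bundled
`inst/extdata/viscosity_synthetic.tsv` is a clearly-labelled synthetic
stand-in — anchored at pure-water viscosities, monotone in %vol and
temperature — because the measured values it replaces exist only as plotted
figures. Any real viscometry table with the same columns drops in via
`read_viscosity_table()`.

# Hydrogen bonds

`count_hbonds()` implements the geometric criterion: a bond exists when the
donor–acceptor oxygen distance is below 0.35 nm **and** the H–O~d~–O~a~
angle (vertex at the donor oxygen, between the O→H and O→O~a~ vectors) does
not exceed 35°. Boundary semantics follow that wording: strict `<` on the
distance, inclusive `≤` on the angle — the choice is flagged here because
equality cases are measure-zero in practice but matter for reproducibility.
Distances use the minimum-image convention, so pairs straddling a box face
count identically to their unwrapped images. CO~2~ has no O–H bond and
participates only through acceptor sites. A cell-list search handles large
frames (used when the box exceeds three cutoffs), with the all-pairs path
kept as a tested fallback and oracle. `hbond_fixture()` constructs frames
with an exact known bond count plus single-criterion near-misses, which is
how the counting logic is validated; `hbond_ratio()` compares per-species
time-averaged counts (ethanol forms roughly fifty times more hydrogen
bonds than CO~2~ in these mixtures, a ratio exercised here on constructed
fixtures only — reproducing it from real trajectories requires the
cluster-scale simulations themselves).

# Bubble growth

`growth_rate()` evaluates the diffusion-limited growth rate of small
bubbles rising in-line,

$$k = \frac{dr}{dt} \approx 0.63\,\frac{RT}{P}\,D^{2/3}
  \left(\frac{2\rho g}{9\eta}\right)^{1/3}(c_L - c_0),$$

with `radius_vs_time()` integrating the constant-rate regime
($r(t) = r_0 + kt$, truncated with a flag if a shrinking bubble reaches
zero). The exact scalings ($D\times 8 \Rightarrow k\times 4$;
$\eta\times 8 \Rightarrow k/2$) are tested as identities. $c_0$ can come
from a Henry's-law helper (`henry_interface_concentration()`); the Henry
constant is user input. Validity is the small-bubble in-line regime the
formula was derived for; no ascent hydrodynamics are modelled.

# The pipeline

`run_pipeline()` chains the stages over a species × temperature × %vol
grid: composition → box side → synthetic trajectory at a configured ground
truth → MSD fit → finite-size correction → Stokes–Einstein experimental
value, producing one report row per grid point (ordered species, then
temperature, then %vol; the corrected theory column is never below the
uncorrected one). Design choices:

* All randomness derives from one top-level seed; grid run $i$ uses
  `seed + i`. Identical config + seed give byte-identical persisted
  reports, which is tested.
* The default ground truth closes the loop on the Stokes–Einstein
  experimental value (`d_true = "stokes_einstein"`), making
  theory-vs-experiment agreement a self-consistency check of the whole
  chain; fixed per-species values are available for calibration studies.
* Configuration is a plain YAML file (`read_run_config()`); outputs carry
  the seed, the knobs in effect and a config hash. The package exposes the
  stages as ordinary R functions rather than a shell subcommand tool —
  partial reruns are function calls, and the only shipped executable is
  the acceptance script.

# Problem sizes and test design

The validation suite runs the estimators at two scales: exhaustive-oracle
scale (≤ 50 frames, ≤ 5 particles for the MSD double loop; 100 × 100 sites
for the hydrogen-bond all-pairs check), where optimised and brute-force
paths must agree to near machine precision, and production scale
(200 particles × 10^4^ frames, three seeds) for statistical recovery of the
ground truth within 5 %. Pipeline-level tests use reduced grids
(4–6 particles, 120–200 frames) because they check plumbing — cardinality,
ordering, determinism — not statistics. These sizes are the package's own
validation design: large enough to pin each property, small enough to run
routinely.

# Known limitations

* Synthetic trajectories validate estimators, not molecular models; no
  claim about real beverages follows from the tests alone.
* The ethanol structural radii depend on the shipped conformer; flexible
  molecules would need conformer averaging.
* The bundled viscosity table is synthetic; quantitative experimental
  diffusivities require real viscometry input.
* The constant-rate bubble integration ignores the time dependence of
  $c_L$, bubble ascent and coalescence.
* Hydrogen-bond counting treats a fixed donor/acceptor site list; it does
  not parse arbitrary topologies.
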