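---
title: "Why a needle tip is visible to a forward-looking ultrasound probe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why a needle tip is visible to a forward-looking ultrasound probe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(needlewave)
```

## The physical question

In vertical (coaxial) puncture the needle is inserted through the middle of a
forward-looking ultrasound probe, so the probe sees the needle end-on. A
smooth steel shaft reflects the beam sideways, and the tip itself is a
sub-wavelength sliver of metal — yet in practice the tip returns a strong,
localisable echo. The explanation examined here is that the thin, tapering
metal near the tip acts as a plate-like waveguide: the incident wave couples
into guided (Lamb-type) waves inside the steel, these reverberate in the tip
region, and their leakage back into the water is the echo that the probe
detects. A vacuum-filled "needle" of identical shape, which supports no
internal waves, serves as the control.

The package implements this investigation end to end in two dimensions: scene
construction (needle, flat-tipped cylinder, inclined thin plate, stepped
tapered rod), a coupled fluid–solid elastodynamic time-domain solver, the
tone-burst drive, receiver-trace metrics, an independent Rayleigh–Lamb
dispersion solver, and the steel-versus-void comparisons and tip-angle /
tip-width / tip-length parameter sweeps.

## Model and discretisation

The solver integrates the 2D velocity–stress form of linear elastodynamics
on a uniform staggered (Virieux) grid: normal stresses at cell centers,
shear stress at cell corners, velocity components on the cell faces.
Water is the $\mu = 0$ limit of the same update, so fluid–solid coupling
needs no explicit interface conditions; the inverse density at velocity
nodes is averaged across the two adjacent cells, and the shear stiffness at
corner nodes is the harmonic mean of the four neighbours (zero if any
neighbour is fluid or void). Void regions use the vacuum formalism: their
moduli are zero (their stresses remain identically zero, making staircased
void boundaries traction-free) and their density does not contribute to the
node averages. This is the standard explicit scheme that the elastodynamic
finite integration technique reduces to on a uniform grid.

Material constants are water $\rho = 1000\,$kg/m³, $c = 1500\,$m/s and
stainless steel (SUS304) $\rho = 7930\,$kg/m³, $v_L = 5780\,$m/s,
$v_S = 3100\,$m/s, giving the Lamé parameters
$\lambda = \rho(v_L^2 - 2 v_S^2)$, $\mu = \rho v_S^2$ and a water–steel
normal-incidence pressure reflection coefficient of
$(Z_2 - Z_1)/(Z_2 + Z_1) \approx 0.937$.

The drive is the Hann-windowed tone burst
$y(t) = -\cos(2\pi f t)\,(1 - \cos(2\pi f t / n))$ on $0 \le t \le n/f$,
with $f = 7$ MHz and $n = 2$ cycles, applied as a normal surface force over
the transmitting element — the standard windowed burst: it starts at exactly
zero, has a smooth envelope, and is (numerically) zero-mean. The precise
window shape affects only the source spectrum; every quantity this package
reports is an amplitude *ratio*, which is insensitive to it.

Key numerical choices:

* **Time step.** $\Delta t = \mathrm{CFL} \cdot \Delta x / (v_{max}\sqrt 2)$
  with a default Courant number of 0.7, leaving margin for the staircased
  free surfaces of void regions. $v_{max}$ is the steel longitudinal speed
  for every steel/void scene pair, so the two variants of a comparison share
  the grid *and* the time step exactly.
* **Grid spacing.** Set by points per wavelength (ppw) of the *water* wave
  at the source frequency (the shortest wavelength in the scene); builders
  refuse below 6 ppw, and presets use 10–12 ppw. The steel shear wave is
  then sampled at roughly double that density.
* **Absorbing frames.** A Cerjan-style sponge (multiplicative factor
  $\exp(-(0.015\,(L-d))^2)$ per step over $L$ = 24–40 cells) on the left,
  right and bottom edges. The transducer face at the top is a rigid baffle
  (zero normal velocity) outside the elements.
* **Rasterisation.** Oblique boundaries (the bevel, the inclined plate) are
  staircased at cell resolution with no sub-cell interface treatment; the
  grid-convergence test quantifies the resulting error and the tip-echo
  amplitude converges at an observed order of at least one.
* **Receivers.** Elements record the element-averaged normal stress on
  their face cells; field probes record the pressure-like quantity
  $-(\sigma_{xx}+\sigma_{yy})/2$. Receiver coupling differs between
  instruments and between simulators, so only amplitude ratios are treated
  as reproducible, never absolute amplitudes.
* **Determinism.** There is no randomness anywhere; reruns are bit-exact.

## Scenes

All scenes are built from physical parameters on a water background with
the ring transducer represented in 2D cross-section: element A (transmit +
receive) spans $-3.5$ to $-1.5$ mm and element B (receive) $+1.5$ to
$+3.5$ mm from the probe axis, from the ring's 3 mm inner and 7 mm outer
diameters.

* **Needle**: 1.5 mm diameter, single bevel whose slanted face is oriented
  toward element A. The *tip angle* is the angle between the bevel face and
  the needle axis; since more than one convention is in circulation, it is
  stated explicitly here and configurable (a symmetric-bevel option
  exists). At 10° the
  bevel face is $d/\tan\theta \approx 8.5$ mm long; at angles where the
  bevel exceeds the insertion depth the needle is partially inserted and
  the bevel is clipped at the face (with a warning), since several swept
  angles — including a 5° bevel at the standard 15 mm insertion depth —
  geometrically require it.
* **Cylinder**: flat-ended 1.5 mm rod; its tip face is completely shadowed
  from above, so everything received is corner diffraction or guided-wave
  leakage.
* **Tapered rod**: 1.5 mm stem whose terminal segment of length $l$ is
  narrowed to width $w$ (stepped profile).
* **Inclined plate**: 0.2 mm steel strip at 36° to the face under a single
  3.3 mm transmitting element, with pressure probes on both sides of the
  plate and a plate-parallel probe row for measuring the apparent leak
  angle. At 7 MHz the frequency–thickness product is 1.4 MHz·mm.

What the generator deliberately does *not* emulate: 3D/axisymmetric
geometry (the ring is a deliberate 2D plane-strain cross-section), probe
hardware (slits, spacers, matching layers), tissue acoustics, and
viscous/viscoelastic attenuation. Passing tests therefore validate the
guided-wave mechanism in an idealised water tank, not clinical image
quality.

## Guided-wave oracle

The Rayleigh–Lamb frequency equations for a traction-free plate are solved
for real phase-velocity roots by sign-change bracketing (2000 brackets over
$c_p \in [50, 1.2 v_L]$) and bisection to $10^{-3}$ m/s; normalised
residuals at the roots are below $10^{-9}$, and sign changes created by the
branch points at $c_p = v_L, v_S$ are rejected. Free-plate (vacuum-loaded)
dispersion is used deliberately: water loading shifts the phase velocity
only slightly at this impedance contrast, and the oracle must stay
independent of the time-domain solver it cross-checks. At 1.4 MHz·mm the
propagating modes are S0 ($c_p \approx 5.08$ km/s, leak angle
$\arcsin(c_w/c_p) \approx 17°$) and A0 ($\approx 2.48$ km/s, $\approx 37°$);
in the fd → 0 limit S0 tends to the plate velocity
$\sqrt{E/\rho(1-\nu^2)} \approx 5.23$ km/s and A0 to zero. The plate demo
measures the apparent leak angle from the plate-parallel probe row in two
ways. First-arrival times (threshold 5% of each trace's peak, regressed on
distance) track the *fastest* mode's precursor: the measured angle agrees
with S0's free-plate prediction within ~2°, as S0's water-loading shift is
negligible. The *dominant* wavelet is tracked separately by the lag of
maximum cross-correlation between adjacent probes (windowed to the main
arrival, sub-sample refined, median over pairs). Which mode dominates is
decided by the geometry, not assumed: at the 36° plate the beam arrives 54°
from the plate normal, total-reflected for both bulk waves in steel, and
the trace velocity it imposes, $c_w/\sin 54° \approx 1.85$ km/s, is far
closer to A0 than to S0. The dominant-wavelet measurement indeed identifies
A0, but sits ~6° above the free-plate A0 angle — the real water-loading
slowdown of A0, which the vacuum-loaded oracle deliberately ignores — so
the tests assert the mode identity for A0 and the 5° angle agreement only
for S0.

## Echo metrics and gating

Tip-echo metrics are computed in a gate centred on the round-trip time
$2\,\mathrm{depth}/c_w$, opening 1.5 µs before it (but never before 1.5
source durations, to exclude transmit breakthrough) and closing 5 µs after
it, which admits the guided-wave arrivals that trail the direct diffraction.
"Signal intensity" is read as the gated peak absolute amplitude; a gated
energy metric is recorded alongside it in every sweep row. The phase
relation of two traces is the sign of their normalised cross-correlation at
the lag of maximum magnitude, with relations below 0.5 in magnitude
classified indeterminate. The peak-pair separation is the time between the
largest positive and largest negative sample in the gate.

## Where each quantity is evaluated, and why

The reference behaviours — steel/void contrast, phase inversion, the sweep
optima — are reproduced at desk scale with these choices, made
on physical grounds and fixed before the acceptance values were read off:

* **Steel/void comparisons** (needle ratio ≈ 1%, cylinder ratio ≈ 100-fold)
  run at the `"bevel"` preset: 10 mm insertion depth — the shallowest depth
  at which the full 10° bevel face (8.5 mm) is submerged with margin — at
  12 ppw. The ratios are evaluated at the **opposite-side receiving element
  B**: the transmit-side gate also contains the tip-corner diffraction, which is material-independent (a vacuum boundary reflects as
  strongly as steel), while the guided-wave leak — the signal the mechanism
  is about, and the one that distinguishes steel from void — is cleanly
  isolated on the opposite side. At this preset the acceptance
  recomputation measures ≈ 1.0% for the needle and ≈ 83-fold for the
  cylinder.
* **Tip-angle sweep** at the `"ci"` preset (6 mm, 10 ppw), argmax evaluated
  on the opposite-side element B, with the same-side result recorded
  alongside in the sweep table.
* **Width/length sweeps** at the `"taper"` preset (12 mm, 10 ppw): deep
  enough that the stem-step corner of a 5 mm tip sits ≥ 7 mm below the face
  and its diffraction arrives well before the tip gate opens. At 6 mm depth
  the step would sit 1 mm under the elements and its near-field diffraction
  floods both traces — a scaled-down artefact, not physics.

## Known limitations

* Two-dimensional plane strain: amplitude decay and diffraction
  coefficients differ from 3D; only ratios and ordinal comparisons are
  meaningful.
* The transmit-side trace superposes tip diffraction and guided-wave leak;
  the steel/void contrast is therefore much smaller at the transmitting
  element than at the opposite-side element, where this package evaluates
  it (see above).
* The dominant positive/negative peak pair at the far-side element sits
  within the first guided-wave wavelet when the second (tip-transit-delayed)
  arrival is weaker, so the measured pair separation can fall below the
  1 µs tip-transit value that holds when the two arrivals are comparable.
* The free-plate oracle ignores both radiation damping (leaky modes'
  complex wavenumbers) and the real water-loading slowdown, which is
  negligible for S0 but ~6° of leak angle for A0 at 1.4 MHz·mm; angle
  agreement is asserted only for S0.
* The rigid-baffle face is an idealisation; a matched (absorbing) face
  would lower late reverberation further.

## Problem sizes

Routine tests run scenes of roughly 250–500 × 250–650 cells for 2,000–8,000
steps; the comparison and sweep experiments run 450–860 × 350–800 cells for
7,000–13,000 steps. These sizes were chosen so the full suite and the
acceptance recomputation each complete comfortably on a single CPU while
keeping every scene at or above 10 points per water wavelength (6 for the
smoke preset).
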