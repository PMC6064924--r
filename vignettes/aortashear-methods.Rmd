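---
title: "Methods: pulsatile wall shear metrics in an idealized branched channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatile wall shear metrics in an idealized branched channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, numerical
choices and limitations. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The physical model

Blood is modelled as an incompressible Newtonian fluid with density
ρ = 1235 kg m⁻³ and dynamic viscosity η = 0.004 Pa·s (the standard
murine blood-model constants; note that a viscosity is Pa·s, not Pa/s).
With a typical maximum aortic-root flow speed V = 1 m s⁻¹ and hydraulic
diameter D = 1.58 mm, the peak Reynolds number is ρVD/η ≈ 488, firmly
laminar, so no turbulence model is used. Vessel walls are rigid; there is
no fluid–structure interaction.

The flow domain is an idealized 2-D plane channel of height
h = D = 1.58 mm: a deliberate desk-scale stand-in for a 3-D
image-derived aortic geometry, which is outside this package's scope.
Twelve ostia — mouths of intercostal-like side branches — are openings in
the top and bottom walls arranged as six axial pairs. Ostia are treated
as boundary openings with prescribed outflow, not meshed side channels
(`branch_length` is metadata only).

**Boundary conditions.** The inlet is a Dirichlet velocity condition: a
parabolic profile scaled so its instantaneous mean equals a periodic
waveform v(t), itself a least-squares periodic cubic Bezier spline fitted
to sampled data. Each outlet carries a fixed fraction of the
instantaneous inflow: raw fractions 69.8% for the main (descending)
outlet and 0.14% per ostium. The full four-branch split
(69.8/16/8/6 + 12×0.14) sums to 101.48%; because mass conservation is
non-negotiable all fractions are renormalized to sum to one, and in the
single-channel geometry only the main and ostial outlets exist, so those
are renormalized among themselves (main 97.65%, each ostium 0.196%).
Whether the original percentages were flow- or area-based is unknowable
from the printed values; renormalization of the stated proportions is
this package's documented choice. Outflow is enforced strongly as
split-scaled plug velocity with zero-gradient pressure — a deliberate
departure from weak Neumann outflow that guarantees the stated flow
division to machine precision at every step (the acceptance run measures
per-ostium split errors ~1e-16). All outlets are in phase with the inlet.

**Cycle protocol.** The time step is 1/1000 of the cycle time; three
cycles are simulated from rest and the last cycle is evaluated. The
first cycles absorb the startup transient; the tests verify the final
and penultimate cycles agree to well below 1% RMS.

## The inlet waveform

No digitized Doppler table is available, so the package ships a
parametric murine-like default (`default_mouse_waveform()`): a
raised-cosine systolic pulse spanning the first 3/8 of a 0.1 s cycle
(≈600 bpm) above a 2% diastolic plateau, peaking at exactly 1 m s⁻¹.
The cycle duration and spline segment count are configuration, not
constants. The Bezier fit enforces C0 continuity at segment joins and
periodic closure v(0) = v(T) but not C1: a "third-order Bezier spline"
does not by itself imply slope continuity, and the weaker constraint
keeps the least-squares problem linear. Interior knots are uniform in
time — the simplest defensible placement absent other guidance. The fit
residual is reported and is non-increasing under nested (doubling)
refinements of the segment count; for non-nested counts (e.g. 3 vs 4)
the spaces are not contained in one another and monotonicity is not
guaranteed.

## Analytic oracles

Steady limits: plane Poiseuille wall shear 6ηU/h and tube Poiseuille
4ηU/R. Unsteady: classical Womersley solutions per pressure-gradient
harmonic G e^{iΩt}, in the tube (J₀/J₁ of complex argument) and plane
channel (cosh) forms, superposed on the steady component. Because the
solver is driven by an inlet *velocity* waveform, a helper inverts the
analytic flow-rate/gradient transfer function per harmonic so the oracle
and the solver share exactly the same mean-velocity waveform. Complex
Bessel J₀/J₁ are evaluated by their power series, accurate to ~1e-12 for
|z| ≤ 20 (Womersley numbers up to ~14; the physiological default is
α ≈ 3.5); larger arguments signal "parameter out of supported range"
rather than returning degraded values. Base R's `besselJ` is real-only,
which is why the series is implemented here, tested against `besselJ` on
the real axis and against the quasi-steady α → 0 limit.

## The flow solver

A staggered (MAC) grid projection method: QUICK-style upwind advection
(quadratic upwind face interpolation, falling back to central where the
upwind node is unavailable) advanced with second-order Adams–Bashforth;
Crank–Nicolson (implicit, second-order) diffusion, which removes the
viscous time-step restriction that would otherwise bind at dt = T/1000 on
fine transverse grids; and an incremental pressure projection with a
sparse Cholesky Poisson solve, the constant null space pinned by a
rank-one regularization. Tangential no-slip at walls uses reflection
ghosts (`u_ghost = -u_interior`), a second-order wall treatment; wall
shear is extracted as the derivative at the wall of the quadratic through
the three nearest tangential velocities — one-sided, second order, and
exact for the discrete steady parabola.

Numerical tolerances: post-projection discrete divergence is direct-solve
accurate (measured ≲1e-10 of V/h); global mass balance is exact by
construction of the outlet plugs. The stability guard signals an
"unstable step" when a direction's advective CFL exceeds 0.9 *and* the
Crank–Nicolson damping bound dt ≤ 2ν/vel² also fails; the second clause
matters because the strong plug outlet creates a thin adjustment zone
with locally large transverse velocity that implicit diffusion damps
completely.

**Validation and problem sizes.** Steady straight-channel runs at
32/64/128 transverse cells converge to plane Poiseuille wall shear at
observed order ≈2.0 (the leading error, ≈1.5/n², comes from the O(dy²)
wall slip of the reflection ghost interacting with the flux
normalization); the 64-cell error is ≈0.04%, far inside the 2% band the
tests assert. These runs use a 6h-long channel sampled in its central
third: the plug outlet perturbs the flow over a decay length ~h/π, so a
2h channel would contaminate the measurement — a pitfall worth recording.
Pulsatile validation drives a 16h straight channel (64×64 cells, 3 cycles
× 1000 steps) with a two-harmonic waveform at α ≈ 3.5 and compares the
final-cycle wall shear in the central region against the Womersley
channel oracle (RMS error ≈0.8%, asserted <3%); the low mean velocity
(0.04 m/s) keeps the oscillatory entrance length short of the measuring
station. The 12-ostia protocol run uses a 12h × h channel at 48×32 cells
— the coarsest grid that resolves each ostium while keeping the advective
CFL of the 1.5 m/s parabolic peak inside the stable range at dt = T/1000.
These sizes are the package's chosen study conditions; they run in
seconds to a couple of minutes each on a single core.

**Ostium regions.** Wall points within 1.5 ostium-widths of an ostium
mouth take that ostium's quadrant label (`left_upper`, `right_upper`,
`left_lower`, `right_lower`; top wall = "left", bottom = "right",
proximal half = "upper" — an arbitrary but fixed mapping of the 2-D
channel onto the four anatomical quadrants); all other wall points are
`non-ostial`. The 1.5-width rule is a package choice; no quantitative
region definition accompanies the quadrant terminology it mirrors.

## Wall shear metrics

All cycle integrals use periodic trapezoidal quadrature on the uniform,
endpoint-exclusive time grid — identical to the arithmetic mean over
samples, and spectrally accurate for smooth periodic signals. Records
that duplicate the endpoint are rejected at construction.

Two definitional choices deserve a note. First, TAWSS is the time
average of the WSS *magnitude*, (1/T)∫|τ|dt. The compact typeset form
of the TAWSS equation can be misread as the magnitude of the average
vector, but the OSI definition distinguishes τ_mean from TAWSS — if the
two were equal OSI would be identically zero — which forces the standard
magnitude-average reading. Second, the transWSS integrand takes the
absolute value of the projection onto the transverse direction
n × τ_mean/|τ_mean|, following the metric's original definition and the
requirement transWSS ≥ 0.

Degenerate conventions (the underlying formulas are silent): TAWSS below
1e-12 Pa yields OSI = 0; a numerically zero mean vector has no transverse
direction, so transWSS returns 0 with a `degenerate` flag (e.g. a WSS
vector rotating uniformly through a full revolution). OSI is clamped to
[0, 0.5] against rounding. transWSS is defined only for 3-D records; for
the 2-D channel solver output the in-plane cross product has no
tangential component and the metric is reported as `NA` ("metric-
undefined") rather than silently zero.

Properties verified by the suite: 0 ≤ OSI ≤ 0.5, 0 ≤ transWSS ≤ TAWSS,
|τ_mean| ≤ TAWSS on large batches of random records; exact agreement with
an independently coded brute-force loop over the defining formulas;
rotation equivariance to 1e-9; and sub-1e-4 sensitivity to quadrature
refinement between 256 and 2048 samples.

## Synthetic data and the two-group design

`generate_wss_field()` draws, per surface point: a random unit normal
with an orthonormal tangent basis; a lognormal mean shear magnitude about
its quadrant's mean (mean-corrected so the expectation equals the
regional parameter); an axial component m(1 + f_osc sin ωt); a transverse
component m f_trans cos ωt (quarter-period phase shift); and tangential
Gaussian noise. A single global fundamental frequency is the simplest
structure that exercises all three metrics distinctly; oscillatory
fractions above 1 produce genuine flow reversal. Tangency and unit
normals hold exactly by construction, and everything is reproducible from
one seed.

The cohort design has exactly two groups. The treated group's defaults
scale the regional mean shear by 0.8 — chosen to match the
treated/control TAWSS *ratio* of ≈0.78 reported for the real 3-D
geometry, since the absolute Pa values depend on that unavailable
geometry — and the oscillatory and transverse fractions by 0.9 so that
OSI and transWSS are also reduced. A single-harmonic synthetic field
cannot simultaneously match the reported absolute OSI (~0.004) and
transWSS/TAWSS (~0.015) values: OSI of order f²/8 and transWSS of order
0.64 f·TAWSS are coupled through the same transverse fraction f. The
defaults therefore target the *directions and ratios* of the group
contrast, not the absolute OSI/transWSS magnitudes; passing tests show
ratio-and-direction recovery, and say nothing about 3-D absolute
fidelity. Between-subject variability is a 5% lognormal magnitude
factor; per-subject seeds are derived as
(base_seed·100003 + 1000·group + subject) mod 2³¹−1, so different base
seeds give disjoint subject streams (naive `base_seed + subject` offsets
make consecutive-seed replicates share subjects, which silently
correlates Monte-Carlo replicates — discovered and fixed by the null
calibration test).

Subjects, not wall points, are the unit of analysis: each subject
contributes one value per region (its region mean), avoiding
pseudo-replication. Group comparisons use Welch's unequal-variance t per
metric × region with Holm correction across regions; the choice of
Welch + Holm is this package's standardization where the underlying
two-group design states only "Student t test, P < 0.05" and no
multiplicity rule. Calibration is verified by simulation: with identical
groups (n = 10/10) the rejection rate at α = 0.05 over 1000 replicates is
within 0.03–0.07, and with the default treated adjustments (n = 12/12)
all three metrics are detected lower (p < 0.05) in >95% of 200
replicates.

## Interfaces

Configs are YAML with a closed schema (unknown keys are rejected).
Waveforms travel as 2-column CSV with a `period_s` metadata row; fitted
splines as JSON segment lists; wall shear records as long-format CSV
(point, region, position, normal, time, τ components) whose period is
recovered from the uniform grid. `run_pipeline()` writes per-point
metric tables, regional summaries, comparisons and a manifest (config,
seed, package and R versions) sufficient to reproduce a run; reruns are
byte-identical. The orchestration surface is the package functions plus
the `analysis/` scripts — no shell wrapper is shipped, as the natural
entry point for this analysis is R itself.

## Known limitations

- The 2-D channel preserves the model class (laminar, Newtonian, rigid,
  same boundary-condition and time-stepping protocol) but not 3-D
  geometry; absolute wall shear levels of a real aorta are out of reach
  by design, and only analytic-oracle agreement and direction-of-effect
  claims are made.
- Strong plug outflow guarantees the flow split but perturbs the flow
  within ~h/π of each outlet; measurements near outlets reflect the
  enforcement, not free outflow.
- The Bessel series caps the Womersley number at ~14; far above the
  murine default, but not suitable for, e.g., large-artery human
  harmonics at high frequency.
- The synthetic field is single-harmonic by default; real WSS spectra
  contain higher harmonics and spatial correlation that the generator
  does not emulate.
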