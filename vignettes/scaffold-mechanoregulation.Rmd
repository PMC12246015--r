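---
title: "Mechanoregulation-driven design of strand-lattice scaffolds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanoregulation-driven design of strand-lattice scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldmech)
```

## The problem

Hydrogel scaffolds for cartilage tissue engineering are cultured under
dynamic compression: a piston cyclically squeezes the scaffold inside a
medium-filled well, exposing cells seeded on the strand surfaces to two
mechanical cues at once — solid-phase shear strain from the deforming
lattice, and fluid-phase wall shear stress (WSS) from the squeeze flow the
compression drives through the pores. Mechanoregulation theory maps the
combined cue to a predicted tissue phenotype, so the scaffold's pore
architecture becomes a design variable: by changing strand count, strand
diameter and pore size one can steer the surface fraction predicted to
differentiate toward cartilage rather than bone or fibrous tissue.

`scaffoldmech` implements this design loop at desk scale. A full
fluid–structure-interaction (FSI) solution of the problem requires coupled
transient FE/CFD solvers; here that stage is replaced by a calibrated
reduced-order surrogate (Section "Synthetic fields") so that the
geometry–stimulus–phenotype chain, and the design sweep built on it, run
in seconds and are fully reproducible under a seed.

## Scaffold geometry

A design is a 0/90 strand lattice inside a cylindrical envelope
(`D_scaffold` = 10 mm, `H_scaffold` = 4.8 mm by default): `N_V` horizontal
layers, each holding `N_H` parallel strands of diameter `D_strand`, with
orientation alternating by 90° between layers. Designs are named
`S{step}-H{N_H}-V{N_V}`. Two span conventions close the geometry when the
spans are not given explicitly:

* **Horizontal span** `Y = D_scaffold / N_H`. The strand pattern then
  tiles the envelope diameter exactly — `N_H` strand-plus-window periods,
  with half an open window at each rim. This convention makes the scaled
  design families self-similar: `Y`, `D_strand` and `h` all scale by the
  same factor in the porosity-preserving sweep below.
* **Vertical span** `h = H_scaffold / N_V`. The layer stack tiles the
  height, and the outermost strand surfaces are trimmed flush at the
  piston and support contact faces, as printed-and-compressed scaffolds
  are. Since `h < D_strand` for the default designs, adjacent layers
  interpenetrate by `D_strand − h`, emulating strand fusion during direct
  ink writing (DIW).

Porosity is `1 − V_solid / V_envelope`. `V_solid` is the volume of the
*union* of the clipped strand cylinders — overlap at layer junctions is
counted once. The default estimator slices the envelope along z
(`resolution`, default 25 µm, the only discretised direction): within a
slice each strand becomes an axis-aligned band across the envelope circle,
and the union area of the bands is evaluated in closed form (chord
integrals for each band, exact rectangle-in-disc areas for the band
crossings). Halving the slice thickness moves the step-1 porosities by
less than 0.05 percentage points, and a seeded Monte-Carlo estimator is
available as an independent check (`pore_metrics(..., method =
"montecarlo")`); the two agree within Monte-Carlo error.

The *minimal equivalent pore diameter* summarises the tightest opening a
cell or nutrient stream must pass: the smallest window is bounded by two
parallel strands of one layer (gap `Y − D_strand`) and the two orthogonal
strands of the adjacent layers, a projected square of area
`(Y − D_strand)²`, so

`D_pore = 2 (Y − D_strand) / sqrt(pi)` (reported in µm).

The square window deliberately carries no corner-rounding correction; the
projected opening between cylinders is exactly the square, and any
three-dimensional narrowing would be model-dependent.

## Solid mechanics and loading

The hydrogel (oxidised alginate–gelatin, ADA-GEL) is modelled as a
one-term incompressible Ogden solid, `mu_1 = −5.8` kPa, `alpha_1 = −1.3`,
`d_1 = 0` (the sentinel for a dropped volumetric term). The package
evaluates the strain-energy density for arbitrary principal stretches and
the closed-form nominal stress on the incompressible uniaxial path; the
two are cross-checked against each other by numerical differentiation in
the test suite. The solid-phase stimulus input is the octahedral shear
strain

`OSS = 2/3 sqrt((e1−e2)² + (e2−e3)² + (e3−e1)²)`

from the elastic principal strains.

Loading is a single compression–release cycle: a raised-cosine piston
displacement `d(t) = A/2 (1 − cos 2π f t)` with `f` = 1 Hz and peak
compression `A` = 5 % of the scaffold height, i.e. 0.24 mm at `t` = 0.5 s.
"Amplitude" is interpreted as the peak compression, not peak-to-peak, and
the raised cosine is chosen so displacement *and* velocity vanish at the
cycle ends. A single cycle suffices because the material model carries no
history dependence; repeating the cycle would repeat the answer. The
default time step is 0.01 s (101 samples per cycle).

## Synthetic fields (the FSI surrogate)

The conformal-interface contract of a coupled FE/CFD model — solid and
fluid meshes sharing identical surface nodes so strain and WSS can be
combined per node — is retained: `surface_mesh()` samples nodes on the
strand surfaces once, and both fields are generated on that shared node
set with equal area weights summing to the strand surface area.

**Strain channel.** Compressive stimulation of a lattice is dominated by
its strand intersections, where the load path crosses and stress
concentrates. We summarise a design by its *junction load index*

`chi = n_junctions · D_strand³ / V_envelope`,

a dimensionless density of intersection-recruited material: each junction
mobilises a volume that scales with the cube of the strand diameter. The
nodal field is

`OSS_node = c(t) · T · (1 + a · chi · g_node) · eps_node`,

where `c(t)` is the instantaneous compression fraction, `T` the baseline
transfer factor, `g_node` the mean-one junction-proximity modulation
(`exp(−dist/D_strand)`, normalised), and `eps_node` mean-one lognormal
heterogeneity (`sigma` = 0.2) frozen over the cycle. The surface mean is
exactly linear in compression and peaks at mid-cycle.

**WSS channel.** The piston displaces fluid through the open pore
fraction, giving a superficial pore speed `u = |v_piston| / porosity`; the
Poiseuille stress through the minimal window is `tau0 = 8 mu u / D_pore`.
The nodal field is `g · tau0^p`, attenuated linearly toward the scaffold
axis (`depth_attenuation` = 0.5 at the core, area-normalised to mean one)
and carrying its own lognormal heterogeneity. The exponent `p < 1`
acknowledges that the true squeeze flow is not fully developed channel
flow: the raw Poiseuille scaling overstates how strongly WSS grows as
pores tighten, and the calibrated sub-linear exponent (~0.56) matches the
relative spread seen in full FSI reference solutions of these designs.

**Calibration.** The four free coefficients `(T, a, g, p)` are solved in
closed form by `calibrate_surrogate()` from the reference peak surface
averages of the two extreme step-1 designs (peak OSS_avg 0.030/0.046 and
peak WSS_avg 7.09/18.74 mPa for S1-H6-V9/S1-H10-V9, from the full FSI
study of this configuration), then frozen into
`inst/extdata/surrogate-defaults.yaml` — they are configuration, not code
constants, and are never re-tuned per design. Everything else the
pipeline reports (intermediate step-1 designs, the whole step-2 family,
stimulus shares, phenotype maps) is out-of-sample for this calibration.

**What the generator does and does not emulate.** It reproduces: zero
fields at rest; strain concentration at strand intersections; the growth
of both peak averages as porosity falls; the growing dominance of the
fluid-shear term in the stimulus as pores tighten; plausible peak
magnitudes. It does not attempt: the time asymmetry of the real squeeze
flow (the surrogate is time-symmetric, so the release-phase maximum is
selected by a tie-break rather than by physics), spatially realistic WSS
patterns beyond the radial attenuation, or inertia/transient flow
effects. Passing tests therefore certify the scoring and sweep machinery
and the *trends* of the surrogate, not CFD fidelity of any single nodal
field.

## Mechanoregulation scoring

The biphasic stimulus is `S = OSS/a + WSS/b` with `a` = 0.0375 and `b` =
10 mPa, mapped to a predicted phenotype by the threshold partition with
inclusive upper bounds: `S ≤ 0.01` very-low, `(0.01, 1]` bone, `(1, 3]`
cartilage, `(3, 6]` fibrous, `> 6` very-high.

Two readings of "average stimulus" are possible and both appear in
practice; the package uses: the *curve* `S_avg(t)` is Eq.-applied to the
surface averages (arithmetic mean for OSS over all surface nodes,
area-weighted mean for WSS), while *phenotype maps* apply the stimulus
per node. `S_Max1`/`S_Max2` are the maxima of `S_avg` on `[0, T/2)` and
`[T/2, T)`; ties break toward the later time, which pins `S_Max2` into
the release phase even for a time-symmetric surrogate. Phenotype maps are
evaluated at the `S_Max2` time (configurable), and surface percentages
are area-weighted. Nodes on the piston/support contact faces are not
excluded from the averages; with the flush-trimmed stack they carry the
same fields as neighbouring surface nodes.

## The two-step design sweep

* **Step 1** varies `N_H` (6–10) at fixed `N_V`, `D_strand` and `h`,
  scanning porosity (≈33–58 %).
* **Step 2** freezes the ratios `h/D_strand` and `Y/D_strand` of the
  step-1 selection and varies `N_V` (8, 10, 11) under `N_H = N_V` and
  `H_scaffold = N_V · h`, which scales `D_strand` (570–790 µm) and
  `D_pore` (380–520 µm) while porosity stays within half a percentage
  point of the base — isolating the pore-size effect from the porosity
  effect. Variants whose strand diameter leaves the DIW-manufacturable
  band (default 500–800 µm) are excluded with an explicit reason.

`select_best()` maximises the cartilage surface share with an
insignificance band: designs within `stop_threshold` (default 1
percentage point) of the maximum are tied — an improvement that small
does not justify a more complex architecture — and the tie breaks toward
fewer layers. The full-factorial enumeration (`step-2 rule applied to
every step-1 design`, 15 architectures) is provided for scoping; the
two-step path evaluates 8.

## Numerical choices and problem sizes

* Porosity: 25 µm slice resolution (192 slices); the reported standard
  error is the refinement estimate against double thickness.
* Surface meshes: 5 000 nodes by default (10 000 in the acceptance
  script, 3 000 in the trend tests); with `sigma` = 0.2 the standard
  error of a surface mean is ≈ 0.3 % of its value at 5 000 nodes, an
  order of magnitude below the between-design differences the sweep
  ranks.
* Cycle: 101 time steps at 0.01 s.
* All randomness (node sampling, heterogeneity) flows from one integer
  seed per run; sweeps derive per-design seeds as `seed + i − 1`. Equal
  seeds give bit-identical fields, reports and CSV exports.
* Degenerate inputs fail loudly: tangent strands are dropped, empty
  layouts yield porosity 1 with a warning, `Y ≤ D_strand` (no pore
  window), non-tiling layer stacks and mismatched node sets are errors.

## Known limitations

* The span conventions are the package's own closure of the lattice
  family; measured architectures whose spans differ (e.g. from a
  printing path plan) can override `Y` and `h` explicitly, and porosities
  of such variants shift by 1–2 percentage points.
* The surrogate's per-node phenotype *distributions* are narrower than
  full FSI fields produce — surface percentages saturate toward the
  dominant class sooner than a solver would show — so sweep rankings are
  meaningful, absolute percentages less so.
* The WSS field is time-symmetric within the cycle; quantities tied to
  the release-phase asymmetry of real squeeze flow are outside the
  surrogate's reach.
* Mass transport, viscoelasticity, multi-cycle remodelling and
  two-way coupling are out of scope.

## A minimal run

```{r example, eval = FALSE}
spec <- original_scaffold()              # S0-H7-V9
pore_metrics(build_layout(spec))         # porosity, D_pore

cyc <- generate_cycle(spec, n_nodes = 2000, seed = 1)
ser <- averaged_series(cyc$strain, cyc$wss)
sm <- find_smax(ser)
map <- phenotype_map(cyc$strain, cyc$wss, sm$smax2[["time"]])
phenotype_percentages(map, cyc$mesh$area, design = spec$name)

report <- run_sweep(step1_designs(spec), n_nodes = 2000, seed = 1)
summary(report)
select_best(report)
```
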