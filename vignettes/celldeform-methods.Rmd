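---
title: "Cell and nucleus deformation during confined migration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell and nucleus deformation during confined migration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldeform)
```

## The model

`celldeform` is a phenomenological, agent-based model of a single
deformable cell with a deformable nucleus. The membrane and the nuclear
envelope are each discretised into `N` nodes (a ring in 2D, an
`N × M` longitude/latitude lattice in 3D), and node `i` of the membrane is
paired with node `i` of the nucleus by a spring-like *deformation
relaxation*: fixed offset vectors recorded at initialisation (`x̂_i` from
nucleus node to membrane node, `x̂ⁿ_i` from nucleus centre to nucleus
node) define the rest shape, and each node relaxes toward its offset
target at rate `α` (membrane, default 250 h⁻¹) or `αⁿ` (nucleus, default
2500 h⁻¹). The stiffer nucleus therefore deforms later and less than the
membrane, which is the core phenomenology: squeezing through a pore
narrower than the nucleus forces a visible nuclear deformation that
relaxes back once the constriction is passed.

Three further ingredients complete the dynamics:

* **Chemotaxis.** A generic chemoattractant from point sources is
  represented by free-space fundamental solutions of the steady diffusion
  equation: logarithmic in 2D, and in 3D (by default) the `1/r²` form,
  with a `greens_3d = "physical"` option selecting the standard
  `1/(4πDr)` kernel. Only the gradient enters the dynamics, with mobility
  `β` (default 60 h⁻¹); the 2D drift is
  `γ_S (x_S − x_new) / (πD‖x_S − x_old‖²)`. Two conventions are worth
  stating explicitly because the tests pin them: the scalar distance in
  the logarithm is the Euclidean norm, and the drift denominator constant
  is `πD` even though differentiating the 2D kernel would give `2πD` — the
  drift is phenomenological, `β` absorbs constant factors, and a
  regression test asserts the factor-2 relationship so it can never drift
  silently. Units: `β∇c` is treated directly as a velocity in µm/h; no
  additional scaling is applied.
* **Random motility.** Every node receives an independent Wiener
  increment with variance `Δt` scaled by `η`. `η` is a free amplitude of
  the model (see *Parameter choices*).
* **Polarity.** Each step, a rigid rotation of the initial shape
  (translated to the current membrane node centroid) is fitted to the
  current membrane by least squares — a closed-form `atan2` solution in
  2D, an orthogonal-Procrustes/SVD solution with Euler-angle extraction in
  the model's `B_x B_y B_z` factor order in 3D — and applied to both
  offset families. The cell therefore remembers not just its shape but
  its orientation.

Obstacles are perfectly rigid and immobile. A node in contact (within
`tol = 10⁻²` µm of a boundary, moving inward) loses the normal component
of its displacement; any residual interior point after the step is
clamped to the nearest boundary point, which prevents slow tunnelling at
finite `Δt`. Noise is added before the projection, so obstacles constrain
random motion too. The same rule applies between cells, using the
neighbouring cell's membrane polygon as the boundary.

## Time integration

The update is IMEX (implicit–explicit) Euler. Linear relaxation terms are
implicit — the per-node solves reduce to divisions by `(1 + Δtα + Δtβγ̃)`
and `(1 + Δtαⁿ)`, so the stiff springs are unconditionally stable — and
the chemotactic term uses the old/new split above (`--explicit-gradient`
selects a fully explicit evaluation; both are first order). The order
within a step is fixed: rotation fit, membrane update, nucleus update
against the *already advanced* membrane, nucleus-centre refresh (the
area centroid of the nucleus polygon in 2D, the volume centroid of the
nucleus mesh in 3D), then source consumption. A source engulfed by the
membrane polygon (even–odd containment; boundary points count as inside)
is deactivated permanently, after which the run continues for a fixed
relaxation tail of 0.05 h — 12.5 relaxation times at the default `α` — so
shape recovery completes. Noise applies to nodes only, not to the nucleus
centre, which is always recomputed geometrically.

An important stability property of the linear-implicit chemotactic term:
as a node approaches the singular source, the implicit solve caps its
update at the source position instead of overshooting, so near-source
"speed peaks" are large but finite. A separate guard aborts with a
"reduce dt" diagnostic if any proposed displacement exceeds the cell
radius in one step.

The compiled (Rcpp) engine and the pure-R reference integrator
(`advance()`) implement the identical update, drawing noise from R's RNG
in the same order; a test asserts agreement to 10⁻¹⁰ over hundreds of
steps, with and without noise. Default steps are `Δt = 10⁻⁴` h in 2D and
`10⁻²` h in 3D. Measured transit times converge at first order in `Δt`
(successive Richardson differences shrink by factors 1.99–2.00), with a
Richardson constant of magnitude a few hundred for the channel preset.

## The channel study and its calibration

The reference experiment is the `channel` preset: a 12.5 µm cell with a
5 µm nucleus transmigrating a 60 µm channel whose walls are
`y = ±(5 + ε sin ωx)` (width ≈ 10 µm), driven by a single source beyond
the exit. The *penetration time* `τ` runs from the first membrane node
crossing the entry plane to the last membrane node crossing the exit
plane (half-open x-interval, membrane nodes only). The default roughness
is `ε = 1` µm, `ω = 0.5` µm⁻¹ — the values at which the kinetic-parameter
Monte Carlo study is run.

Two geometric choices deserve explanation:

* **Channel walls are curve-only obstacles.** The wall boundary is the
  sinusoid itself over the channel's x-extent; nodes beyond that extent
  are unconstrained, and there are no solid end faces. This matters: a
  solid slab with a flat face perpendicular to the drive makes the
  entrance a *stable fixed point* of the projected dynamics — the radial
  spring targets give blocked nodes no tangential pull toward the
  aperture, so the cell parks against the wall forever. With curve-only
  walls, a node carried into the wall region is clamped back onto the
  curve: the wall squeezes the advancing cell into the channel mouth,
  which is the intended phenomenology. Vessel walls, by contrast, are
  finite-thickness bands with solid faces; their apertures are oriented
  along the drive so sliding reaches them.
* **Source placement and strength are the preset's calibration
  constants.** The transit scenario fixes where the cell starts
  (−20 µm), where the source sits (105 µm, i.e. 45 µm beyond the exit so
  it is not engulfed before the cell has fully exited), and the
  preset-specific secretion rate 8.7×10⁶ mol/(h µm³). The steady
  translation speed of the coupled membrane–nucleus system is
  `β|∇c|/2` (the nucleus nodes share the drag but feel no chemotaxis),
  and the entry and exit events bracket ~88 µm of centroid travel, so the
  transit time and the in-channel speed are rigidly linked. The
  calibration was set once against the deterministic reference outputs —
  a transit time near 0.37–0.40 h and in-channel speeds in the
  150–250 µm/h amoeboid range — and then frozen; with it, `τ` is
  insensitive to the node count (within 1% across `N` = 10…100).

## Parameter choices

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `R`, `R_n` | 12.5, 5 (2D); 10, 8 (3D) | µm | cell and nucleus radii |
| `N`, `M` | 30, 30 | – | nodes per ring / lattice |
| `alpha` | 250 | h⁻¹ | membrane shape-memory relaxation |
| `alpha_n` | 2500 | h⁻¹ | nucleus shape-memory relaxation |
| `beta` | 60 | h⁻¹ | signal mobility |
| `D` | 3600 | µm²/h | chemokine diffusivity |
| `gamma_s` | 1.2×10⁶ | mol/(h µm³) | default secretion rate |
| `eta` | 20 | µm/√h | random-walk amplitude |
| `dt` | 10⁻⁴ (2D), 10⁻² (3D) | h | time step |

`eta` deserves a note because no table value pins it. Around a resting
shape each node is an Ornstein–Uhlenbeck process with stationary spread
`η/√(2α)` ≈ 0.9 µm at the default — cells stay visibly smooth — while the
cell-level transit-time jitter it produces (≈ 0.015 h per run) gives the
six-parameter Monte Carlo study a transit-time dispersion in the
0.05–0.07 h range, consistent with reported dispersions for this class of
study and with amoeboid cells' substantial random motility. Larger `η`
would be ragged; much smaller `η` would make the stochastic study nearly
deterministic.

## Monte Carlo uncertainty quantification

`run_mc()` draws `D ~ N(3600, 30²)`, `β ~ N(60, 3²)`, `α ~ N(250, 40²)`,
`αⁿ ~ N(2500, 125²)` (the "four" set), `ε ~ U(0.5, 1.5)`,
`ω ~ U(0, 0.6)` (the "two" set), or all six, runs one seeded channel
simulation per sample with the random walk enabled, and reports the mean
transit time, the sample standard deviation `S_n`, per-parameter Pearson
correlations, histogram/CDF (with a lognormal fit — the transit
distribution is right-skewed), and the Monte Carlo error `S_n/√N_s`.
Per-sample RNG streams derive from the master seed by sample index, so
results are identical whatever the worker count. Normal draws of
positive-only parameters are redrawn on non-positive values. Samples that
have not completed the transit by `t = 3.7` h (ten times the reference
transit) are recorded as non-penetrating and excluded from the
statistics, with the count reported.

Structural expectations for the correlation screen follow from the model:
`β` speeds transit (r < 0), `α` resists entry deformation (r > 0), `αⁿ`
barely matters while the channel is only slightly sub-nuclear, and `D`
and `β` act only through the combination `βγ_S/D` — so with a 0.83%
relative spread on `D` against 5% on `β`, the `D` correlation is
necessarily small. Roughness correlations are dominated by the wall slope
`εω`: transit slows superlinearly once `εω` is large, while gentle
long-wavelength waviness (`ω ≈ 0.25` µm⁻¹) in fact *funnels* the cell and
speeds transit by 1–2%, so mean transit time is not globally monotone in
the roughness parameters in this implementation.

The error budget combines the time-integration and sampling errors,
`E ≤ C·Δt + S_n/√N_s`, with `C` estimated by Richardson differencing of
transit times at `Δt` and `2Δt`.

## What the presets emulate — and what they do not

The presets (`channel`, `cavity`, `obstacle2d`, `obstacle3d`, `vessel`,
`free`) are idealised micro-environments: rigid geometry, a quasi-steady
point-source field, no ECM degradation, no adhesion, no cell death, no
fluid flow. Passing tests on them demonstrates the internal consistency
of the model — shape memory, contact kinematics, transit statistics — not
fidelity to any particular experimental system. The `vessel` preset
stacks two rough walls with aligned entry/exit apertures and a source
beyond the far wall; the cell intravasates, crosses the lumen and
extravasates, with the near-source speed spike characteristic of the
singular kernel. In this model protrusions are cheap (a node's maximum
lead over its spring target is `β|∇c|/α`), so strong nearby sources are
engulfed by a pseudopod-like protrusion before the cell body arrives;
preset sources are placed far enough away that this happens only at the
intended end of a run.

## Numerical choices and degenerate inputs

* Shoelace areas are returned as absolute values so ring orientation
  never flips downstream metrics; mesh volumes are signed (orientation
  is meaningful) and cross-checked against the y/z divergence-theorem
  projections, warning above 1% disagreement (open mesh).
* Zero-area polygons fall back to the vertex mean with a warning;
  all-coincident rotation fits return 0 with a warning; degenerate 3D
  configurations return the identity rotation.
* The 3D lattice uses latitudes pole-to-pole with duplicate pole nodes
  merged, giving a closed triangulation (`N(M−1)+2` nodes) for the
  volume/area metrics; triangle orientation is fixed outward at build
  time.
* The trajectory centroid used for speed traces is the membrane *node
  mean*, so runaway protrusion nodes contribute to speed the way they do
  to mean node velocity; the nucleus centre entering the dynamics is the
  *area/volume centroid*, which is insensitive to thin protrusions.
* Contact membership uses `tol = 10⁻²` µm plus a swept-crossing check;
  exact point membership on a measure-zero boundary almost never
  triggers in floating point.
* Problem sizes in the test-suite statistics (200–500 Monte Carlo
  samples; replicate studies at a coarsened `Δt = 5×10⁻⁴` h for the
  sampling-error scaling check) were chosen so the whole suite completes
  in a few minutes on one CPU while leaving the assertions statistically
  meaningful.

## Known limitations

* The transit time and in-channel speed are tied by the ~88 µm
  entry-to-exit centroid path, so the pair cannot be tuned independently.
* Narrower channels are not intrinsically slower: with tangential
  projection plus clamping, squeezing costs no time by itself — only wall
  *slope* does. The amplitude `ε` therefore influences transit mostly
  through `εω`, and its marginal correlation with `τ` is weak at moderate
  `ω`.
* The six-parameter transit-time dispersion is dominated by a heavy right
  tail (occasional near-stall transits at stiff/rough corners of
  parameter space), so `S_n` estimates at a few hundred samples are
  noisy.
* Obstacles are rigid; there is no mechanical back-reaction, adhesion, or
  ECM remodelling. Membrane-resident signalling species and anisotropic
  (orientation-tensor) mobility are out of scope.
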