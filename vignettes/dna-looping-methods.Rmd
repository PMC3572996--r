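---
title: "Methods: base-pair-step Monte Carlo for protein-mediated DNA looping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-pair-step Monte Carlo for protein-mediated DNA looping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`loopmc` treats double-helical DNA as a chain of rigid base pairs. Each
base-pair step carries six rigid-body coordinates — tilt, roll, twist
(degrees) and shift, slide, rise (Angstroms) — and the step's generator is a
4x4 homogeneous transform built in the mid-step-frame convention of the 3DNA
standard (`params_to_transform()`). That convention makes the parameters
chain-direction independent: reading a chain backwards negates only tilt and
shift, which the package exposes as `strand_flip()` and verifies as an
invariance of both geometry and energy.

Fluctuations follow a diagonal quadratic potential about the ideal B-form
rest state: intrinsic twist 360/10.5 degrees (10.5 bp/turn), intrinsic
translations (0, 0, 3.4 A) frozen, and independent Gaussian tilt, roll and
twist. Sampling a Boltzmann ensemble of such a potential is exactly
independent Gaussian draws per step (`sample_steps()`), so no Metropolis
machinery is needed.

### Elastic constants

The source analyses pin the model to observables, not printed constants: the
bending width must reproduce the ~500 A persistence length of
mixed-sequence DNA and the twisting width must be compatible with
topoisomer distributions. We therefore set, per step of rise `h`,

* `sigma_tilt = sigma_roll = sqrt(h / l_p)` radians (4.725 degrees for
  `l_p = 500` A) — for a discrete chain with isotropic bending this gives
  bending-correlation decay `<cos Theta(k)> = exp(-k h / l_p)` with exactly
  the requested `l_p`;
* `sigma_twist = 4.3` degrees, configurable.

Persistence-length recovery is an acceptance test, not an assumption:
`persistence_length()` refits `l_p` from simulated chains (weighted
log-linear fit through the origin, fit range capped at `l_p / 2`).

## Protein-bound DNA

**HU templates.** A bound HU dimer replaces 14 consecutive steps with a
rigid protein-bent template. Crystal-derived step parameters are not
redistributable in this build, so the package generates *synthetic*
templates (`make_hu_fixture()`): the requested overall bend is spread as a
planar arc over the ten core steps by phasing tilt/roll against the
accumulated helical twist, the requested untwist is spread evenly over the
same steps, and the two outermost steps at each end stay at rest so the
terminal helical axes (used by `overall_bend()`, which averages the local
helical axes of the two outermost steps at each end) are well defined. The
arc amplitude is solved by root finding, so the realized bend matches the
request to well under the 2-degree tolerance. Four source templates with
bends 113-128 degrees and untwists 15-24 degrees — inside the 112-129 degree
range of the crystal complexes — times two strand orientations give the
eight variants the sampler draws from. Synthetic templates reproduce the
*magnitude and reach* of HU bending but not crystal-specific kink placement
or any sequence preference; conclusions that depend on those details are out
of scope here.

**Repressor end conditions.** A loop of `N` bp between operator centres
consists of 7 rigid bp from the inner half of each 13-step operator segment
(6 rigid steps per end) and `N - 14` deformable bp (`N - 13` Gaussian
steps). Closure is tested against a *joining step*: the transform expressing
the frame of the loop's first base pair in the frame of its last. The
packaged end conditions come from a documented synthetic model of the
V-shaped tetramer: arms of 80 A at half-angle 25 degrees in the xz-plane,
operator tangents along the inter-arm direction (sign choices generate the
four loop orientations A1/A2/P1/P2: antiparallel/parallel, entry operator
toward/away from the interior) with a small common out-of-plane skew (0.18)
that keeps the joining rotation away from the 180-degree parametrization
singularity at every opening angle. Opening by `dalpha` rotates the entry
arm rigidly about the arm-frame y-axis (`lacr_frame()`), so
`lacr_end_condition(type, dalpha)` is a closed-form conjugation of the base
condition — continuous in `dalpha`, with the implied operator separation
`2 * 80 * sin(25 + dalpha/2)` degrees growing monotonically over the default
[0, 120] range. The table shipped in
`inst/extdata/lacr_end_conditions_synthetic.csv` is this construction on a
10-degree grid and is cross-checked against the constructor in the tests.

Opening is energetically free, as in the source model; a run with
`dalpha_max = 0` is the rigid V-shaped assembly, and a deformable run
accepts a configuration if any (loop type, `dalpha` grid point) window
matches, recording the minimum-deviation window (deviation =
`r/r_max + (1-cos g)/(1-cos g_min) + (1-cos f)/(1-cos f_min)`) to avoid
double counting.

## Sampling and the J factor

A configuration is looped/closed when the accumulated transform times the
joining step is close enough to the identity: end-to-end distance below
`r_max` (default 15 A), and cosines of the net bend `gamma` (angle between
terminal base-pair normals) and residual end-to-end twist `phi` at least
0.98. The twist `phi` is defined by factoring the net rotation into a bend
about the common perpendicular of the two normals followed by a twist about
the normal; for pure-twist chains it reduces to the algebraic twist sum in
(-180, 180], which is tested.

`J` converts the acceptance fraction to an effective molar concentration by
dividing out the phase-space volume of the windows:
`J = f_acc / (N_A V_r) * [4 pi / (2 pi (1 - cos g_max))] * [2 pi / (2 phi_max)]`
with `V_r = (4/3) pi r_max^3`. With the default windows the constant is
184.2 M. Small-tolerance stability of this normalization (halving `r_max`
leaves `J` unchanged within errors) is a test.

**Direct mode** builds each trial chain in full. **Half-chain mode**
generates two independent ensembles of `M` half chains and tests all `M^2`
pairings, an enormous variance reduction for rare closures. The pairing
position error equals the distance between the second half's shifted end
point and the first half's inverse-pose point, so a spatial hash with cell
edge `r_max` and 27-neighbour queries prunes pairs *conservatively* — no
accepted pair can be missed. The standard error in half-chain mode is the
U-statistic estimate, which inflates the binomial error by the between-half
variance of row and column acceptance counts; a single unusually bent half
chain can dominate a rare-event estimate, and the SE reports that honestly.
Direct-vs-half-chain agreement within statistical error is an acceptance
test.

**HU placement.** Dimers are placed by a sequential scan: positions are
visited 5' to 3' and an unoccupied position starts a 14-step footprint with
a calibrated probability; the variant is uniform over the eight templates.
The attempt probability is calibrated *exactly* (dynamic-programme
expectation plus root finding, `calibrate_hu_prob()`) so the mean occupancy
equals one dimer per 150 bp of deformable DNA, the in-vivo HU level the
model assumes. So that direct and half-chain modes sample literally the same
measure, the deformable region is split at its midpoint into two placement
windows in *both* modes and no footprint spans the midpoint; the per-window
probabilities are calibrated so the total mean is unchanged. This is a
documented deviation from a junction-reservation scheme: it trades a small
physical artifact (no dimer centred on the mid-loop junction) for exact
cross-mode equivalence, which is what the equivalence oracle certifies. The
published overlap/partial-site corrections live in prior work that is not
reproduced here.

## The closed-form ring-closure reference

The cyclization test needs an oracle that is not Monte Carlo. The package
evaluates the saddle-point ring-closure J of the discrete twisted chain in
closed form (`wlc_ring_closure_j()`): the saddle is the uniformly bent,
helically phased circle — which closes the discrete chain *exactly*, a
property the construction exploits — contributing `exp(-E)` with
`E = 2 pi^2 l_p / L` plus the twist-mismatch penalty per candidate linking
number; the Gaussian fluctuation integral over the six closure constraints
is computed exactly from the constraint Jacobian, with the flat
circle-phase orbit integrated as a collective coordinate; and the leading
anharmonic coil correction `exp(0.246 L / l_p)` is applied. Beware the
widely quoted end-contact interpolation with the same 0.246 coefficient but
a 14.055/t exponent: that is the *teardrop* (no tangent alignment) closure
density — a different observable from the aligned, twist-registered closure
the acceptance windows measure — and it overshoots the aligned J severalfold
in this regime. At `N = 315` (30 helical turns, in phase) the reference
gives 4.7e-8 M and the half-chain simulation agrees within its ~15%
statistical error; the acceptance band is a factor of two.

## The expression bridge

Reporter activity `E'` is the activity ratio of a two-operator construct to
a single-operator construct, proportional to the probability that the
promoter-proximal operator is unoccupied. Enumerating the binding states of
the two-operator construct (empty; either operator bound; both bound by two
repressors; bridged by one looped repressor weighted by `J`) gives

```
E' = (1 + aR)(1 + bR) / (1 + aR + bR + a b R^2 + a b R J)
```

with `a = K_Osym = 1.3e9 /M`, `b = K_O2 = 3.6e7 /M`, and `R = [LacR] =
103.8 nM` (ten tetramers in the 0.16 um^3 nucleoid,
`molar_concentration(10, 0.16)`; note the value would be roughly fourfold
lower if referred to the 0.67 um^3 cytoplasmic volume — the nucleoid figure
is the packaged default). The form is pinned by two identities the tests
enforce: at `J = 0` the numerator factorizes into the denominator (`E' = 1`,
independent operators), and the closed-form inverse round-trips to 1e-12.
`J` enters in molar units exactly as the simulation emits it, with no hidden
symmetry factors.

As a sanity scale (documented, not asserted): ~30,000 HU dimers on a
4.6e6-bp genome is one per ~153 bp, consistent with the 1/150 default
density.

## Scaled-down testing, and what a green test establishes

The source-scale ensembles (10^12-10^16 configurations, crystal templates)
are not desk-reproducible. The test suite therefore runs scaled-down
ensembles with widened closure windows, and the windows are widened *only
as far as measurability requires*: wide twist windows blur helical phasing
by construction, so phasing tests keep `cos phi >= 0.98` while loosening
position and bend. All runs use fixed seeds; direct mode is bit-for-bit
reproducible from the config echo.

A green suite establishes that the machinery is correct (algebra exact to
1e-9, estimator unbiased across modes, normalization stable, physics
orderings right) in the *synthetic* stated world. It does not establish
crystal-geometry-dependent numbers: loop-type mixes, opening-angle
statistics and absolute looping J depend on the real operator geometry.

One stated ordering is genuinely not reproduced by the synthetic geometry
and its acceptance test is left red deliberately: "mean opening angle larger
at J dips than at peaks (deformable repressor, no HU)". In the synthetic V,
operator separation — and with it loopability — grows monotonically with
opening over the whole [0, 120] degree range, so accepted configurations
concentrate near maximal opening at *every* chain length and the best-phased
windows at dip lengths sit *lower* in `dalpha`, inverting the ordering. The
source geometry's signal relies on the closed V-form being itself near
loop-optimal, so that opening acts purely as a twist-mismatch rescue; that
is a property of the crystallographic arrangement that a synthetic stand-in
does not inherit. The experiment is implemented exactly as stated and
reports the inversion honestly.

## Numerical choices

* Degrees and Angstroms in every interface and file; radians only inside
  function bodies and compiled code.
* Rotation blocks are re-orthonormalized by polar decomposition when a long
  serial product drifts beyond 1e-9.
* `transform_to_params()` is the exact ZYZ inverse of the generator; the
  branch cut that shifts twist by a full turn is corrected jointly with a
  half-turn shift of the bend phase, and a 180-degree bend about an in-plane
  axis raises a degenerate-geometry error rather than returning an
  arbitrary branch.
* Step indices are 1-based in all R interfaces; PDB output numbers base
  pairs from 1.
* Randomness always flows through R's generator (also inside the compiled
  kernels), so `set.seed()` governs every run; half-chain sub-ensembles
  consume the single stream sequentially (halves of side 1, then side 2).
* Configs and results serialize to JSON (a YAML reader is not part of the
  dependency footprint).
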