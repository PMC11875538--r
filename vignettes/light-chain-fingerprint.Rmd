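---
title: "Conformational fingerprinting of immunoglobulin light-chain ensembles"
author: "lcfingerprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational fingerprinting of immunoglobulin light-chain ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcfingerprint)
```

## The scientific problem

Immunoglobulin light chains (LCs) are overproduced both in LC amyloidosis
(AL), where they misfold into organ-damaging fibrils, and in multiple
myeloma (MM), where they stay soluble. Sequence alone has not explained the
difference, but native-state conformational dynamics appears to: in
SAXS-restrained molecular-dynamics ensembles of LC homodimers, the
amyloidogenic proteins transiently visit a distinctive *extended* quaternary
state in which the variable-domain (VL) and constant-domain (CL) dimer
halves are straightened and pulled apart. This package implements the
analysis that turns a weighted conformational ensemble into that
"conformational fingerprint": two global collective variables, a four-state
partition with populations and errors, free-energy surfaces, flexibility
profiles, and SAXS back-calculation against experiment.

The package consumes simulation *output* only — multi-model PDB ensembles
plus per-frame statistical weights (or the final enhanced-sampling bias from
which weights are derived). Running the simulations themselves is out of
scope.

## Collective variables

An LC homodimer has two chains, each split by a hinge (linker, residues
110–120 by convention) into a VL and a CL domain. Per frame we compute:

* **Elbow angle θ** — the angle at the vertex `H = COM(linker A ∪ linker B)`
  between the vectors to `COM(VL dimer)` and `COM(CL dimer)`. Straight
  conformers approach π. The vertex-at-hinge construction is a design
  choice: the published analysis illustrates but does not define its atom
  groups, and this construction reproduces the "straight ≈ θ > 2.5 rad"
  reading. Thresholds may shift slightly under other constructions.
* **d_VC** — distance between the VL-dimer and CL-dimer centers of mass (nm).
* **d_CC, d_VV** — distances between the two CL (respectively VL) domain
  centers of mass, used for the state-conditioned interface surfaces.

Centers of mass are mass-weighted over all atoms of a domain (a `caOnly`
switch restricts to Cα for sensitivity checks). All CVs are invariant under
rigid-body transforms and under chain relabeling — both property-tested.
Internally all lengths are nm; PDB I/O converts from/to Å.

## The four-state partition and the fingerprint call

With the printed thresholds (θ > 2.5 rad "straight"; d_VC boundaries 3.4 nm
and 4.1 nm) the (θ, d_VC) plane is partitioned totally:

| state | definition |
|-------|------------|
| L_B | θ ≤ 2.5 rad (bent, any distance) |
| G   | θ > 2.5 rad, d_VC < 3.4 nm |
| L_S | θ > 2.5 rad, 3.4 ≤ d_VC ≤ 4.1 nm |
| H   | θ > 2.5 rad, d_VC > 4.1 nm |

Boundary closure is a measure-zero design choice: since G and H are defined
by strict inequalities, distances exactly at 3.4 or 4.1 nm fall into L_S,
and θ = 2.5 exactly is bent. L_B carries no distance bounds because only
the angle and distance thresholds are published.

A state's population is the summed frame weight; its error comes from block
averaging (below). Two independent replicates combine per state as the mean
with error `max(half absolute difference, propagated block error)`, so
across-replicate disagreement dominates when present.

The **fingerprint call** classifies an ensemble from its H population:
amyloidogenic LCs populate H at roughly 5–10%, myeloma LCs below 1%. The
call uses the upper error bound `H + nSigma·stderr` (default `nSigma = 1`):
`AL-like` when it reaches 5%, `MM-like` when it stays below 1%, otherwise
`indeterminate`. Using the upper bound means a borderline estimate such as
4.8 ± 0.5% is still called AL-like, matching how such a value is read in
practice; the gap between the bands is reported as indeterminate rather than
forced. Both thresholds and `nSigma` are arguments.

```{r}
pop <- PopulationTable(c(L_B = 62, L_S = 33, G = 0.2, H = 4.8),
                       c(0.4, 0.2, 0.1, 0.5))
fingerprintCall(pop)
```

## Weights, reweighting and errors

Enhanced-sampling frames are unbiased with the final bias potential:
`w_i ∝ exp(V_i / k_B T)` with `k_B = 0.0083144621` kJ mol⁻¹ K⁻¹, computed
max-shifted for overflow safety and normalized. The sign convention (the
deposited bias enters with +) is the standard last-bias estimator and is
overridable. Weight quality is summarized by the Kish effective sample size
`1/Σw²`.

Errors of any weighted estimate use **contiguous block averaging** (default
5 blocks, in frame order to respect autocorrelation; the block count is a
convention since the source states block averaging without a count). Block
means are computed with block-local weight renormalization; the estimate
equals the plain weighted mean, and the standard error is the weighted
standard error over block means.

## Free-energy surfaces

`fes2D()` bins weighted samples on a uniform grid (default 60×60 over the
data range padded 5%; the binning is not published, so this is a package
default) and applies `F = −k_B T ln(P/P_max)`, leaving the occupied minimum
at exactly 0 and empty bins `NA` rather than an arbitrary finite ceiling.
At 310 K the conventional isoline spacing `2 k_B T` equals
`r round(2 * thermalEnergy(310), 4)` kJ/mol (printed as 5.16 in the source
tables, which corresponds to 310.15 K; the package computes, never stores,
the constant). Isolines are plot metadata via `isolineLevels()`, not part of
the stored F values. `stateConditionedFES()` restricts to one state's
frames, renormalizes their weights and builds the (d_CC, d_VV) surface used
to show the perturbed CL–CL interface of the H state.

## Flexibility

`ensembleRMSF()` superposes every frame onto the weighted mean structure on
the Cα of a fit core (default: all selected residues; CDR exclusion is
config-driven since canonical renumbering is out of scope), iterating
mean → fit → mean twice — further iterations change the profile by less
than 1e-4 nm on test ensembles, which is asserted in the suite. The
per-residue RMSF is the square root of the weighted mean squared Cα
deviation. Profiles average over the two equivalent chains and the two
replicates, with provenance recorded.

`leftHandedAlphaOccupancy()` reports the weighted fraction of frames whose
backbone (φ, ψ) falls in the left-handed α region, taken as
0° < φ ≤ 120°, −60° ≤ ψ ≤ 90° — a documented convention, as the region is
never defined numerically in the source.

## SAXS

`debyeIntensity()` is a deliberately **coarse Debye calculator**: scattering
centers are residue centers of mass weighted by residue electron counts
(summed atomic numbers of the atoms present), or individual atoms with
atomic numbers under `representation = "atomic"`. `I(0) = (Σf)²` exactly.
There is no hydration-shell or excluded-volume model, so absolute χ² values
against experiment differ systematically from hydration-aware predictors;
the package's χ² is meaningful for *comparisons* (e.g. the amyloidogenic
ensembles fitting worse than single structures) rather than for reproducing
published absolute values. Ensemble curves are weight-linear combinations of
frame curves.

`fitScaleChi2()` interpolates the calculated curve linearly onto the
experimental grid (never extrapolating), solves scale and optional constant
background in closed form, and reports the *reduced* χ² (divided by
N − n_params; the source convention is unstated).

`guinierRg()` fits ln I vs q² iteratively: starting from the lowest
`⌈n/10⌉+5` points it shrinks/extends the window to the fixed point of
`q_max·R_g ≤ 1.3` (the standard globular-protein bound, unstated in the
source), then — because a straight-line fit pushed to the full 1.3 window
carries a ~2% systematic on sharply curved form factors such as a sphere —
shrinks further while a quartic term in the fit is statistically significant
(|t| > 3), the usual residual-systematics check of Guinier analysis. On an
analytic sphere this recovers `R_g = sqrt(3/5)·R` to better than 0.1%; on
noisy or genuinely Guinier-like data the check leaves the window untouched.
Weights are `(I/σ)²` (delta method on ln I) or unit when σ is unavailable.

```{r}
q <- seq(0.002, 0.25, by = 0.002)
guinierRg(sphereIntensity(3.227, q))
```

## The synthetic generator: what it emulates and what it does not

`generateDimerEnsemble()` is the package's ground-truth instrument. Each
frame samples a state i.i.d. from target populations (defaults mirror an
amyloidogenic LC: 62 / 33 / 0.2 / 4.8% for L_B / L_S / G / H, including the
rare ~5% extended state), then draws (θ, d_VC, d_CC, d_VV) from truncated
Gaussians confined to that state's partition region. Defaults place the
state means inside the printed regions — L_B (2.1 rad, 3.1 nm), L_S (2.8,
3.7), G (2.8, 3.1), H (2.8, 4.4) — with σ of 0.10–0.15 in each coordinate,
and give the H state a CL–CL distance 0.4 nm wider than the compact states,
emulating its perturbed interface. Four rigid 50-bead spherical clouds
(radius 1 nm) plus two 11-bead linker clouds realize the target COM
geometry *exactly* before optional per-bead Gaussian jitter (default
0.05 nm); with 50 beads the COM jitter is ~0.007 nm, so labels recovered
through the full write → read → classify round trip match the generating
truth for ≥99% of frames away from boundaries, and 100% at zero jitter.
Weights are uniform or derived from Gaussian pseudo-biases through the
reweighting path. A single seeded RNG stream makes generation
byte-reproducible.

What the generator does **not** emulate: atomistic side chains, secondary
structure, kinetics or autocorrelation between frames (sampling is i.i.d.),
sequence-specific effects, and experimental SAXS systematics beyond
relative Gaussian noise. Passing tests therefore demonstrate correctness of
the *analysis* under known statistical structure, not force-field realism.

## Numerical choices and degenerate inputs

* Elbow angle errors out when either arm vector is shorter than 1e-6 nm.
* `classifyState()` rejects non-finite CVs; the partition is total otherwise.
* Weight vectors must be non-negative and normalize to 1 within 1e-9.
* FES construction refuses zero total weight and all-points-outside ranges;
  an unpopulated state raises an explicit "state unpopulated" error.
* Guinier fitting needs ≥5 usable (I > 0) points and raises a
  "no Guinier regime" condition on non-negative low-q slopes.
* The weight table binds to PDB models by order, not id, matching deposited
  per-frame bias files; atom masses default to standard atomic masses by
  element inferred from the atom name, with unknown names an error.
* q is Å⁻¹ throughout, with an explicit `nm^-1` input override.

## Problem sizes

The test suite exercises the population machinery at n = 2 000 and 20 000
frames with 3σ multinomial bands (the scale at which a 0.2% state is still
resolvable), FES discretization on 2×10⁵ smooth samples, and Debye/Guinier
consistency on ensembles of a few dozen frames with ~220 scattering centers
— sizes chosen so the full suite runs in well under a minute while every
statistical claim retains power.

## Known limitations

* χ² against real detector data is not comparable to hydration-aware
  predictors (by design; see the SAXS section).
* The elbow-angle construction is one of several reasonable definitions;
  populations near the 2.5 rad threshold shift slightly under alternatives.
* Whether published per-LC population errors are within-run block errors or
  across-replicate spreads is not stated; both are computed
  (`statePopulations()` and `combineReplicates()`).
* Binary trajectory formats (XTC/DCD) and mmCIF are not read; ensembles
  arrive as multi-model PDB.
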