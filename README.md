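# lcfingerprint

Conformational fingerprinting of immunoglobulin light-chain (LC) ensembles
in R.

Free LCs are overproduced both in LC amyloidosis (AL), where they aggregate
into fibrils, and in multiple myeloma (MM), where they remain soluble.
SAXS-restrained molecular-dynamics ensembles of LC homodimers show that the
discriminating feature is dynamic rather than structural: amyloidogenic LCs
transiently (~5–10% of the ensemble weight) visit an extended **H state** in
which the variable-domain (VL) and constant-domain (CL) dimer halves are
straight and well separated, while myeloma LCs populate it below 1%. This
package takes such ensembles — multi-model PDB plus per-frame weights or a
final enhanced-sampling bias — and computes that fingerprint end to end. It
is aimed at structural bioinformaticians analyzing weighted conformational
ensembles of multidomain proteins.

## What it computes

Per frame, two global collective variables: the **elbow angle**
θ = ∠(COM(VL dimer), COM(linkers), COM(CL dimer)) and the dimer separation
d<sub>VC</sub> = |COM(VL dimer) − COM(CL dimer)|, plus the interface
distances d<sub>CC</sub>, d<sub>VV</sub>. Frames are classified by the
printed thresholds into four states,

| state | definition |
|------|-------------|
| L<sub>B</sub> | θ ≤ 2.5 rad |
| G | θ > 2.5 rad, d<sub>VC</sub> < 3.4 nm |
| L<sub>S</sub> | θ > 2.5 rad, 3.4 ≤ d<sub>VC</sub> ≤ 4.1 nm |
| H | θ > 2.5 rad, d<sub>VC</sub> > 4.1 nm |

and populations are weighted sums with block-averaged errors
(`statePopulations`), combined over replicates (`combineReplicates`) and
summarized as an `AL-like` / `MM-like` / `indeterminate` call
(`fingerprintCall`). Around this core: final-bias reweighting
w<sub>i</sub> ∝ exp(V<sub>i</sub>/k<sub>B</sub>T) (`biasToWeights`),
free-energy surfaces F = −k<sub>B</sub>T ln(P/P<sub>max</sub>) with
2k<sub>B</sub>T isolines (`fes2D`, `stateConditionedFES`), weighted RMSF
with iterated superposition (`ensembleRMSF`), left-handed-α Ramachandran
occupancy, a coarse Debye SAXS calculator with ensemble averaging, scale/χ²
fitting and iterative Guinier R<sub>g</sub> (`debyeIntensity`,
`fitScaleChi2`, `guinierRg`, `kratky`), and a deterministic synthetic
dumbbell-dimer generator with exact ground truth
(`generateDimerEnsemble`). A thin CLI over these functions lives at
`inst/scripts/lcfp`.

## Worked example

Generate a synthetic amyloid-like ensemble (the defaults mirror an AL
light chain: 62 / 33 / 0.2 / 4.8% for L_B / L_S / G / H), compute CVs,
populations and the call:

```r
library(lcfingerprint)

spec <- syntheticSpec(nFrames = 5000, seed = 11)
out  <- generateDimerEnsemble(spec)
arch <- syntheticArchitecture(spec)

cv  <- computeCVTable(out$ensemble, arch)
head(cv, 3)
#>   frame theta_rad  d_vc_nm  d_cc_nm  d_vv_nm weight
#> 1     1  1.798485 2.817425 2.320164 2.003456  2e-04
#> 2     2  2.300046 3.180691 2.292551 2.125887  2e-04
#> 3     3  2.237959 3.172041 2.451581 1.853965  2e-04

(pop <- statePopulations(cv))
#> PopulationTable (percent of ensemble weight):
#>   L_B   61.66 +/- 0.72
#>   L_S   33.30 +/- 0.58
#>   G      0.22 +/- 0.07
#>   H      4.82 +/- 0.24
fingerprintCall(pop)
#> [1] "AL-like"
```

The H population (4.82 ± 0.24%) recovers the generator's 4.8% target; the
upper-error-bound call flags the ensemble as amyloid-like. The same objects
feed the free-energy surface and the ensemble radius of gyration:

```r
cvFES(cv)
#> FESGrid: elbow angle (rad) x d(VL dimer, CL dimer) (nm), 60 x 60 bins, 865 occupied
#>   T = 310 K, isoline spacing 2kT = 5.1550 kJ/mol

rg <- ensembleAverageRg(out$ensemble)
sprintf("ensemble Rg = %.3f +/- %.3f nm", rg$rg, rg$stderr)
#> [1] "ensemble Rg = 2.059 +/- 0.002 nm"

guinierRg(sphereIntensity(3.227, seq(0.002, 0.25, by = 0.002)))
#> GuinierResult: Rg = 2.502 +/- 0.000 nm, I0 = 1 (5 pts, qmax*Rg = 0.25, R2 = 1.0000)
```

For real data, `readEnsemble()` reads a multi-model PDB with an optional
`weight`/`bias_kJmol` TSV, `readSAXSCurve()` reads 3-column `.dat` files,
and `runFingerprint()` drives the whole battery from a YAML config and
writes a JSON report plus TSV tables.

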