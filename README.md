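# watref

Absolute quantification of brain metabolite concentrations from 2D proton MR
spectroscopic imaging (MRSI), using a spectroscopic water reference
**synthesized from quantitative MRI maps** and calibrated by a single-voxel
STEAM water measurement — instead of the conventional, lengthy unsuppressed
MRSI water acquisition. The package targets MR physicists and spectroscopy
methodologists who need voxel-wise metabolite concentration maps with
subject-specific water-relaxation correction, and who want to compare that
approach against the two conventional water-scaling schemes.

## What it computes

A metabolite amplitude `S_M` in an MRSI voxel becomes a molal concentration
(mmol per kg of tissue water, CSF excluded) through water referencing:

```
[M]_molal = (S_M / S_W) * 1/(1 - fCSF_H2O) * 1/R_M * H2Omolal
[M]_molar = [M]_molal * (H2O - fCSF) / (1 - fCSF) * rho_w
```

where `R_M = exp(-TE/T2_M) * (1 - exp(-TR/T1_M))` is the metabolite
relaxation factor, `fCSF_H2O = fCSF * dCSF / H2O` the CSF fraction of the
voxel's water mass, `H2O` the voxel water-content fraction, and `H2Omolal`
the molality of water. The three methods differ in the water reference
`S_W`:

* **proposed** — `S_W` is synthesized: the water-content map is resliced
  into MRSI space through the point-spread function (k-space truncation to
  the phase-encode matrix) and scaled by a single-voxel STEAM water
  amplitude corrected for T1/T2/B1+/voxel-volume:
  `svSTEAMWcorr = svSTEAMW * 2 * T1corr * T2corr * B1corr * voxelcorr`,
  with the STEAM-voxel water T2 estimated from T2* by the constant white
  matter calibration `T2 = T2* * 59/47`. No water-relaxation term remains
  downstream, because the synthesized reference is already fully relaxed.
* **ref** — an acquired unsuppressed water grid, relaxation-corrected from
  *literature* GM/WM/CSF values via compartment water scaling.
* **ref-qmri** — the same acquired grid, corrected voxel-wise from
  *measured* T1/T2/H2O maps.

Supporting machinery: PSF-aware reslicing and tissue-fraction computation,
monoexponential T2 mapping from multi-TE spin echoes, a seeded synthetic
phantom generated under the exact forward model the quantification inverts,
ROI aggregation, and Bland–Altman agreement statistics.

## Worked example

Simulate one subject (known ground truth tNAA/tCr/tCho = 13.5/9.0/2.7
mmol/kg, 1% amplitude noise), quantify with the synthesized reference, and
compare against the qMRI-corrected acquired reference:

```r
library(watref)
ph  <- generatePhantom(phantomConfig(seed = 1, noiseSigma = 0.01))
tab <- ph$table

pw  <- proposedWaterReference(ph$steam, ph$maps$t1, ph$maps$t2star,
                              ph$maps$b1, ph$maps$h2o, ph$geom, table = tab)
unlist(pw$factors)
#>    t1corr    t2corr    b1corr voxelcorr
#>  1.012127  1.284025  1.005151  1.728000

res <- quantifyProposed(ph$sm, pw$waterRef, ph$fractionsPsf, pw$h2oMrsi, tab)
res
#> ConcentrationResult (proposed): tNAA, tCr, tCho; 396/400 valid voxels
#>   tNAA   median 13.44 mmol/kg (molal), 10.41 mmol/L (molar)
#>   tCr    median 8.97 mmol/kg (molal), 6.95 mmol/L (molar)
#>   tCho   median 2.69 mmol/kg (molal), 2.09 mmol/L (molar)
```

The medians land on the configured truth to within the 1% noise. Agreement
with the qMRI-based reference method over the four default ROIs:

```r
rq   <- quantifyRefQmri(ph$sm, ph$sw, ph$fractionsPsf, ph$maps$t1,
                        ph$maps$h2o, ph$geom, t2Hr = ph$maps$t2, table = tab)
rois <- defaultRois(ph$geom, ph$fractionsPsf)
blandAltman(roiSummarize(rq, rois, "molar")$mean,
            roiSummarize(res, rois, "molar")$mean)
#> Bland-Altman (n = 12, first minus second):
#>   bias 0.0171 (0.29% of mean), SD 0.01214 (0.20%)
#>   limits of agreement [-0.006696, 0.04089]
```

A bias of a fraction of a percent means the synthesized reference replaces
the 8-minute acquired water scan with a 10-second STEAM measurement at
negligible cost in accuracy — the point of the method.

A thin command-line wrapper is installed at `inst/cli/watref.R`
(`make-phantom`, `quantify proposed|ref|ref-qmri`, `compare`) for running
the same pipeline on NIfTI/JSON bundles from a shell.

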