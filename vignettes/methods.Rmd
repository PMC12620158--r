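---
title: "Water-referenced MRSI quantification: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-referenced MRSI quantification: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watref)
```

## The quantification problem

A proton MRSI voxel yields metabolite amplitudes `S_M` in arbitrary scanner
units. Converting them to concentrations requires a reference signal of
known concentration — tissue water — together with corrections for
relaxation-induced signal loss in both metabolite and water, for the CSF
water that contains no detectable metabolites, and for the coarse spatial
response of phase-encoded MRSI. `watref` implements that conversion three
ways and provides the agreement statistics to compare them.

All three share the molal/molar pair

\[
[M]_{molal} = \frac{S_M}{S_W}\cdot\frac{1}{1 - f^{H_2O}_{CSF}}\cdot
\frac{1}{R_M}\cdot W_{molal},\qquad
[M]_{molar} = [M]_{molal}\cdot\frac{H_2O - f_{CSF}}{1 - f_{CSF}}\cdot\rho_w
\]

with `R_M = exp(-TE/T2_M)(1 - exp(-TR/T1_M))` and
`f^{H2O}_CSF = f_CSF d_CSF / H2O`. The molar map is defined per liter of
tissue excluding CSF; the identity linking the two maps is enforced
voxel-wise on every output and checked by the test suite at 1e-9.

The methods differ only in the water reference `S_W`:

* **proposed** (`quantifyProposed`): `S_W` is synthesized. A 10 s
  single-voxel STEAM water measurement in normal-appearing white matter is
  corrected to a fully relaxed amplitude,
  `svSTEAMWcorr = svSTEAMW \cdot 2 \cdot T1corr \cdot T2corr \cdot B1corr
  \cdot voxelcorr`, and propagated over the slice by the water-content map
  resliced into MRSI space: `S_W(v) = svSTEAMWcorr \cdot
  H2O_{MRSI}(v) / \langle H2O \rangle_{STEAM}`. Because the reference is
  relaxation-corrected by construction, no water-relaxation factor appears
  in the concentration formula.
* **ref** (`quantifyRefLiterature`): an acquired unsuppressed water grid is
  decomposed into GM/WM/CSF molal water fractions
  `f_c^{H2O} = f_c \alpha_c / \sum_j f_j \alpha_j` and attenuated with
  literature spin-echo factors `A_c = exp(-TE/T2_c)(1 - exp(-TR/T1_c))`.
* **ref-qmri** (`quantifyRefQmri`): the same, but with `A` evaluated from
  measured T1/T2 maps and `H2O` from the measured water-content map.

### STEAM-specific corrections

The stimulated echo refocuses half of the available magnetization, so a
factor 2 is applied (toggleable in `correctSteamSignal`; the comparison of
STEAM against the full-echo MRSI water only makes sense after it). The
longitudinal term accounts for the steady state over TR with the mixing
time TM spent along the longitudinal axis:
`attenuation = (1 - exp((TE/2 + TM - TR)/T1)) exp(-TM/T1)`. The transverse
term is `exp(-TE/T2)`. The flip-angle term uses the three nominally
90-degree pulses of STEAM: the amplitude scales with `sin^3` of the actual
flip `B1^+ \cdot \alpha`.

Two typographic ambiguities in the source formulas were resolved as
follows, with the alternative kept behind a switch:

* The longitudinal expression evaluates to an *attenuation* (< 1) while the
  transverse correction is explicitly a reciprocal. Multiplying a measured
  signal by an attenuation would attenuate twice, so every correction
  factor here is the reciprocal of its attenuation (`asPrinted = TRUE`
  reproduces the literal reading; at TR = 10 s the two differ by under
  about 2%).
* The flip correction is implemented literally as
  `sin(alpha)/sin(B1 alpha)^3`; at the nominal alpha = 90 degrees this is
  numerically indistinguishable from the physically motivated
  `sin^3(alpha)/sin^3(B1 alpha)`, available via `cubedNumerator = TRUE`.

The calibration denominator ("the water content summed over the STEAM
voxel") is implemented as the **mean** over HR voxels whose centers fall in
the box: a raw sum would scale with the HR voxel count and break the unit
of the synthesized reference.

### The T2* to T2 calibration

The fast qMRI protocol yields T2*, not T2. The STEAM-voxel water T2 is
estimated by a constant white-matter calibration
`T2 = T2* \cdot 59/47 = T2* \cdot 1.255` (literature WM T2 = 59 ms over
WM T2* = 47 ms, both stored in `RelaxationTable` and overridable). This is
exact when tissue satisfies the same proportionality; the phantom's
`calibratedWm` flag reproduces that regime. Where a measured T2 map exists
(`fitT2Map` on multi-TE spin echoes, log-linear weighted least squares with
optional `nls` refinement), it takes precedence.

## Reslicing and the MRSI point spread function

Phase-encoded MRSI samples k-space on a small matrix (20 x 20 here), so an
MRSI voxel sees tissue through a broad PSF. `resliceToMRSI` collapses the
HR map over the slice profile (box overlap weights) and truncates the
in-plane field in k-space to the MRSI matrix — an ideal top-hat window by
default, a Hamming window to mimic weighted phase encoding — then samples
the truncated field at MRSI voxel centers. The operator is linear,
preserves constant fields, and its discretized kernel integrates to one;
those three properties plus equality with a brute-force DFT oracle are
unit-tested. The source method names the PSF correction without giving its
form, and does not state whether it was applied before or after
downsampling; both the window shape and a plain box average are
configurable, with the top-hat truncation as default since it is the exact
forward model of unweighted Cartesian phase encoding.

Tissue fractions default to plain box averaging (`psf = FALSE`), matching
common partial-volume practice. The phantom, however, forms its signals
through the PSF, so the recovery tests and the acceptance pipeline use
PSF-weighted fractions — with box fractions they would measure the
PSF-vs-box discrepancy rather than the quantification method. PSF-weighted
fractions can ring slightly outside [0, 1] near sharp edges; they are
renormalized to unit sum but deliberately not clipped, preserving the
linear-inverse relationship with the forward model.

Coordinates are world mm via voxel-to-world affines (voxel-center
convention, 0-based indices); inputs must be co-registered and axis-aligned
— rotations are rejected rather than silently resampled. NaN marks invalid
voxels everywhere; reslicing renormalizes around missing data and sets
outputs NaN when the invalid PSF weight exceeds `naThreshold` (default
1e-3).

## Constants and tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| WM T2 / T2* literature pair | 59 / 47 | ms | defines the 1.255 calibration |
| water T1 (GM/WM/CSF) | 1300 / 830 / 4300 | ms | editable literature-style defaults |
| water T2 (GM/WM/CSF) | 110 / 80 / 500 | ms | idem |
| relative water density (GM/WM/CSF) | 0.78 / 0.65 / 1.00 | – | CSF at 1.0: water-content maps are CSF-normalized, and `d_CSF = 1`; keeping the table's CSF density equal makes the compartment model self-consistent |
| `d_CSF`, `rho_w` | 1, 1 | –, kg/L | |
| water molality `W_molal` | 55100 | mmol/kg | the printed "55.1 mmol/kg" is read as 55.1 mol/kg so concentrations land on the mmol scale; the physical 55510 is available as `defaultRelaxationTable("physical")` |
| metabolite T1/T2 (tNAA, tCr, tCho) | 1400/250, 1300/160, 1150/220 | ms | single tissue-averaged pair per metabolite |
| sLASER TR/TE | 2000 / 40 | ms | metabolite and acquired-water sequence |
| STEAM TR/TE/TM, flip | 10000 / 20 / 10, 90 | ms, deg | |

Degenerate voxels are masked, never zeroed: CSF fraction at or above 0.95,
non-positive water reference, `f^{H2O}_{CSF} \ge 1`, or non-positive
non-CSF water content all invalidate a voxel, and the mask travels with the
result.

## What the phantom emulates — and what it does not

`generatePhantom` builds a 96 x 96 x 24 grid of 2.5 mm voxels (an
elliptical WM core, GM elsewhere, two CSF pockets, optionally a rectangular
lesion that segments as GM with elevated T1/T2/water), a smooth polynomial
B1+ field within 0.85–1.15, and forms the MRSI metabolite amplitudes,
the unsuppressed water grid and the STEAM amplitude through exactly the
forward model the quantification inverts, with seeded multiplicative
Gaussian noise on measured amplitudes only. Tissue parameter defaults equal
the literature table, so each method's assumptions can be made to hold (or
deliberately broken via `relaxationScale` or a lesion).

Passing recovery tests on this phantom therefore demonstrates the
*algebraic* correctness of each inversion under its own assumptions — they
cannot certify behavior under model mismatch that real data carry:
lineshape and baseline errors from spectral fitting, residual eddy
currents, receive-field mismatch between STEAM and MRSI (the `kFactor`
correction exists for that case), chemical-shift displacement,
through-slice profile imperfections, or segmentation errors. The noise
model is a first-order stand-in for amplitude-fit uncertainty, not a
spectral simulation.

Problem sizes used by the shipped simulations: unit tests run a
48 x 48 x 8 phantom at 5 mm; the acceptance checks run the full
96 x 96 x 24 phantom — 100 noise-free phantoms for the 0.1% recovery
sweep and a 5-subject cohort (seeds 1–5, 1% noise, four ROIs, three
metabolites, 60 ROI-mean pairs) for the Bland–Altman comparison. These
sizes were chosen as the smallest grids that keep at least four HR voxels
per MRSI voxel per axis and a fully interior STEAM box.

## Agreement statistics

`blandAltman` uses sample (n-1) SDs, differences taken first-minus-second
with the order recorded, and percent forms normalized by the grand mean of
the pair means. ROI-level pairs are the default unit of analysis (the
four-sector VOI layout of `defaultRois`); voxel-level pairing is available
by passing voxel vectors directly. Friedman and post-hoc rank tests on the
three methods are deliberately not re-implemented — `stats::friedman.test`
operates directly on the `roiSummarize` output.

## Known limitations

* The two reference-method formulas reconstruct the standard compartment
  water-scaling formulation; the original supporting material is not
  reproduced here, so details could differ in edge cases (e.g. the exact
  handling of mixed-tissue attenuation averaging — both per-HR-voxel and
  at-averaged-maps modes are provided).
* The constant 1.255 calibration is a WM statement; the proposed method is
  accurate only when the STEAM voxel sits in (normal-appearing) WM.
* Adiabatic-pulse T2 prolongation in sLASER (STEAM water reading ~5–10%
  low against sLASER water in vivo) is not modeled or corrected.
* Metabolite relaxation uses one tissue-averaged T1/T2 pair per metabolite.
* With five subjects and 1% noise on the single STEAM scalar, the
  Bland–Altman bias estimator carries a sampling SD of roughly
  1%/sqrt(5); cohort-level bias bounds tighter than that are
  seed-dependent at this scale.
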