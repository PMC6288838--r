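---
title: "Quantifying germline enrichment of a maternal protein: models and methods"
author: "pieQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying germline enrichment of a maternal protein: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pieQuant)
```

# The scientific problem

In the early *C. elegans* embryo the germline determinant PIE-1 becomes
progressively enriched in the P lineage: the zygote P0 divides
asymmetrically into AB and P1, and P1 into EMS and P2, with PIE-1
concentrating in each germline daughter. pieQuant implements the
quantitative machinery needed to ask *how much* of that enrichment each
mechanism explains:

1. **Absolute concentration estimation.** Embryos expressing a
   GFP-tagged protein are imaged in a bath of recombinant GFP at known
   concentration; after flat-field, camera-background and
   autofluorescence corrections, the intracellular concentration is the
   bath concentration times the intensity ratio.
2. **Blastomere volumetrics.** Cell volumes come from voxel counting over
   labelled membrane-marker z-stacks (1 pL = 1000 µm³).
3. **A mass-balance inheritance model.** At each division, a fraction
   $f$ of the mother's protein amount goes to the germline daughter:
   $f = c_g v_g / (c_g v_g + c_s v_s)$. Concentration attributable to
   inheritance alone after a volume fold-decrease $\varphi$ is
   $c_0\,\varphi\,\prod_i f_i$; whatever the observed concentration
   exceeds that prediction by is attributed to synthesis,
   $1 - \mathrm{predicted}/\mathrm{observed}$.
4. **FRAP-style synthesis detection.** Photobleaching erases maternal
   fluorescence; any subsequent signal increase reports new synthesis.
   Final vs first post-bleach values are compared per embryo with a
   paired t-test.
5. **Two-stage screen statistics.** Per-embryo background-subtracted P2
   means are normalized to an empty-vector control; clones pass stage 1
   (n ≥ 5) by a two-tailed Student's t-test and are confirmed at stage 2
   (n ≥ 11).

With the measured inputs — daughter concentration ratios 2.03:1 and
1.91:1, daughter volumes 10.1/14.7 and 4.2/6.1 pL, zygote concentration
92 nM, volume fold-decrease 6.4 — the model gives segregation fractions
of 58% and 57%, and an inheritance-only P2 prediction of ~195 nM,
roughly half of the observed 424 nM; the remainder is attributed to
germline-restricted translation.

```{r arithmetic}
f1 <- segregationFraction(2.03, 1, 10.1, 14.7)
f2 <- segregationFraction(1.91, 1, 4.2, 6.1)
c(percent1 = segregationPercent(f1), percent2 = segregationPercent(f2))
predictInheritedConcentration(92, 6.4, c(0.58, 0.57))
```

# The synthetic-scene generator

No raw microscopy data accompany the measurements the model rests on, so
every estimator in the package is validated against a generator with
complete ground truth. The generator emulates, per pixel,

$$I = \mathrm{Poisson}\!\left(k\,(C + C_\mathrm{af})\right)\, g + o +
\mathcal{N}(0, \sigma_r),$$

with $k$ the counts-per-nM conversion (`photonsPerNM`, default 5), $g$
a radial vignetting gain peaking at 1 (default 25% corner fall-off),
$o$ the camera offset (default 100 counts), $\sigma_r$ Gaussian read
noise (default 5 counts), and $C_\mathrm{af}$ embryo autofluorescence
(default 20 nM-equivalents, inside the embryo only). Counts are rounded
and clamped to the 16-bit camera range. The Poisson-plus-Gaussian
camera model is the standard EMCCD approximation; the conversion factor
is a free synthetic parameter because real acquisition gain is not part
of the measured record.

Geometry is deliberately two-tier, matching what each measurement
actually used: a 2D midplane ellipse partitioned into blastomeres along
the anteroposterior axis for all intensity work, and 3D ellipsoids on an
anisotropic voxel grid (1 µm z steps over sub-µm xy pixels, as in a
47-slice membrane-marker stack) for all volume work. Midplane cell
*areas* are never used as volumes; every mass-balance step uses the
per-cell volumes in pL carried by the parameters.

The lineage simulation evolves per-cell amounts $A = CV$ between events
by $dC/dt = k_\mathrm{syn} - k_\mathrm{deg} C$ (closed form), splits
amounts $f : 1-f$ at instantaneous divisions, and treats a bleach as
multiplying each cell's fluorescent amount by $1 - p + p s$, where $p$
is the fraction of the cell's area inside the bleach circle and $s$ the
survival fraction. Default study conditions: $c_0 = 92$ nM, divisions
at 600 s and 1500 s after pronuclear meeting, 15 s FRAP frame
intervals with five pre-bleach frames (bleach at 75 s), survival 0.4,
volumes AB 14.7, P1 10.1, EMS 6.1, P2 4.2 pL, and a zygote volume of
26.88 pL so that the P0:P2 fold decrease is exactly 6.4. The default
germline synthesis rate is tuned analytically (`tuneSynthesisRate`) so
synthesized protein accounts for half of the final P2 amount, matching
the observed decomposition; somatic degradation (default
1.5×10⁻³ s⁻¹) acts in ABa/ABp only, where the degradation pathway is
derepressed.

## Modelling choices worth knowing about

- **Cells are well mixed.** A bleach is accounted at cell granularity:
  the spot's area fraction scales the whole cell's amount, and the cell
  re-homogenizes instantly. Sub-cellular bleach gradients and diffusive
  recovery are out of scope (the protocol uses bleaching only to erase
  maternal signal, not to measure mobility). The standard
  whole-embryo-depth bleach (`frapBleachEvent` default) covers the full
  embryo, emulating the repeated spot bleaching that brought total
  fluorescence to ~40%.
- **Autofluorescence bleaches too.** The bleach factor applies to the
  embryo autofluorescence inside the spot as well as to the tagged
  protein — physically, autofluorophores photobleach — so a
  pre-bleach-normalized trace lands at the survival fraction.
- **Maturation delay defaults to 0.** Newly synthesized fluorophore can
  be made invisible for a configurable delay (a FIFO of synthesis
  increments); estimated synthesis is then an underestimate, mirroring
  the real measurement's caveat. None of the validation studies enable
  it.
- **Divisions are instantaneous**; mitotic intervals are not modelled.
- **Determinism.** Every generator takes one integer seed; multi-part
  simulations derive child seeds with `childSeed`, so identical inputs
  give bit-identical outputs.

# Calibration: correction order and its consequences

The estimator follows the experimental recipe exactly: (i) average ten
bath-only images into an illumination reference; (ii) divide the
specimen image by the reference and multiply by the reference's maximum
pixel; (iii) subtract the camera background, measured from an M9 blank
(the outside-embryo region of a *bath-containing* frame contains bath
signal and is the wrong background for calibration frames — both modes
are exposed and documented); (iv) subtract autofluorescence, a single
scalar measured from wild-type embryos in the same bath; (v) convert by
the bath ratio. Means, not medians, are used throughout, and saturated
pixels are excluded with a warning.

Because the camera offset sits *inside* the flat-field division, the
correction is exact for the bath and approximate for the dimmer embryo
interior; with the default optics this leaves a residual bias below 1%,
dominated by vignetting across the embryo footprint. The validation
suite quantifies it: over 100 seeded noisy scenes spanning 50–1500 nM in
the 150/300 nM bath protocols, mean bias is < 2% and the per-scene SD
< 5%; skipping flat-field correction in a vignetted scene at least
doubles the error, which is the ablation the suite also checks.

# Volumetrics without interactive tools

`segmentMembraneStack` replaces interactive commercial segmentation
with a reproducible seeded region-growing on the membrane signal: cell
interiors (sub-threshold voxels) are flooded from one seed per cell;
the bright membrane shell is then contested between the grown cells and
the dark exterior with fronts advancing at equal speed, so the
boundary lands mid-shell at the true surface. Two seeds in one
connected interior are rejected by name. Assignment is winner-take-all
— no partial-volume weighting — so splitting a label conserves voxels
exactly. On blastomere-sized ellipsoid phantoms, label-count volumes
are within 2% of the analytic value and segmented volumes within 5%.
The equal-speed front is isotropic in voxel steps, not micrometres; at
the default 1 × 0.5 × 0.5 µm voxels this costs well under the 5%
tolerance on mid-shell placement.

# Statistical choices

- **Paired t-tests** for within-embryo comparisons (final vs first
  post-bleach timepoint); **Welch's unpaired** for between-genotype
  contrasts; **pooled-variance Student's** tests for the screen, as in
  the original analysis. All two-tailed.
- A degenerate screen comparison (zero variance everywhere, equal
  means) is defined as $p = 1$ rather than an error.
- **No multiple-testing correction by default**: the two-stage retest
  design is itself the false-positive control (stage-2 expected false
  discoveries ≈ $n_\mathrm{null}\,\alpha^2$). A Benjamini–Hochberg
  option exists but defaults off.
- The screen generator draws per-embryo P2 means with CV 0.15 around
  the clone mean; the negative control gets its own larger sample
  (default 20/stage) because an empty-vector control is imaged in every
  session of a real screen, so its pooled n far exceeds any single
  clone's.
- Normalization to a control embryo is implemented as a
  single scalar from the control's first frame (a per-timepoint variant
  would additionally cancel acquisition bleaching, which the original
  analysis did not correct for either; traces are not detrended).

# Problem sizes used in validation

Validation studies are sized to be decisive yet quick: estimator
recovery uses 100 seeded scenes at 100×150 px; the partitioning
round-trip simulates one division per fraction in {0.5, 0.57, 0.58,
0.7}, noise-free and at default noise; the FRAP power/size study runs
500 replicates of 6 embryos each at trace level — the per-cell mean of
an n-pixel region has SE $\sqrt{kC + \sigma_r^2}/\sqrt{n}$ under the
camera model, so large replicate studies need not re-render every frame
(the rendered path is validated separately by the trace-extraction and
partitioning tests); the screen study pools ten replicate 249-clone
screens with 5% true effects drawn from multipliers 0.35–0.65.

Because embryo-to-embryo variability in the FRAP replicates comes from
measurement noise alone (no biological scatter in $c_0$ — a pure scale
factor would cancel under pre-bleach normalization anyway), the quoted
power is an upper bound on what identically-imaged real embryos would
give at the same SNR.

# What passing tests do and do not show

The generator shares its forward model with the estimator's
assumptions: linearity of counts in concentration, a single scalar
autofluorescence, uniform concentration within each compartment, and
well-mixed cells. Passing validation therefore shows the estimators
correctly invert the stated model at realistic SNR — it cannot certify
real-microscope effects outside that model: detector nonlinearity,
spatially structured autofluorescence, refractive-index mismatch along
z, partial confocal sectioning (no PSF is simulated), cell-shape
dynamics, or mRNA-level regulation. Those are explicit non-goals.

# Known limitations

- The zygote volume is not independently measured; 26.88 pL is chosen
  so the volume fold-decrease equals the quoted 6.4. Computing
  $\varphi$ from AB+P1 instead gives 5.9, and both are supported inputs
  (`reproduceFigure1` flags a non-default $\varphi$ in its report;
  92 × 5.9 × 0.58 × 0.57 ≈ 179 nM).
- Whether the 92 nM zygote value is whole-cell or cytoplasm-only at
  NEBD is ambiguous in the measured record; the package treats it as
  whole-cell.
- The 4-cell midplane geometry is a band partition, not a faithful
  cell arrangement; it is adequate for mean intensities because each
  cell is uniform, but not for shape-sensitive statistics.
- P3/P4 divisions are not modelled; the quantified window ends at the
  4-cell stage.
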