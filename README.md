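# pieQuant

Quantitative analysis of how a maternally deposited germline determinant
(PIE-1::GFP) becomes enriched in the P lineage of the early *C. elegans*
embryo.

During the first two embryonic divisions, the zygote P0 splits into AB and
P1, and P1 into EMS and P2, with PIE-1 concentrating in each germline
daughter. pieQuant implements the full quantitative chain needed to
apportion that enrichment between its possible causes — asymmetric
inheritance, volume decrease, somatic degradation and germline-restricted
translation:

- **Calibration** (`estimateConcentration` and friends): absolute
  intracellular concentration (nM) from images of embryos bathed in
  recombinant GFP at known concentration, with flat-field, camera-background
  and autofluorescence corrections applied in the experimental order.
- **Volumetrics** (`volumesFromLabels`, `segmentMembraneStack`): per-cell
  volumes in pL from labelled membrane-marker z-stacks (seeded 3D
  region-growing; winner-take-all, voxel-conserving).
- **Mass-balance inheritance model** (`segregationFraction`,
  `predictInheritedConcentration`, `synthesizedFraction`,
  `fitPartitioning`): at each division a fraction
  f = c_g v_g / (c_g v_g + c_s v_s) of the mother's protein amount goes to
  the germline daughter; the inheritance-only concentration after a volume
  fold-decrease φ is c0 · φ · Π f_i, and the shortfall against the observed
  concentration is attributed to synthesis.
- **FRAP-style time series** (`extractTraces`, `synthesisTest`,
  `endpointSlope`): photobleaching erases maternal signal so that any
  subsequent rise reports new synthesis; final vs first post-bleach values
  are compared per embryo with a paired t-test.
- **Two-stage RNAi-screen statistics** (`normalizeToControl`, `callHits`):
  control-normalized P2 intensities, Student's t-tests, and stage-1 (n ≥ 5)
  / stage-2 (n ≥ 11) hit calling.
- **Synthetic scenes with full ground truth** (`makeCalibrationScene`,
  `makeLineageTimelapse`, `makeMembraneStack`, `makeScreenDataset`): a
  Poisson + Gaussian camera model with vignetting, offset, autofluorescence,
  divisions, photobleaching, synthesis and degradation, used to validate
  every estimator end to end.

## Worked example

```r
library(pieQuant)

report <- reproduceFigure1(defaultRunConfig(seed = 1))
report$segregation_percent_div1   # 58  (% of PIE-1::GFP inherited by P1)
report$segregation_percent_div2   # 57  (% inherited by P2)
report$volume_ratio_div1          # 1.46  (AB : P1 volume)
report$volume_ratio_div2          # 1.45  (EMS : P2 volume)
report$predicted_inherited_p2_nM  # 194.6573  (~195 nM from inheritance alone)
report$synthesized_fraction       # 0.5409  (share of observed 424 nM not
                                  #          explained by inheritance)
report$fold_change_p0_to_p2       # 4.6087  (92 -> 424 nM)
report$synthetic_recovery         # end-to-end estimator check on a rendered
                                  # zygote scene: true 92 nM, estimated
                                  # 91.3 nM (relative error -0.8%)
```

Reading of the headline numbers: given the measured daughter concentration
ratios (2.03:1 and 1.91:1) and volumes (10.1/14.7 and 4.2/6.1 pL), 58% and
57% of the protein amount segregates to the germline daughter at the first
two divisions. Starting from 92 nM in the zygote, a 6.4-fold volume
decrease and those two fractions predict ~195 nM in P2 from inheritance
alone — roughly half the observed 424 nM, implying the other half is newly
synthesized in the germline lineage.

The same model components are exposed individually:

```r
segregationFraction(2.03, 1, 10.1, 14.7)        # 0.5824
predictInheritedConcentration(92, 6.4, c(0.58, 0.57))  # 194.6573
synthesizedFraction(195, 424)                   # 0.54
volumeRatio(10.1, 14.7)                         # 1.46
```

`runSyntheticSuite(defaultRunConfig(seed))` executes the reduced
self-validation battery (estimator recovery, partitioning round-trip,
synthesis-test power/size, screen error rates) and reports pass flags
against its declared tolerances.

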