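# steatoCARS

Label-free quantification of hepatic **microvesicular steatosis** from
coherent anti-Stokes Raman scattering (CARS) microscopy, for hepatologists
and imaging scientists who want droplet-level readouts from unprocessed,
unstained liver tissue. The package implements the full analysis chain —
intensity-based liver lipid scoring, ImageJ-style lipid-droplet enumeration,
Raman band-ratio lipid characterization, spectral identification of
lipid-rich non-parenchymal cells (NPCs), and steatosis grading — together
with a seeded synthetic-data module that generates calibrated liver volumes
and Raman spectra with known ground truth, so every stage is testable
without a microscope.

## The quantities it computes

**Lipid level.** The resonant CARS signal at the 2851 cm⁻¹ C–H stretch
grows with the *square* of the C–H oscillator concentration. The liver
lipid score is therefore

&nbsp;&nbsp;&nbsp;&nbsp;L = √( Ī − B ),

where Ī is the mean voxel intensity of the analysis volume and B the
background (non-resonant signal plus membrane signal, estimated as the
median of sub-Otsu voxels). L is linear in lipid concentration and is
reported normalized to 1 for a reference group, so other groups read as
fold changes.

**Droplet enumeration.** The maximum-intensity z-projection is despeckled,
thresholded at `background + 3·MAD` of the sub-threshold pixels, and
8-connected components are gated by equivalent diameter
d = 2√(A/π) with detection limits **0.4 µm–5 µm** (diffraction limit and
largest expected droplet). Merged droplet clusters exceed the upper gate
and are rejected rather than split, so dense steatosis is slightly
undercounted — by design. Counts are normalized to the standard
167 µm × 167 µm × 25 µm analysis volume.

**Raman band ratios.** From lipid-droplet spectra: unsaturation
I₁₆₆₀/I₁₄₄₅ (C=C stretch over CH₂ bend), packing order I₂₈₅₀/I₂₉₃₅
(CH₂ over CH₃ symmetric stretch), the 1742 cm⁻¹ carbonyl triglyceride
signature, and the 1620 cm⁻¹ marker band that separates lipid-rich NPCs
(Kupffer cells) from hepatocytes, optionally corroborated by 510 nm
autofluorescence.

**Grading.** Steatosis is called when projected droplet area reaches 5% of
the field; the micro/macro/mixed call follows the area share of components
at or above 5 µm, counted on the pre-gating mask.

## Worked example

```r
library(steatoCARS)

# simulate one no-steatosis and one severe-steatosis liver volume
wt  <- generate_volume(cohort_preset("control", seed = 1))
fen <- generate_volume(cohort_preset("severe",  seed = 2))

seg <- segment_droplets(max_project(fen$volume))
seg
#> DropletSegmentation: 800 components, 800 kept in [0.4, 5] um,
#>   0 small / 0 large rejected (threshold 50.4)

droplet_statistics(seg, volume_dims_um(fen$volume))
#> DropletStats: 800 droplets (800.0 per standard volume),
#>   mean area 13.63 um^2, rejected 0 small / 0 large

res <- analyze_cohort(list(wt, fen), c("control", "severe"), "control")
res$summary
#>     group n mean_level sd_level mean_count mean_area_um2 fold_change
#> 1 control 1   1.000000       NA         50      2.276705    1.000000
#> 2  severe 1   2.246657       NA        800     13.627650    2.246657

s <- generate_spectrum(lipid_band_preset("severe", seed = 3))
unsaturation_ratio(s)
#> [1] 1.079806
```

The severe group shows the expected pattern: 800 gated droplets per
standard volume versus 50 in the control, a higher normalized lipid level,
and a raised unsaturation ratio (preset target 1.1). Measured projected
areas run above the geometric truth (13.6 vs 10.2 µm² here) because the
threshold keeps part of the PSF-blurred droplet rim — a property of
threshold-based sizing worth remembering when comparing instruments.

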