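---
title: "Quantifying hepatic microvesicular steatosis from CARS microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hepatic microvesicular steatosis from CARS microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Microvesicular steatosis — many small (≈1 to a few µm) cytoplasmic lipid
droplets that do not displace the hepatocyte nucleus — is an early marker of
fatty liver disease and of drug-induced mitochondrial injury, and it is
poorly served by conventional histology: H&E misses small droplets, and
lipophilic stains over- or under-estimate lipid after tissue processing.
CARS microscopy images unprocessed tissue label-free: the resonant signal at
the C–H stretch (≈2851 cm⁻¹) is strong in lipid droplets, weaker in
membranes, and sits on a Raman-shift-independent non-resonant background.
This package turns such image volumes, plus spontaneous Raman spectra of
individual droplets, into quantitative steatosis readouts.

`steatoCARS` deliberately mirrors the kind of ImageJ-based workflow used in
practice (max projection, global threshold, particle sizing with detection
limits) rather than a more elaborate segmentation, because droplet number
and size gated this way are robust across instruments.

## The intensity model and the lipid score

The resonant CARS intensity is quadratic in the concentration of the probed
C–H oscillators, on top of an additive background from the non-resonant
response and from membranes. The lipid score of a volume is

$$ L = \sqrt{\max(\bar I - B,\, 0)} $$

with $\bar I$ the mean intensity over *all* voxels of the analysis volume
and $B$ the background estimate. Squaring-down restores linearity: on
noise-free synthetic volumes $L$ is proportional to droplet concentration
(the acceptance suite fits a line through the origin with $R^2 \ge 0.999$
and recovers the generator's slope within 5%). Scores are reported
normalized so the reference group's mean is exactly 1; group means then read
directly as fold changes.

Choices a user should know:

* **Background** is the median intensity of voxels at or below the Otsu
  threshold of the volume histogram (deterministic, robust to the droplet
  fraction); a fixed-percentile alternative is available
  (`estimate_background(method = "percentile")`). Background is estimated
  per volume. A constant volume returns its own value with a warning.
* **Negative corrected intensity is clipped to 0** — lipid content is
  nonnegative.
* The mean is over all voxels, not a droplet mask, so the score reflects
  total tissue lipid rather than segmented-droplet lipid.

## Droplet enumeration

Particle analysis operates on the maximum-intensity z-projection (the
per-plane alternative is a matter of calling `segment_droplets` on
single-plane volumes). The steps:

1. **Despeckle**: 3×3 median filter (ImageJ's *Despeckle*), on by default.
   A maximum projection lifts the noise floor and leaves speck excursions;
   without despeckling these become sub-gate false components.
2. **Threshold**: `background + k_thr · MAD` of the sub-threshold pixels,
   `k_thr = 3`. The sub-threshold population is defined by a fixed point —
   starting from the whole image, the statistics are recomputed on pixels
   below the current threshold until stable. This remains well-behaved at
   both extremes: a field with no droplets at all (the healthy-control
   case, where a one-shot Otsu gate would bisect the background histogram)
   and a field a third covered by droplets.
3. **Labeling**: 8-connected components (the ImageJ default).
4. **Gating**: components are kept when their equivalent diameter
   $d = 2\sqrt{A/\pi}$ lies in `[d_min, d_max]` = **[0.4 µm, 5 µm]** — the
   diffraction-limited resolution and the largest droplet expected in liver
   tissue. Rejections are counted by side. Clusters of merged droplets
   exceed the upper gate and are *rejected, not split* — no watershed — so
   dense steatosis is undercounted slightly; this conservative behavior is
   intentional and is verified by the overlap-enabled acceptance check
   (automated count ≤ truth in every volume).

Counts are normalized to the standard analysis volume of
167 µm × 167 µm × 25 µm. Size limits gate on the circle-equivalent
diameter (area-based, as in ImageJ), not a Feret diameter.

## The synthetic liver volume generator

Because no reference image data exist, the generator *is* the study
condition. It emulates:

* **Geometry**: spherical droplets with lognormal radii (log-sd 0.25),
  hard-clipped to radii 0.5–2.0 µm — droplet diameters of one to a few
  microns, with the upper gate respecting the ~5 µm maximum droplet size.
  Severity presets reproduce the droplet burden of the three animal-group
  conditions the pipeline targets, per standard volume: ~50 droplets of
  mean projected area 1.5 µm² (control), ~300 of 6.6 µm² (mild), ~800 of
  10.2 µm² (severe). The lognormal median is solved numerically so the
  clipped distribution hits the target mean area exactly.
* **Placement**: by default droplets keep a minimum *in-plane* boundary
  gap (1.2 µm), which both forbids 3-D overlap and keeps droplets
  separable in the projection the particle analysis runs on — the
  well-separated droplet fields described for healthy and mildly steatotic
  tissue. `overlap = TRUE` drops the constraint to stress the
  merged-cluster rejection path. Placement is rejection sampling, largest
  droplets first; infeasible packings fail with the density named.
* **Intensity**: `nonres_bg + membrane_bg · M + k · c²`, with `c` the
  voxel lipid concentration (axial partial-volume weighted, so sub-micron
  droplets between the 1 µm z-planes still deposit their full signal), and
  `M` a smooth membrane texture. The default contrast (droplet interior
  ≈400 counts over a ≈40-count background) reflects the strong
  droplet-over-membrane contrast characteristic of CARS steatosis images.
* **Membrane texture**: a Gaussian-smoothed random field squashed through
  `tanh`, hence *bounded* within ±15% of the membrane level. Boundedness
  matters: membrane signal stays strictly below any droplet threshold, as
  in the real contrast situation; an unbounded Gaussian texture would put
  rare membrane excursions above any MAD-based threshold.
* **Optics and detection**: anisotropic Gaussian PSF (σ = 0.2 µm lateral,
  0.75 µm axial), additive Gaussian noise (PMT analog detection; sd 2
  counts), quantization to 16-bit integer counts. The blur kernel is
  normalized with edge renormalization, so constant fields are preserved
  exactly and total intensity within 0.5%.
* **Sampling**: 512 px across the 167 µm field (0.326 µm/px), 1 µm
  z-step. Volumes are `[y, x, z]` arrays with voxel centers at
  `(i − 0.5)·step`; a stack of n planes spans `n·z_step`, so the 25 µm
  standard volume has 25 slabs.

Every volume returns a `GroundTruth`: the exact droplet list, analytic
totals, gate counts, and the voxel sums of the concentration field and its
square (the oracle quantities for volume-integration and intensity-linearity
checks). Identical specs (including seed) generate bit-identical volumes.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: hepatocyte morphology and nuclei, spatially
correlated droplet clustering within cells, depth-dependent attenuation,
Poisson (photon) noise statistics (optional Gaussian only), refractive
distortions, and non-spherical droplets. Recovery results on synthetic
volumes bound algorithmic error, not biological segmentation difficulty.

## Synthetic Raman spectra and band metrics

Spectra are sums of Lorentzian bands
$A\,\gamma^2/((\nu - \nu_0)^2 + \gamma^2)$ over a low polynomial baseline
with Gaussian noise, on a 1 cm⁻¹ axis from 600–3100 cm⁻¹. The preset band
inventory covers 1265 (=CH deformation), 1445 (CH₂ bend), 1620 (NPC
marker), 1660 (C=C stretch; the window 1645–1675 cm⁻¹ covers the
1654/1660 usage), 1742 (ester carbonyl), 2850 and 2935 cm⁻¹ (CH₂/CH₃
symmetric stretch). The 1660 amplitude is calibrated numerically so the
closed-form unsaturation ratio hits the group targets 0.73 / 0.98 / 1.1
(control / mild / severe), and the 1620 amplitude likewise for a requested
NPC score.

**Band intensity** is peak height, not integrated area: the maximum within
±15 cm⁻¹ of the band center minus a local linear baseline interpolated
between the window edges, clipped at zero. A quadratic Savitzky–Golay
filter (9 points) is applied first; a raw maximum is biased upward by the
extreme of window noise, while the smoothed height matches closed-form
Lorentzian ratios within 2% across the tested SNR range (weakest-band
SNR 50–150, consistent with averaged lipid-droplet acquisitions; note the
local-linear baseline subtracts a band's own wing level at the window
edges, which the closed-form reference shares by construction). Ratios are
exactly invariant to global intensity scaling and, with the local-linear
baseline, to additive offsets.

**Classification**: the NPC score is I₁₆₂₀/I₁₄₄₅; a spectrum is called
`lipid_rich_NPC` when the score reaches `npc_threshold`, or half of it
with corroborating autofluorescence. The default threshold 0.3 is a design
choice, not a literature value — no numeric cutoff exists for this marker —
and is surfaced as a prominent argument; the acceptance check uses score
distributions well separated from it (0.4–0.8 vs 0.02–0.15). Zero-valued
denominators flag results as undefined rather than erroring.

## Grading

Steatosis is called present when the projected droplet area fraction of the
field reaches 5% — the area-fraction analogue of the "triglyceride
exceeding 5% of liver volume" definition (delineating individual
hepatocytes is out of scope, so the per-hepatocyte clinical criterion is
not computable here). The micro/macro call uses droplet size only — the
nucleus-displacement criterion is unobservable in a CARS channel — with
5 µm as the cutoff diameter, aligned with the particle-analysis upper gate:
macrovesicular at ≥25% of droplet area in components ≥5 µm (counted on the
pre-gating mask, so upper-gate rejects contribute), microvesicular below
5%, mixed between. All grade boundaries are inclusive (≥).

## Numerical and reproducibility choices

* Sizes for the shipped checks: the enumeration bound runs 9 volumes per
  preset at the full 512×512×25 standard-volume sampling; the linearity
  check uses a 84 µm field at the same pixel size; unit tests use 40 µm
  fields. These sizes were chosen so each property is exercised at, or in
  simple proportion to, the study geometry.
* All randomness is seed-scoped (`withr::with_seed`); generators never
  disturb the caller's RNG state. Cohort volume *i* uses `seed + i − 1`.
* 16-bit TIFF + YAML sidecar round-trips are bit-exact for integer counts;
  reading a stack with neither sidecar nor explicit calibration is an
  error — pixel sizes are never assumed.
* Degenerate inputs: constant volumes (background = the constant, with a
  warning), empty droplet lists (mean area flagged undefined, not 0),
  background above the mean (level clipped to 0), zero denominator bands
  (flagged `NA`).

## Known limitations

* No absolute triglyceride calibration (mg/g); scores are relative to a
  reference group.
* No watershed splitting: severe, confluent steatosis is undercounted by
  construction (merged clusters rejected at the upper gate).
* The NPC threshold and the 5 µm micro/macro cutoff are interpretive
  defaults, to be tuned against local histopathology practice.
* Per-volume background estimation assumes the background mode dominates
  the histogram; fields nearly filled with lipid would need the
  percentile method or an external background.
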