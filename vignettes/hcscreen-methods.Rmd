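---
title: "Models and methods behind hcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hcscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscreen)
```

# The assay model

`hcscreen` analyses cell-based reporter screens of the kind used to find
compounds that re-induce a silenced gene — for example an antigen-processing
gene such as TAP-1 whose promoter drives GFP in an engineered reporter cell
line. Each 96-well plate carries library extract wells flanked by a column of
negative controls (1% DMSO vehicle; basal reporter expression) and a column
of positive controls (IFN-γ; maximal induction). An automated imager acquires
a DNA-stain channel and a GFP channel per field, counts nuclei, and reports
per well the total cell count and the average GFP intensity per cell per
pixel. These two numbers per well are the screen's atomic observation.

Three standard statistics drive everything downstream:

* **Percent activity.** A well with average intensity $x$ scores
  $100\,(x-\mu_n)/(\mu_p-\mu_n)$, where $\mu_n,\mu_p$ are the means of the
  negative and positive control wells of the same plate. The scale is
  anchored (0 = vehicle, 100 = full induction) but deliberately unclamped:
  values below 0 and above 100 are informative.
* **Z′-factor.** $1 - 3(\delta_p+\delta_n)/|\mu_p-\mu_n|$ with
  $\delta$ the control standard deviations. It compares the screening window
  to control noise; ≥ 0.5 is the conventional "excellent assay" mark, and a
  plate QC threshold of 0.4 is the package default (`z_min`).
* **Viability band.** A well is only scoreable if its cell count is
  plausible: within $k$ SD (default $k=1$) of the negative-control cell
  density. The band is two-sided for the primary screen ("within one SD")
  and one-sided (floor only) for dilution-series cytotoxicity flagging
  ("below the mean minus one SD is cytotoxic"); both readings are exposed
  via `sided`.

A **hit** is a well with percent activity strictly above the threshold
(default 40) *and* a cell count inside the band *and* a reported intensity.
Failure reasons (`LOW_ACTIVITY`, `CYTOTOXIC`, `HIGH_COUNT`, `MISSING_GFP`)
are recorded per well. Boundary conventions: the activity rule is strict
(`>`), band boundaries are kept (`>=`, `<=`); sample SDs use the $n-1$
denominator; controls are computed per plate, never pooled.

# The synthetic world

Real screens of this type are not publicly deposited, so the package ships a
generator whose defaults state one fixed world, used by every test:

* **Library**: 480 extracts at 0.175 mg/mL on six 96-well plates (column 1
  NEG, column 12 POS, 80 extract wells/plate).
* **Controls**: negative intensity $\mathcal N(200, 200/3)$, positive
  $\mathcal N(1000, 200/3)$ (arbitrary units, truncated at 0). These give a
  true Z′ of exactly $1 - 3(66.7+66.7)/800 = 0.5$, the assay-quality level
  the pipeline is designed around.
* **Cells**: healthy wells $\mathcal N(3500, 500)$ cells — the scale and
  spread of typical hit-well counts (≈3100–4500). Cytotoxic decoys lose a
  `cytotoxic_kill_fraction` (default 50%) of their cells; wells below 25% of
  the healthy mean are emitted with *missing* intensity, as imagers do for
  heavily cytotoxic wells.
* **Effects**: planted hits carry a true activity drawn from `hit_effect`
  (default 47–68%, the range seen in real primary screens of this kind);
  inactive extracts sit at $\mathcal N(0, 5)$. Extract-well intensities are
  drawn on the well-average scale with the negative-control SD, so the
  expected percent activity of a well equals its planted activity exactly.

Two generator choices deserve explanation because they are what make planted
truth *decidable*:

1. **Hit wells get the healthy mean cell count deterministically.** If hit
   wells drew counts from the same distribution as the negative controls,
   about 32% of them would fall outside the mean ± 1 SD band purely by
   shape — whatever the SD — and "planted non-cytotoxic hit" would not be a
   well-defined label under the band rule. Real screens have borderline
   wells; the generator deliberately reserves that role for the explicit
   cytotoxic decoy class.
2. **"Well-separated" hits are ≥ 3σ above the threshold.** Under the stated
   control world an extract well's percent-activity noise SD is
   $100 \cdot (200/3)/800 \approx 8.3$ points, so exact recovery of every
   planted hit requires planted effects of at least $40 + 3\cdot 8.3 \approx
   65$. The end-to-end recovery runs therefore use `hit_effect = c(65, 85)`;
   with the default 47–68 range a per-hit miss rate of ~20% is *expected*,
   which is a statement about single-well screening at Z′ = 0.5, not a
   defect.

What a green end-to-end test establishes is therefore: the pipeline's
normalisation, QC, masking and dual-criterion logic are exact on a world
that satisfies the assay's own design assumptions. It does not establish
robustness to spatial plate effects, intensity drift, carry-over, or
non-Gaussian well noise — none of which the generator emulates.

# Imaging

Field images are geometric phantoms: disk nuclei (DNA channel ≈ 20000 over
background 500) and annular cytoplasm rings carrying the well's GFP mean,
plus i.i.d. Gaussian noise on both channels, clamped to the unsigned 16-bit
range. Centres are placed ≥ $2(r+w)+1$ px apart with a border margin, so
planted counts are unambiguous; the painted GFP annulus extends one pixel
beyond the nominal ring so that measured masks stay inside signal. There is
no PSF, shading, or cell-shape variation — these images test segmentation
book-keeping, not optics.

Quantification mirrors vendor "target activation" pipelines with published,
reproducible pieces: Gaussian smoothing (σ = 1 px) → Otsu threshold →
8-connected labelling → `min_area` filter → border exclusion. Because Otsu
always splits a histogram, a separation guard refuses to call foreground
when the class means differ by < 4 pooled within-class SDs; this is what
makes blank or pure-noise fields return zero nuclei. Cytoplasmic masks are
the Euclidean dilation of each nucleus by `ring_width_px` minus all nuclear
pixels, with contested pixels assigned to the nearest nucleus centroid —
masks are disjoint by construction and the per-cell mean GFP is a plain
arithmetic mean over the mask. Equivalence with any particular instrument's
unpublished algorithm is not claimed.

Image mode renders, per well, one field capturing a configurable fraction
(default 0.6%) of the well's cells at a reduced r = 3 / w = 2 px geometry and
scales the segmented count back up — the full 12 × high-resolution fields per
well would add nothing to the logic being tested. The analysis default for
real-scale images remains `ring_width_px = 5`. A stage-separability test
shows the in-memory path and the TIFF-file path give identical counts and
intensities up to 16-bit quantisation.

# Dose-response fitting

Validation series follow the standard 7-point 3-fold dilution from
0.5 mg/mL. Responses are fitted to the four-parameter logistic
$y = b + (t-b)/(1+(\mathrm{EC}_{50}/x)^h)$ by least squares on
log-concentration (`stats::nls`, port algorithm, tolerance $10^{-10}$, with
an L-BFGS-B fallback). Numerical choices, since "sigmoidal" underdetermines
them: initialisation $b=\min y$, $t=\max y$, EC$_{50}$ at the geometric
mid-concentration, $h=1$; bounds EC$_{50} \in [\min x/10,\ 10\max x]$,
$h \in [0.1, 10]$. Missing responses (cytotoxic dilutions) are dropped; ≥ 4
points at ≥ 4 distinct concentrations are required; perfectly flat data are
returned as a flagged degenerate fit (top = bottom) rather than an error.
Noiseless data are recovered to $10^{-6}$ relative; at 2 activity-points of
noise the median EC$_{50}$ relative error over 100 seeded series stays
within 10%. `classify_validated` applies the same dual criterion per
dilution and breaks best-dilution ties toward the lower concentration (more
potent).

Printed concentrations use the two-significant-figure rule with a third
digit when the leading digit is 1, which reproduces the conventional
printed series (0.5, 0.167, 0.056, 0.0185, 0.0062, 0.0021, 0.00069) from
full-precision internal values.

# Validation calculators

* **MFI** is the arithmetic mean of event intensities ("mean fluorescence
  intensity" read literally; geometric means are sometimes used elsewhere
  but are not what the name says).
* **Percentile gating** selects the $\lceil pn/100\rceil$ largest events,
  including all values tied at the cut (a sorter cannot split a threshold).
* **ΔΔCt**: $\mathrm{RQ} = 2^{-\Delta\Delta C_t}$ with
  $\Delta\Delta C_t = (C_t^{\mathrm{tgt,trt}} - C_t^{\mathrm{hk,trt}}) -
  (C_t^{\mathrm{tgt,ref}} - C_t^{\mathrm{hk,ref}})$; the reference condition
  is 1 by construction. Amplification-efficiency corrections (Pfaffl) and
  instrument-software confidence limits are out of scope.
* **Unit conversion**: µg/mL = µM × molar mass / 1000, with molar masses
  from the embedded IUPAC standard atomic weights (2021 abridged values).
  A published value of 16.37 µg/mL for 75 µM of a 218.34 g/mol compound
  reflects two-decimal truncation of 16.375; comparisons use a 0.01
  tolerance.

# Reproducibility

Every stochastic operation takes an explicit integer seed and runs under a
private RNG state (`withr::with_seed`), so no call perturbs the caller's
RNG. Pipeline stages derive their seeds deterministically from the master
`run_config` seed and a stage label; identical configurations produce
byte-identical JSON reports, which the suite asserts.

# Known limitations

* The well-intensity model is Normal on the well-average scale; per-cell
  intensity distributions and cell-to-cell correlation are not modelled.
* No spatial artefacts (edge effects, gradients), so no B-score or
  median-polish correction is provided or needed here.
* Segmentation is tuned to separated phantoms; the optional watershed-free
  design means touching nuclei in real images would under-count (a
  distance-transform watershed would be the first extension for real data).
* The TIFF layer supports exactly the baseline uncompressed grayscale
  flavour the package writes.
* EC50 confidence intervals, multiple-testing control, and FCS binary
  parsing are deliberately absent.
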