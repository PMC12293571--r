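---
title: "Scoring nucleolar protein redistribution in multiplex IHF images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring nucleolar protein redistribution in multiplex IHF images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNA damage in the ribosomal DNA redistributes nucleolar proteins such as
Treacle/TCOF1 from a diffuse nucleolar pattern into a small number of
discrete foci -- typically one focus per rDNA cluster, so between one and
five per nucleolus. Scoring the fraction of cells that show this
redistribution in immunohistofluorescently (IHF) stained FFPE tissue
sections is a per-cell, sub-nuclear measurement: every cell must be
decomposed into nucleus, nucleoli, nucleoplasm, and foci before a single
count can be made.

`nucleofoci` implements this decomposition as an explicit pipeline over
four channel roles:

* **DAPI** -- nuclei;
* **RNA polymerase II** -- nucleoplasmic staining whose *absence* marks
  nucleoli ("inverse mask": nucleoli appear as dark 3--15 um holes);
* **marker** -- the nucleolar protein of interest, carrying the foci;
* **pan-cytokeratin** (optional) -- cytoplasmic epithelial marker used to
  restrict tissue analysis to epithelium.

The package also ships a forward simulator that renders images with this
exact staining logic together with complete per-cell ground truth, and an
evaluation layer that reproduces a manual-vs-automated agreement analysis
(green/yellow/red per-cell categories and an overall accuracy).

## Pipeline model and assumptions

Inputs are 2-D, single-plane, square-pixel rasters with 16-bit-range
integer intensities. All absolute thresholds in the default configuration
(pan-CK 500, focus peak 400, DAPI sum 50,000) are raw detector counts on
that scale; no normalization or background subtraction is applied, and
every intensity statistic is measured on the **original** channels -- the
enhancement steps below feed segmentation only.

The stages, in order:

1. **Richardson--Lucy enhancement** of the channels feeding segmentation.
   The PSF of the acquiring instrument is not known to the package, so a
   generic isotropic Gaussian is used (sigma 1.5 px, 10 iterations,
   configurable). Because the result is only used to sharpen structures
   before detection, the exact PSF is not load-bearing.
2. **Dark-sphere enhancement** of the RNA Pol II channel: a multi-scale
   scale-normalised Laplacian-of-Gaussian bank over five logarithmic
   scales spanning a 3--15 um diameter band (`sigma = d/(2*sqrt(2))` at the
   band edges), minus the response at a guard scale of 2.5x the upper
   band edge, clamped at zero, times `sensitivity/1000` (default 1133).
   The guard subtraction is what makes the band a true band-pass: the
   scale-normalised response of a step edge *grows* linearly with sigma,
   so subtracting a larger-scale response cancels edges and
   larger-than-band structures instead of merely down-weighting them. A
   20 um disk scores well below half of a 3 um disk's response.
3. **Epithelium segmentation** (tissue mode): pixels strictly above the
   pan-CK threshold, components kept at area strictly above 15 um^2,
   then internal holes filled so that nuclei enclosed by cytoplasmic
   staining fall inside their epithelial region. The threshold is applied
   to the original pan-CK channel: it is an absolute detector-count rule
   and deconvolution would shift its meaning.
4. **Nuclei segmentation** from DAPI. The default `classical` backend is
   fully deterministic: Gaussian smoothing (sigma = diameter/8), Otsu
   threshold, distance-transform watershed; objects under the configured
   minimum area are dropped. A `learned` backend slot exists for a
   pretrained generalist segmentation network; this installation does not
   bundle one and requesting it raises an error naming the fallback. All
   tests and reference computations use the classical backend.
5. **Blob detection** for nucleoli (3 um, probability threshold 5.03%,
   split sensitivity 65.23%) and foci (0.7 um, 13%, 65%). The semantics
   of the two percentage parameters are described below.
6. **The filter ledger** (assignment plus filters), in order: nucleolus
   area > 3 um^2; nucleolus-to-nucleus containment (inside or >= 95%
   overlap, ties to larger overlap then lower label); epithelial
   assignment (>= 50% of nucleus pixels in **one** region); nucleus
   filters (area < 400 um^2, DAPI sum > 50,000, at least one assigned
   nucleolus, no border pixel, epithelial in tissue mode); nucleolus
   dilation by 1 px (box, collisions to the nearest object, ties to the
   lower label); focus filters (inside a dilated nucleolus or >= 10%
   overlap, maximum marker intensity > 400); nucleoplasm = nucleus minus
   **undilated** nucleoli; per-nucleolus foci-count window 1--5.

Strict versus inclusive comparisons follow the printed operators
verbatim (`>`, `<` strict; "at least"/"or 95% intersection"/"intersecting
with 10%" inclusive), and the boundary of every one of these parameters
is pinned by a test.

## Blob finder semantics

The two blob parameters are proprietary in their original setting, so
this package gives them precise, testable meanings:

* **Probability threshold** -- a response basin becomes a blob only when
  its peak reaches this percentage of the global per-image response
  maximum. This is scale-free and matches the percent form of the
  printed values.
* **Split sensitivity** -- adjacent response basins are merged unless the
  saddle-to-peak ratio between them falls below this percentage (deep
  saddle = two blobs). Merging is processed in decreasing saddle order
  with union-find, so the result is order-independent. Higher values
  split more readily.

Two supporting choices make detection well-behaved:

* **Blob footprint.** A watershed catchment basin extends far beyond the
  structure that created it, so each blob is cropped to the basin pixels
  above 30% of its peak response. The 30% figure is calibrated so that a
  top-hat disk at the matched scale keeps approximately its true extent,
  which matters because nucleolus areas feed the > 3 um^2 filter and the
  nucleoplasm subtraction.
* **Contrast floors.** A threshold defined relative to the per-image
  maximum is undefined on an image with no true structure: the maximum is
  then itself noise, and everything scales to it. Detection therefore
  also requires an absolute minimum band-pass contrast (100 counts), and
  focus detection additionally requires 45x the robust noise scale (MAD)
  of the unclamped response. Shot noise at typical staining levels
  produces spurious maxima up to roughly 40x that scale over a megapixel
  image, while genuine diffraction-limited foci sit well above; on
  noise-free input the MAD collapses to zero and only the absolute floor
  remains. This is what makes a signal-free image yield exactly zero
  foci.

For the 0.7 um foci a further structural point matters: a focus rides on
the nucleolus itself, a locally bright 3 um pedestal whose boundary would
leak into any plain band-pass response (and the pedestal's own scale is
close to any usable guard scale). The focus response is therefore
computed on a white top-hat of the lightly smoothed marker channel -- a
greyscale opening with a square element of half-width 0.75x the focus
diameter removes every structure wider than about 1.5 diameters,
including the pedestal and its edges -- followed by a matched-scale
negated LoG for localisation.

## Scoring semantics

The per-cell call follows the manual reference rule: a nucleolus is
*stressed* when its retained focus count lies in the inclusive window
1--5, and a cell is *foci-positive* when at least one of its nucleoli is
stressed. A configuration flag (`foci_window_scope = "nucleus"`) instead
pools retained foci across the cell's nucleoli before applying the
window. The two readings differ because the upper bound is stated
per-nucleolus in the manual protocol but as a plain child-count filter in
the automated one; the manual protocol also says "less than 5" where the
automated filter admits 5. The package defaults to the automated window
(1--5 inclusive) applied per nucleolus, and both choices are explicit
configuration, not behaviour buried in code.

Cells excluded by the pipeline (no nucleolus found, size/intensity/border
failures, non-epithelial) are reported in a separate *excluded* bucket by
the evaluation layer rather than as disagreements, since exclusion is a
different failure mode from mis-scoring. Each excluded nucleus carries
its first failed rule in the `reason` column.

## The simulator

`simulate_tissue()` is a forward model of the staining logic, not of
histology. It renders, at the reference 0.173 um/px scale: ~200
ellipsoidal nuclei (10 +/- 0.8 um) packed by rejection sampling with a
minimum centroid spacing of 0.8x the diameter (dense enough that nuclei
touch and the watershed split is exercised); 1--3 nucleolar holes of
~3 um per nucleus; Bernoulli-`fraction_stressed` cells carrying 1--5
Gaussian foci (0.7 um FWHM) per nucleolus at interior and peripheral
positions; cytoplasmic pan-CK annuli around the epithelial fraction
(0.7 by default), where one cell's cytoplasm may overlie a neighbouring
nucleus exactly as in a 2-D projection of dense tissue -- this is what
keeps the annuli closed so the pipeline's hole-filling step can
reconstruct solid epithelial regions; a smooth autofluorescent field
(amplitude 50); a 1 px optical blur; and Poisson shot noise plus
Gaussian read noise (sd 20), clipped to 16 bits.

Intensity levels (background 100, DAPI 1200, RNA Pol II nucleoplasm
2000, marker nucleolus 1500 over nucleoplasmic 250, focus peak +3000,
pan-CK 1500) are chosen so that the absolute default thresholds sit in a
realistic operating range: a default-parameter simulation survives the
default filters (DAPI sums far above 50,000, focus peaks far above 400).

What the simulator deliberately does **not** emulate: tissue
architecture and texture, out-of-focus cell layers, autofluorescent
structures (collagen, blood cells), spectral bleed-through, anisotropic
PSFs, and staining variability between cores. Passing the end-to-end
recovery tests therefore demonstrates that the pipeline's geometry,
filters and counting are correct under the staining model -- it does not
certify performance on real tissue, where nucleolus identification
through layered cells is the known dominant failure mode.

## Numerical choices and degenerate inputs

* All convolutions are frequency-domain with circular boundary; kernels
  are truncated at 4 sigma and cropped (with normalisation restored) when
  larger than the image.
* LoG kernels are adjusted to exact zero sum, making every response
  invariant to additive intensity offsets.
* Richardson--Lucy guards divisions with a 1e-12 floor and is exactly the
  identity for `iterations = 0` or a zero-width PSF.
* Empty results are valid everywhere: zero nuclei, zero nucleoli, zero
  foci, empty feature tables (full header, zero rows), and undefined
  percentages (`NA` plus an `undefined` flag) for empty denominators.
* Foci intensity statistics for cells with no retained focus are 0, not
  missing; the count column disambiguates.
* Ties are never left to implementation order: containment ties go to
  the larger overlap then the lower label, dilation collisions to the
  nearest object then the lower label, and blob merging is
  order-independent by construction.
* The printed nucleus minimum area (41,994 nm^2, i.e. 0.042 um^2) is
  carried verbatim as the default even though it removes only
  sub-resolution specks at 0.173 um/px; it is an ordinary config field.

## Problem sizes used by the tests

Unit fixtures are 60--512 px rasters built in code. The oracle
equivalence and partition tests use twenty random 256 x 256 mask
fixtures against an independent brute-force reimplementation of the
filter ledger. End-to-end recovery uses the simulator defaults (1024 x
1024 px, ~200 nuclei) at stress fractions 0, 0.3 and 0.6 over five
seeds, with the recovered percentage required to stay within ten points
of ground truth and exactly zero when no foci are rendered. Determinism
is checked byte-for-byte on repeated runs of the command-line interface
over a smaller simulation (384 px, 20 nuclei).

## Known limitations

* The classical nuclei backend assumes roughly convex, DAPI-bright
  nuclei; heavily overlapping or layered nuclei will merge or
  over-split where a learned model would not.
* Blob detection is 2-D; foci split across focal planes are invisible.
* The epithelial rule inherits pan-cytokeratin's inability to separate
  normal epithelium from carcinoma.
* `xlsx` export is not implemented in this installation; CSV is the
  canonical output format.
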