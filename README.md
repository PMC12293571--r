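# nucleofoci

Automated per-cell scoring of nucleolar protein redistribution in
multi-channel immunohistofluorescence (IHF) images of FFPE tissue.

rDNA damage drives nucleolar proteins (e.g. Treacle/TCOF1) out of their
diffuse nucleolar pattern into 1–5 discrete foci per nucleolus. Counting
the cells that show this redistribution requires decomposing every cell
into sub-nuclear compartments. `nucleofoci` does this from four channel
roles — DAPI (nuclei), RNA polymerase II (nucleoplasm, whose *absence*
marks nucleoli as dark holes), a nucleolar marker (foci), and optionally
pan-cytokeratin (epithelium) — and is aimed at image-analysis and
pathology-research groups quantifying nucleolar stress in tissue
sections or FFPE cell blocks.

## The method

For each image the pipeline computes, per retained nucleus *i*:

- nucleus mask `N_i` (deterministic DAPI segmentation: Gaussian
  smoothing, Otsu, distance-transform watershed),
- nucleoli `L_{ij} ⊂ N_i` via a multi-scale Laplacian-of-Gaussian
  dark-sphere band-pass (3–15 µm) on the RNA Pol II channel followed by
  a blob finder (diameter 3 µm, probability threshold 5.03 % of the
  global response maximum, saddle/peak split sensitivity 65.23 %),
- nucleoplasm `P_i = N_i \ ∪_j L_{ij}` (exact pixel-set difference),
- foci `F_{ijk}` at 0.7 µm on the marker channel (white top-hat plus
  matched LoG; probability threshold 13 %, split sensitivity 65 %),

then applies the filter ledger: nucleolus area > 3 µm²; containment
(inside a nucleus or ≥ 95 % overlap); nucleus area < 400 µm², DAPI sum
> 50 000, ≥ 1 nucleolus, no border contact, epithelial (≥ 50 % overlap
with one pan-CK region, tissue mode); focus in a 1-px-dilated nucleolus
or ≥ 10 % overlap, max marker intensity > 400. A cell is
**foci-positive** when at least one of its nucleoli carries a retained
focus count in the inclusive window [1, 5]:

```
positive(i) = ∃ j : 1 ≤ #{k : F_ijk retained} ≤ 5
```

The package also contains a synthetic tissue generator with complete
ground truth (`simulate_tissue()`) and an evaluation layer
(`per_cell_agreement()`, `percent_positive()`, `aggregate_cores()`) that
reproduces a manual-vs-automated agreement analysis with
green/yellow/red per-cell categories.

## Worked example

Simulate a 512-px tissue image with 50 nuclei, 40 % of cells stressed,
run the full pipeline, and compare with ground truth:

```r
library(nucleofoci)

params <- simulation_params(width_px = 512L, height_px = 512L,
                            n_nuclei = 50L, fraction_stressed = 0.4)
sim <- simulate_tissue(params, seed = 42)
res <- analyze_image(sim$image, pipeline_config())
#> epithelium: 11 region(s)
#> nuclei: 47
#> nucleolus candidates: 126
#> focus candidates: 101
#> retained nuclei: 28, foci-positive: 16

head(res$features[, c("id", "nucleolus_count", "nucleolar_foci_count",
                      "foci_positive", "epithelial")])
#>   id nucleolus_count nucleolar_foci_count foci_positive epithelial
#> 1  1               3                    1          TRUE       TRUE
#> 2  2               4                    0         FALSE       TRUE
#> 3  3               2                    6          TRUE       TRUE
#> 4  5               1                    3          TRUE       TRUE
#> 5  6               2                    0         FALSE       TRUE
#> 6 10               1                    1          TRUE       TRUE

percent_positive(res$records, restrict_epithelial = TRUE)$percent
#> [1] 57.14286

ev <- evaluate_against_truth(res, sim$truth)
ev$agreement
#> <agreement_report> n=28 accuracy=1.000 | ++:16 auto-only:0 manual-only:0 --:12 | excluded:22
```

Of the 50 simulated cells, 28 survive all filters (border cells,
non-epithelial cells and cells without a segmentable nucleolus are
excluded and reported separately); every scored cell agrees with its
ground-truth label, and the recovered positive fraction (57.1 %) tracks
the truth over the same tissue (47.4 % over all epithelial cells,
including the excluded ones). Row `id 3` shows a cell scored positive
through one stressed nucleolus even though its pooled count (6) exceeds
the window — the per-nucleolus scoring rule; `foci_positive` reflects
`nucleolar_foci_count` per nucleolus, not the pooled column.

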