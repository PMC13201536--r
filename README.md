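# skinarch

Quantitative analysis of skin tissue architecture from segmented
single-cell spatial data.

In fibrotic skin disease (systemic sclerosis being the prototype), the
finely structured dermal–epidermal interface flattens: dermal papillae
and rete ridges disappear, superficial capillaries are lost, and
collagen fibers become abnormally aligned. Assessing whether a therapy
*reverses* these changes requires measuring tissue architecture — not
just cell counts — from imaging-based spatial assays (Xenium-class
spatial transcriptomics, imaging mass cytometry) and from annotated
histology. `skinarch` packages that analysis as a tested, reusable
pipeline:

- **Preprocessing** — cell-level QC (area, negative-control fraction,
  detected features), shifted-log normalization of counts
  (`ln(1 + x·s/total)`, scaling factor 300), arcsinh and two-stage
  z-score normalization for mass-cytometry intensities.
- **Phenotyping** — marker-gating hierarchy (E-cadherin/CD45/CD31/
  SM22/αSMA), Euclidean knn-graph Leiden clustering, knn label
  transfer (k = 10) with majority vote, and correspondence filtering.
- **Architecture** — epidermal-layer detection from keratinocyte
  patches (≥ 10 cells), per-cell distance to the epidermis, the
  papillary (< 100 µm) / reticular (≥ 100 µm) compartment split,
  papillary vessel-patch detection (knn reachability, ≥ 3 endothelial
  cells), PCA patch orientation relative to the local epidermis axis
  (flagged perpendicular when > 45°), and weighted Gaussian KDE maps.
- **Scoring** — DEG-weighted response score (the t-statistic of a
  univariate linear model of expression on log2 fold-change weights),
  bin-matched module scores, AUCell recovery-curve scores, preranked
  GSEA with a gene-permutation null, pseudobulk aggregation.
- **Composition** — a Bayesian Dirichlet-multinomial contrast of
  cell-type proportions between time points with the ±0.1 minimum
  effect / FDR < 0.05 decision rule.
- **Morphometry** — papillae/mm, perpendicular papilla heights over
  the rete-ridge base line, rete ridges/mm, baseline-normalized fold
  changes, and the collagen fiber alignment coefficient
  `c = |mean(cos 2θ, sin 2θ)|` ∈ [0, 1].
- **Communication** — spatially constrained ligand–receptor scores
  (product of 10%-truncated means, 250 µm secreted / 20 µm contact
  cutoffs, ≥ 10 cells per type).
- **Synthetic tissue** — a generator for layered skin with a
  sinusoidal dermal–epidermal interface, planted vessels of known
  orientation, negative-binomial expression with marker and treatment
  effects, and complete ground truth, so every stage is testable
  without patient data.

## Worked example

```r
library(skinarch)

cfg <- tissue_config(
  samples = data.frame(sample = c("BL_1", "M12_1"),
                       timepoint = c("baseline", "12mo")),
  cells_per_type = data.frame(
    type = c("keratinocyte", "fibroblast", "immune",
             "fibroblast", "endothelial", "immune"),
    compartment = c("epidermis", "papillary", "papillary",
                    "reticular", "reticular", "reticular"),
    n = c(500, 300, 40, 500, 40, 60)),
  vessel_specs = list(
    list(n_cells = 8, centroid = c(500, 90), orientation_deg = 90,
         length_um = 70),
    list(n_cells = 8, centroid = c(1200, 90), orientation_deg = 0,
         length_um = 70)),
  seed = 42L)
tt <- generate_tissue(cfg)

f <- qc_filter(tt$cells, tt$expr)
norm <- shifted_log_normalize(f$expr)

epi <- detect_epidermis(f$cells)
d <- distance_to_epidermis(f$cells, epi)
comp <- ifelse(f$cells$cell_id %in% epi$cell_ids, "epidermis",
               assign_compartment(d))
table(comp)
#> epidermis papillary reticular
#>      1000       696      1200

pap_endo <- f$cells[f$cells$true_type == "endothelial" &
                      comp == "papillary", ]
patches <- lapply(detect_vessel_patches(pap_endo),
                  patch_orientation, epi = epi)
#> vessel patch: 8 cells, angle 89.4 deg, perpendicular: TRUE
#> vessel patch: 8 cells, angle  0.9 deg, perpendicular: FALSE

sig <- build_signature(tt$truth$deg_table)   # padj < 0.05, log2FC weights
scores <- ulm_scores(norm$values, sig)
tapply(scores, f$cells$timepoint, median)
#>     12mo baseline
#>     1.81     0.00
```

The compartment table shows the three tissue layers recovered from
coordinates and type labels alone; the two planted vessels are found
with their planted orientations (the perpendicular one flagged, as
papillary capillaries typically are); and the planted treatment
signature separates post-treatment from baseline cells (median
response score 1.81 vs 0.00).

Histomorphometry works directly on labeled interface contours and
fiber orientation samples:

```r
ct <- generate_interface_contour(8, amplitude_um = 45, period_um = 125)
papillae_per_mm(ct)                        # 8.0
rete_ridges_per_mm(ct)                     # 9.0
median(contour_papilla_heights(ct))        # 45.0 (um)

angles <- generate_orientation_field(1e4, kappa = 2, mu_deg = 30,
                                     seed = 1)
alignment_coefficient(angles)              # 0.698 = I1(2)/I0(2)
```

## Command line

```sh
Rscript inst/cli/skinarch.R preprocess --cells cells.tsv --mtx expr.mtx \
    --method shifted_log --scale 300 --out normalized.tsv
Rscript inst/cli/skinarch.R architecture --cells cells.tsv --border-um 100
Rscript inst/cli/skinarch.R morphometry --contour contour.wkt
```

See `vignettes/skin-architecture.Rmd` for the model descriptions,
parameter defaults and their rationale, and known limitations.
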