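# qispr

Quantified in situ pattern (QISP) analysis of radial gene expression in
the developing cerebral cortex.

## The problem

During corticogenesis, excitatory neurons migrate radially from the
ventricular zone (VZ) through the intermediate zone (IZ) into the
cortical plate (CP), switching gene expression programs as they go.
Colorimetric in situ hybridization (ISH) atlases show *where* along this
radial axis each gene is expressed, but the images are qualitative. The
QISP approach makes them quantitative:

1. **Screen** a log2-scale RMA microarray matrix for genes up- or
   down-regulated ≥ *k*-fold (default 3) between a sorted neuron
   population and its reference, keeping only genes whose expression
   reaches a "not expressed" threshold derived from negative-control
   genes: `threshold = mean + 2·SD` of the controls, rounded up to the
   nearest 0.5 log2 unit. With the canonical internal standard of
   5.5 ± 0.7 this gives 7.0, i.e. every analyzed gene is expressed at
   least `2^(7.0−5.5) ≈ 2.8`-fold over baseline.
2. **Extract** a QISP from each gene's ISH image: a region of interest
   spanning the cerebral wall is split into 20 equal sub-regions
   (sROI 1 at the ventricular surface, sROI 20 at the pia, each 5% of
   the wall), mean optical density is measured per sROI, a scalar
   background is subtracted, and adjacent bins are averaged to smooth.
3. **Validate** each profile with the deep ratio
   `mean(sROI 1–2) / mean(sROI 3–20)`; ratios strictly above 1 mark
   VZ-surface-dominant patterns inconsistent with the differentiating
   lineage and are removed.
4. **Cluster** the validated profiles hierarchically under the
   scale-invariant Pearson correlation distance `d = 1 − r`, cut the
   tree into k groups, and assign each cluster to the **deep**
   (sROIs 1–10), **middle** (11–15) or **upper** (16–20) compartment by
   its centroid peak.

Because no machine-readable images ship with public ISH atlases, the
package includes a synthetic generator that renders ISH-like images and
expression matrices from known archetypes (VZ/IZ/CP peaks, Dab1-like
dual peaks, deep-invalid profiles, flat), so every stage is testable
end to end against planted ground truth.

## Worked example

```r
library(qispr)

demo <- make_demo_dataset("demo", seed = 0, n_genes = 60)  # writes TSVs + PNGs
res  <- run_pipeline(demo$config)

glance(res$screen)
#>   n_genes n_eligible  n_up n_down threshold fold_cutoff
#> 1      70         60    60      0         7           3

res$zone_summary
#>   zone       n   pct pct_1dp
#> 1 deep      18    33    33.3
#> 2 middle    18    33    33.3
#> 3 upper     18    33    33.3

res$clusters
#> <qisp_clusters> 54 genes in 3 clusters (average linkage, Pearson distance)
#>   deep middle  upper
#>     18     18     18
```

The demo plants 60 genes (30% each VZ/IZ/CP peaks, 10% deep-invalid)
plus 10 negative controls. The screen derives threshold 7.0 from the
controls and recovers all 60 planted up-regulated genes; extraction and
validation then drop the 6 deep-invalid genes (54 retained), and
clustering at k = 3 recovers the three archetype groups and their
laminar zones exactly.

Replicate precision, as for repeated manual densitometry of a dual-peak
(VZ + CP) gene:

```r
reps <- generate_replicates(archetype_profile(default_archetypes()$dual_peak),
                            n_reps = 5, seed = 11)
qs <- purrr::map_dfr(seq_along(reps), \(i)
  extract_qisp(reps[[i]]$image, reps[[i]]$roi, paste0("rep_", i)))
replicate_concordance(qs)
#> <qisp_concordance> 5 replicates: r in [0.871, 0.999], mean 0.957;
#>   max peak deviation 0 sROI
```

`plot_qisp()`, `autoplot()` on cluster objects, and
`plot_qisp_heatmap()` draw the profiles, centroids and the
dendrogram-ordered heatmap; `tidy()`/`glance()` turn every result into
tibbles. A thin command-line wrapper with `screen`, `extract`,
`validate`, `cluster`, `run` and `demo` subcommands lives at
`inst/cli/qispr.R`.

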