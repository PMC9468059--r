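# lctau — 3D quantification of cellular tau pathology in the locus coeruleus

The locus coeruleus (LC), a tube-shaped noradrenergic nucleus in the pons, is
among the earliest sites of tau pathology in Alzheimer's disease. Cleared-tissue
light-sheet microscopy produces two-channel volumes of the LC and its
pericoerulear neighbourhood — TH (tyrosine hydroxylase) marking noradrenergic
neurons, AT8 marking hyperphosphorylated tau — and the analysis questions are
quantitative and three-dimensional: how much AT8 signal does each subregion
carry, how is it split between cell bodies and processes, is pathology
dorsally biased, and are AT8+ cells spatially clustered?

`lctau` is an R package for exactly this class of analysis, aimed at
neuroanatomy and imaging groups working with volumetric (anisotropic-voxel)
cell-marker data. It provides:

* a **synthetic phantom generator** (`make_phantom`) emulating the LC/PC
  system — core/shell/A4/subcoeruleus region masks, hard-core TH+ soma
  placement with "hugging" duos, a clustered and dorsally biased AT8+ subset,
  dendrite/axon painting with degeneration-form morphology, and microscope
  noise — with full per-cell ground truth, so every downstream stage is
  testable without any data download;
* **3D segmentation**: soma detection with watershed splitting
  (`detect_cells`), and decomposition of the AT8 foreground into cell-body vs
  process compartments by Euclidean-ball opening (`split_body_process`);
* **geometry**: equal-volume dorso-ventral core splitting
  (`split_dorsoventral`) and concentric-shell zoning of processes around cell
  bodies (`shell_profile`);
* **spatial statistics**: the Monte-Carlo nearest-neighbour index, dense
  cells, duo/minigroup components, neighbouring cells (`nni`,
  `cluster_analysis`);
* **quantification and reporting**: regional burden tables
  (`regional_burden`), five-grade semiquantitative scores
  (`semiquant_score`), group summaries, two-way ANOVA / ANCOVA / Pearson /
  Tukey (`two_way_anova`, `ancova_age`, ...), and simple plots.

The statistic at the core is the **nearest-neighbour index**

    NNI = mean observed 3D NN distance /
          mean NN distance of n uniform-random points in the same mask
          (averaged over Monte-Carlo simulations)

with NNI < 1 indicating clustering; the Monte-Carlo null inside the same
bounded mask makes analytic edge corrections unnecessary. **Dense cells** are
those with NN distance strictly below 75% of the pattern mean; linked dense
cells form **duos** (2) and **minigroups** (3–9).

The compiled core (exact anisotropic distance transforms, connected
components, watershed, 3D thinning, voxel painting, grid-index NN search) is
implemented in Rcpp.

## Worked example

Generate a phantom with 80 TH+ core somas, half of them AT8+, a 0.7 dorsal
bias and clustered AT8+ placement; then recover everything from the images:

```r
library(lctau)

cfg <- phantom_config(grid_shape = c(z = 150, y = 160, x = 250),
                      voxel_size_um = 4, core_radius_um = 150,
                      core_length_um = 700,
                      region_counts = c(core = 80, shell = 0, A4 = 0,
                                        subcoeruleus = 0),
                      at8_fraction = 0.5, dorsal_bias = 0.7, seed = 7)
ph <- make_phantom(cfg)
#> <lc_phantom> B12: 81 TH+ cells (core=81), 40 AT8+, seed 7

det <- detect_cells(ph$th)
nrow(det)
#> [1] 81                      # all somas found, incl. split hugging duos

comp <- split_body_process(threshold_foreground(ph$at8),
                           opening_radius_um = 5)
comp
#> <compartment_masks> body 1.737e+05 um^3 (43.4%), process 2.269e+05 um^3 (56.6%)
# configured body fraction 0.5; the one-voxel erosion shell biases the
# recovered share slightly low (documented; tolerance +-0.1 at 4 um voxels)

bodies <- body_centroids(comp$body, min_volume_um3 = 1000)
res <- nni(bodies, mask_from_regions(ph$regions, "core"),
           n_sims = 100, seed = 8)
res
#> <nni_result> n=40, observed mean NN 60.11 um, simulated 66.11 um (100 sims), NNI = 0.909
# NNI < 1: the generator's AT8+ clustering is detected

cluster_analysis(bodies, th_mean_nn_um = mean(nn_distances(det)))
#> <cluster_result> 40 cells, 10 dense (thr 45.08 um): 3 duos, 1 minigroups, 0 large groups
#>   neighbouring cells: 10 (25.00 per 100)
```

An end-to-end run (`simulate -> segment -> quantify -> spatialstats ->
report`) with CSV/JSON outputs and a seed/config-hash manifest:

```r
run_pipeline(run_config(seed = 1), outdir = "lctau_run")
```

or from the shell via `Rscript inst/cli/lctau.R all --seed 1 --outdir run/`.

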