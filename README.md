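# homologDA

Quantification of **differential chromatin accessibility (DA) between
homologous metaphase chromosomes**, as reported by short (1.5–5 kb)
single-copy FISH probes.

At some genomic loci the two homologs of a chromosome pair reproducibly
bind different amounts of hybridization probe in the same cell — one
allelic target is accessible, the other compacted.  This package
implements the measurement pipeline for that phenomenon, for
cytogeneticists and image analysts who need to go from probe
fluorescence to defensible statistics:

* **GVF active-contour segmentation** of probe spots.  The external
  force is the gradient vector flow of the edge map
  `f = |∇(G_σ∗I)|²`, i.e. the field `(u, v)` solving
  `μ∇²u = (u − f_x)(f_x² + f_y²)`, which extends the snake's capture
  range far beyond the raw gradient.  Integrated intensities are
  background-corrected and measured over matched per-cell apertures.
* **The normalized homolog intensity ratio**
  `R = |I₁ − I₂| / (I₁ + I₂) ∈ [0, 1]` — scale-invariant and symmetric;
  `R ≈ 0` means equivalent accessibility, `R → 1` strong DA.
* **Categorical cell scoring** (bright / intermediate / dim / nil per
  homolog → DA / equivalent / excluded) and a two-proportion z-test for
  non-random preference of one homolog, plus Welch t-tests on ratio
  distributions and Bartlett's test across samples.
* **3D probe geometry**: volume (voxels × voxel volume) and axial depth
  ((sections spanned − 1) × z-step) from reconstructed optical-section
  stacks, with paired homolog comparisons.
* **Open-chromatin context**: a packaged table of 93 probe regions with
  integrated ENCODE GM12878 DNase/FAIRE/histone-mark signal, interval
  signal aggregation from bedGraph tracks, DA-vs-equivalent ANOVA, CNV
  overlap and GC-content checks.
* **Synthetic-data generators** with exact ground truth for every stage,
  so the whole pipeline is covered by parameter-recovery tests.

## Worked example

Simulate a metaphase cell whose homolog-2 spot has 20% of the homolog-1
amplitude (asymmetry δ = 0.8, so the true ratio is δ/(2−δ) = 0.667),
segment both spots, and compute the ratio:

```r
library(homologDA)

sim <- simulate_metaphase_image(asymmetry_delta = 0.8, seed = 5)
q <- quantify_probes(sim$probe, sim$truth$rois)
q
#>  cell_id homolog_id integrated_intensity area_px aperture_px background
#>        1          1             5503.994       5          21   50.13760
#>        1          2             1069.931       5          21   49.72187

normalized_ratio(q$integrated_intensity[1], q$integrated_intensity[2])
#> 0.674        # true value 0.667
```

Score a simulated 40-cell sample in which the designated homolog is
brighter in 85% of informative cells:

```r
tab <- simulate_cell_scores(n_cells = 40, bias = 0.85, seed = 7)
assess_sample(tab)
#> Sample: 40 cells (39 scored, 1 excluded); DA 33 (84.6%), equivalent 6
#> Two-proportion z-test (complementary): 29/33 cells (87.9%) favor the designated homolog
#>   z = 4.352, p = 1.35e-05 -> non-random at alpha = 0.05
```

The z-test answers the study's central question: is the brighter
hybridization biased to one homolog, or random?  Here p ≪ 0.05, so the
asymmetry is non-random.

Compare open-chromatin signal between the packaged DA and equivalent
regions (means are pooled region × feature intensities; `sd` is the mean
of the six per-feature standard deviations):

```r
compare_groups(load_region_features(), design = "two_way")
#> Open-chromatin signal by accessibility class:
#>       class n_regions n_values     mean       sd
#>          DA        34      204 2839.088 1882.898
#>  equivalent        59      354 4399.789 3560.688
#> ANOVA (two_way, log10): F(1, 551) = 52.66, p = 1.35e-12
```

DA regions carry markedly less open-chromatin signal (DNase I HS, FAIRE,
H3K4me1/2, H3K9ac, H3K27ac) than equivalently accessible regions.

Measure probe geometry from a reconstructed stack:

```r
ss <- simulate_probe_stack(n_sections = 21, spot_radii = c(6, 6, 7.5))
geo <- probe_geometry(threshold_stack(ss$stack),
                      lateral_pixel = ss$stack$lateral_pixel,
                      z_step = ss$stack$z_step)
geo$depth    # axial depth in micrometres
```

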