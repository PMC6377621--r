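# polarscape

Landscape-scale analysis of what controls soil biodiversity in polar cold
deserts — for ecologists and biogeographers working with community
fingerprints, terrain data, and structural equation models (SEM).

In ice-free polar soils (the Antarctic Dry Valleys being the canonical
case), three forces compete to structure communities of cyanobacteria,
fungi, and multicellular taxa (nematodes, rotifers, tardigrades,
springtails, mites, mats, mosses, lichens, hypoliths):

* **abiotic filtering** — elevation, slope, aspect, distance to the coast,
  a topographic wetness index, surface temperature, soil chemistry;
* **spatial processes** — dispersal limitation and legacy effects,
  independent of the measured environment;
* **biotic interactions** — links between the richness of the groups
  themselves.

`polarscape` implements the full analysis chain that partitions these
contributions, plus a synthetic-landscape generator with a known
ground-truth path model so that every stage is testable end-to-end without
any field data.

## The pipeline

1. **ARISA richness** (`call_true_peaks`, `arisa_richness`, `bin_peaks`):
   peaks of automated ribosomal intergenic spacer analysis
   electropherograms are accepted as true peaks when they fall in the
   group's size window (100–1200 bp for cyanobacteria/total bacteria,
   100–1400 bp for fungi), exceed 30 RFU, and exceed 0.3 % of the summed
   fluorescence of peaks over 30 RFU; richness S = number of true peaks;
   fragments within 1 bp are binned by single linkage across samples.
2. **Terrain covariates** (`slope_aspect`, `flow_accumulation`, `cti`,
   `distance_to_coast`): Horn slope/aspect, D8 flow accumulation, the
   compound topographic wetness index `CTI = ln(A_s / tan beta)` with
   `A_s` the upslope contributing area per unit contour width and `beta`
   the slope in radians, and Euclidean distance to the zero-elevation
   coastline.
3. **Community structure** (`bray_curtis`, `nmds`,
   `nestedness_temperature`, `nestedness_test`,
   `richness_axis_correlation`): Bray–Curtis dissimilarity, non-metric
   multidimensional scaling by isotonic regression + Guttman updates,
   matrix nestedness temperature (0 = species-poor sites are perfect
   subsets of species-rich ones) with permutation nulls.
4. **Spatial filters** (`pcnm_basis`, `residualize`,
   `spatial_components`): principal coordinates of neighbour matrices
   (PCNM), residualized against all environmental variables, then used to
   predict the three richness variables; a PCA of the predictions yields
   the environment-independent spatial components `s1` and `s2`.
5. **SEM** (`parse_model`, `fit_ml`, `fit_indices`, `standardize`,
   `total_effects`, `net_effects`, `residual_covariance`,
   `predict_richness`): maximum-likelihood covariance-structure fitting of
   recursive path models with composite variables
   (`F_ML = ln|Sigma(theta)| + tr(S Sigma^-1) - ln|S| - p`,
   `chi2 = (n-1) F_ML`, CFI against the independence baseline), total
   effects `(I - B)^-1 - I` on the standardized path matrix, and net
   effects of the abiotic/spatial/biotic constructs as absolute
   standardized composite coefficients.

The built-in model `"final_2019"` links 14 observed variables (8 exogenous
terrain/temperature/spatial columns; endogenous pH, total N, soil water,
and the three richness scores) with 28 paths and df = 35.

## Worked example

```r
library(polarscape)

dem     <- generate_dem(nrows = 32, ncols = 32, cellsize = 100,
                        relief = 800, seed = 42)
samples <- generate_sample_table(dem, n_sites = 490, seed = 42)

fit <- fit_ml("final_2019", samples)
fit
#> <sem_fit> 'final_2019': n = 490, chi2 = 35.528, df = 35, p = 0.4433, CFI = 1.000

round(net_effects(fit), 2)
#>          abiotic spatial biotic
#> cyano_s     0.45    0.40   0.00
#> fungal_s    0.46    0.30   0.23
#> multi_s     0.34    0.17   0.34
```

The fit statistics say the recursive model reproduces the sample
covariance (chi2 close to its 35 degrees of freedom, p > 0.05, CFI 1.0, as
expected since the generator satisfies the model). The net-effects table
is the headline decomposition: for cyanobacteria, abiotic filtering (0.45)
and spatial structure (0.40) dominate and there is no biotic path by
construction; fungi and multicellular taxa pick up biotic contributions
(0.23, 0.34) through the richness links.

ARISA calling and nestedness on the same bundle:

```r
e  <- generate_electropherogram(true_richness = 25,
                                size_range = c(100, 1200), seed = 7)
arisa_richness(call_true_peaks(e, "cyanobacteria"))
#> [1] 25

m  <- generate_community_matrix(samples$multi_richness[1:60],
                                pool_size = 9, nestedness_strength = 0.8,
                                seed = 1)
nt <- nestedness_test(m[rowSums(m) > 0, ], n_perm = 199, seed = 1)
sprintf("temperature %.2f, P = %.3f", nt$temperature, nt$p_value)
#> [1] "temperature 14.18, P = 0.005"
```

A full orchestrated run (synthetic data, ARISA, community statistics,
PCNM filtering, SEM, per-stage CSV/JSON artifacts):

```r
res <- run_all(list(seed = 1, n_sites = 490), out_dir = "out")
```

or from the shell: `Rscript inst/cli/polarscape.R run --seed 1 --out out`.

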