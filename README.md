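# clutraffic

Quantification of clusterin (CLU) trafficking and secretion phenotypes.

Wild-type clusterin is a secreted chaperone: it transits the ER, matures in
the Golgi, and is exported to the medium as the cleaved α/β heterodimer
(sCLU). Several Alzheimer-associated β-chain coding mutations break this
route — the protein is retained in the ER and far less of it is secreted.
`clutraffic` is for cell biologists who need to *quantify* such a phenotype
from two kinds of evidence, with a statistics layer that connects them:

- **Imaging**: per-cell Golgi enrichment ratio of a CLU-EGFP reporter,
  `R = (mean_in_Golgi − background) / (mean_outside_Golgi − background)`,
  with automatic (Otsu) Golgi segmentation on the Golgi-marker channel,
  low-expression exclusion, and Pearson colocalization of the reporter with
  an ER marker per cell.
- **Secretion assays**: conditioned-medium (CM) vs cell-lysate (CL) ELISA
  and western tables turned into per-genotype secreted fractions
  `f = CM/(CM+CL)` after matrix-background subtraction and TGF-β1
  normalization, per experiment and pooled.
- **Group statistics**: single-pass 3-SD outlier removal, one-way ANOVA with
  Tukey HSD contrasts vs wild type, Bonferroni thresholding over constructs
  (α/m), and a Cochran–Mantel–Haenszel test across experiment strata with
  the Mantel–Haenszel common odds ratio
  `OR = Σ(aᵢdᵢ/nᵢ) / Σ(bᵢcᵢ/nᵢ)` and its Robins–Breslow–Greenland 95% CI.

Since no raw micrographs or plates ship with the package, a first-class
synthetic-data module generates seeded multi-channel fields (cells with
nucleus, Golgi crescent, ER web, vesicles) and assay tables with known
ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(clutraffic)
res <- run_pipeline(default_config(seed = 1))

res$summary$cm_cl_proportions
#>   genotype   cm_pct    cl_pct
#> 1  p.I360N 14.95393 85.046074
#> 2  p.R338W 68.40534 31.594655
#> 3       wt 91.56773  8.432268

res$summary$per_genotype[, c("genotype", "n", "golgi_ratio_median", "pearson_er_median")]
#>   genotype n golgi_ratio_median pearson_er_median
#> 1  p.I360N 6           3.896919        0.80595292
#> 2  p.R338W 9           3.963222        0.78705745
#> 3       wt 9          20.553274        0.05073957

dplyr::select(res$comparisons, genotype, metric, p_raw, or_mh, ci_lower, ci_upper, significant)
#>   genotype      metric         p_raw      or_mh   ci_lower   ci_upper significant
#> 1  p.I360N golgi_ratio  4.363176e-14         NA         NA         NA        TRUE
#> 2  p.R338W golgi_ratio  4.363176e-14         NA         NA         NA        TRUE
#> 3  p.I360N  pearson_er  4.363176e-14         NA         NA         NA        TRUE
#> 4  p.R338W  pearson_er  4.363176e-14         NA         NA         NA        TRUE
#> 5  p.I360N cm_fraction  0.000000e+00 0.01628884 0.01383862 0.01917287        TRUE
#> 6  p.R338W cm_fraction 8.359771e-111 0.20072787 0.17283175 0.23312658        TRUE
```

Reading it: the simulated wild type secretes ~92% of total CLU (CM share),
p.R338W ~68% and p.I360N ~15%, matching the generator's ground-truth
fractions (0.91 / 0.68 / 0.15). Wild-type cells show a high Golgi enrichment
ratio (median ~21) and near-zero ER Pearson, while the ER-retained mutants
sit near ratio ~4 with ER Pearson ~0.8. The odds ratios are
mutant-vs-wild-type odds of a CLU molecule being secreted (0.20 for
p.R338W, 0.016 for p.I360N); every p-value clears the Bonferroni threshold
0.05/11 ≈ 0.0045. `run_pipeline(cfg, out_dir = ...)` additionally writes
`cells.csv`, `secretion_estimates.csv`, `comparisons.csv` and
`summary.json`, each stamped with the seed and config hash.

A thin CLI lives at `inst/cli/clutraffic.R`:

```sh
Rscript inst/cli/clutraffic.R run --seed 1 --out out/
Rscript inst/cli/clutraffic.R simulate elisa --seed 1 --out out/
```

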