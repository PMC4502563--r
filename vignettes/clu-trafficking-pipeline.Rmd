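---
title: "Quantifying clusterin trafficking and secretion phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clusterin trafficking and secretion phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clutraffic)
```

## The biological question

Clusterin (CLU) is a secreted chaperone: the wild-type protein transits the
ER, is cleaved and glycosylated in the Golgi, and leaves the cell as the
α/β heterodimer sCLU. Several Alzheimer-associated coding mutations in the
CLU β-chain disrupt this route — the reporter no longer accumulates in the
perinuclear Golgi zone but colocalizes almost exclusively with ER markers,
and far less CLU reaches the conditioned medium. `clutraffic` packages the
quantitative machinery needed to demonstrate such a phenotype:

1. **Per-cell imaging metrics** — a background-corrected Golgi-enrichment
   ratio of a CLU reporter (EGFP fusion) and its Pearson colocalization with
   an ER marker (PDI), computed per manually delineated cell.
2. **Secretion quantification** — converting conditioned-medium (CM) versus
   cell-lysate (CL) ELISA or western measurements into per-genotype secreted
   fractions after matrix-background subtraction and TGF-β1 normalization.
3. **Group statistics** — single-pass 3-SD outlier removal, one-way ANOVA
   with Tukey HSD contrasts against wild type, Bonferroni thresholding
   across constructs, and a Cochran–Mantel–Haenszel (CMH) test with
   Mantel–Haenszel common odds ratio and Robins–Breslow–Greenland (RBG)
   confidence interval across experiment strata.

Because the original micrographs and plates are not public, the package
includes a first-class synthetic-data module with known ground truth, so
every stage is testable end to end.

## The measurement model

### Golgi enrichment ratio

For a cell region $C$ (from the actin channel in real data; from the truth
mask in simulations), a Golgi mask $G \subseteq C$ and field background $b$,

$$ R \;=\; \frac{\overline{I}_{G} - b}{\overline{I}_{C \setminus G} - b}, $$

where $\overline{I}$ are mean reporter intensities. $R \approx 1$ for a
uniformly distributed reporter and grows with Golgi accumulation. $R$ is
invariant to adding a constant to the image (when $b$ is re-estimated) and
to rescaling intensities, which the test suite asserts to $10^{-9}$; this is
what makes the ratio comparable across acquisitions done at identical
settings. Cells whose background-corrected signal outside the Golgi falls
below a fixed cutoff are flagged and excluded — such cells express too
little reporter for a stable denominator.

$G$ is segmented on the **Golgi-marker channel** (Giantin-like), not on the
reporter: an ER-retained mutant has essentially no reporter in the Golgi, so
thresholding the reporter would leave no region to measure and the ratio
would be undefined exactly where it is most informative. The threshold is
Otsu's criterion computed on the marker intensities inside the cell ROI
(256 bins), followed by removal of connected components smaller than
`min_object_px` (default 20 px at 106 nm/px, i.e. ~0.22 µm², well below a
cisterna ribbon but above speckle noise).

### ER colocalization

Pearson correlation between the reporter and the ER-marker channel over all
ROI pixels, with no Costes-style thresholding — the plain Pearson value a
default Coloc2 run reports. It is checked against a direct
covariance/variance computation to $10^{-12}$.

### Secreted fraction

ELISA wells are corrected in three steps, in order: (i) subtract the matrix
immunoreactive background, estimated as the mean concentration of all
nontransfected control wells pooled across experiments (negative corrected
values are clamped to zero with a warning — concentrations below the blank
are measurement noise, not signal); (ii) divide each well by its *relative*
TGF-β1 response (well normalizer over the grand-mean normalizer), which
keeps units of ng/ml and applies to both compartments since the paper trail
gives no formula restricting it to CM; (iii) average duplicates within
(genotype, experiment, compartment) and form
$f_{CM} = CM / (CM + CL)$ per experiment, pooling across experiments by the
ratio of summed amounts (one stacked bar per genotype). By construction
$f_{CM} + f_{CL} = 1$.

### From amounts to a CMH test

The CMH test needs counts. Continuous per-experiment CM/CL amounts are
rescaled so each genotype row sums to `pseudo_n` (default 1000) counts per
experiment stratum, using largest-remainder rounding so row sums are exact.
`pseudo_n` is a config knob: it sets the granularity of the pseudo-counts
and, with it, the nominal power of the test, so reported p-values should be
read as a function of this choice rather than as absolute well counts. The
common odds ratio
$\mathrm{OR}_{MH} = \sum_i a_i d_i / n_i \,/\, \sum_i b_i c_i / n_i$ is
reported in the mutant-versus-wild-type orientation (odds of a CLU molecule
being secreted in the mutant relative to wild type), the orientation in
which such ratios and their CIs are conventionally printed — e.g. a 68/32
mutant split against a 91/9 wild-type split gives
$(68 \times 9)/(32 \times 91) \approx 0.21$. The 95% CI uses the RBG
variance of $\log \mathrm{OR}_{MH}$; calibration of that interval (95% ± 2%
coverage over 1000 simulated stratified tables with a known common OR) is
part of the test suite. The continuity correction is off by default,
matching the classic statistic; a toggle is provided.

### Outliers, Tukey, Bonferroni

Outlier removal is a *single pooled pass per metric*: mean and SD are taken
once over all cells of all genotypes, and values beyond 3 SD are dropped.
(Pooling, rather than per-genotype passes, is consistent with reporting a
single removed-count over all measurements.) Tukey HSD p-values come from
`stats::TukeyHSD`, i.e. the studentized-range distribution with the
Tukey–Kramer correction for unbalanced groups; with two groups this reduces
exactly to the pooled-variance t-test ($q = \sqrt{2}\,|t|$), which the suite
verifies. Both the Tukey p-values and the CMH p-values are compared to the
Bonferroni threshold $\alpha/m$ (default $0.05/11 \approx 0.0045$ for
eleven constructs); the two adjustments are computed and reported
separately rather than composed.

## What the synthetic generator emulates

`make_scene()` builds fields of HeLa-like cells: Fourier-perturbed
elliptical cell outlines, a contained elliptical nucleus, a perinuclear
Golgi crescent broken into 2–4 cisterna ribbons, an ER web obtained by
thresholding band-pass-filtered noise to cover ~30% of the cytoplasm, and
Poisson-placed vesicle puncta. Genotype enters through three multipliers:
`golgi_enrichment` (reporter in Golgi relative to ER), `er_retention`
(reporter in ER relative to cytoplasm) and `vesicle_density`. The packaged
wild type uses (6, 1, 15) — strong Golgi accumulation, weak ER, visible
vesicles — and the ER-retained mutants (1, 3, 2), reproducing the direction
of the published phenotype without claiming its effect size. Noise is
scaled-Poisson shot noise plus additive Gaussian read noise (defaults:
background 100 counts, SD 10, shot scale 1 on amplitudes of ~2000 counts);
there is no PSF convolution by default (a flag enables Gaussian blur of
sd 1 px), no spectral bleed-through, no 3-D structure, and no acquisition
drift. Passing tests therefore show that the *estimators* behave correctly
on well-registered, moderately noisy 2-D data — they do not certify
performance on real confocal stacks with optical crosstalk or segmentation
error, and cell ROIs are taken as given (as with manual delineation).

`simulate_assay()` draws one total CLU amount per experiment (log-normal,
mean 200 ng/ml, CV 0.2 between experiments), splits it CM/CL by the
genotype's true secreted fraction, scales each well by its relative TGF-β1
draw (CV 0.1), multiplies duplicate noise (CV 0.05), and adds a
genotype-independent matrix background (mean 5 ng/ml) that nontransfected
wells carry alone. These defaults were fixed once as plausible conditions
for a commercial sandwich ELISA; no acquisition statistics were published
to match. The packaged phenotype table carries the published secreted
fractions as generator truth (e.g. wild type 0.91 in Flp-In cells, 0.766 in
HEK293T, p.I360N 0.15), so parameter-recovery tests compare the pipeline's
pooled CM percentage against those values.

## Numerical and design choices

- **Field background** is the mean over all pixels belonging to no cell ROI
  (at least 100 such pixels are required); the default exclusion cutoff is
  `background mean + 2 × background SD`, overridable, since the original
  fixed cutoff value is unpublished.
- **Degenerate cases** never abort a batch: a constant marker channel, an
  empty Golgi mask, or a non-positive outside mean produce flagged rows
  (`degenerate_threshold`, `empty_golgi`, `degenerate_denominator`);
  constant channels make the Pearson value `NA`.
- **Determinism**: every generator is a pure function of (inputs, seed) via
  an isolated RNG scope, and the pipeline derives one seed stream per stage
  from the master seed, so disabling one stage cannot shift another stage's
  draws. Re-running a config reproduces the CSVs byte for byte.
- **Coordinates** are 0-based row-major in the written masks; in R, matrices
  are addressed `[row, col]` and label masks use 0 for background.
- **Config** is YAML (nested keys merged over `default_config()`); scenes
  are written as 16-bit multi-channel TIFF (fixed channel order reporter,
  golgi, er, nucleus, actin) with a JSON sidecar, and intensities are
  truncated to integer counts on write.
- **Problem sizes** in the shipped tests: imaging checks use fields of 4–8
  cells at 300–400 px with ≥ 20 cells per genotype for the separation
  check; secretion recovery uses 200 Monte-Carlo replicates of the 3
  experiment × duplicate design; calibration suites use 1000 replicates.
  These sizes were chosen to estimate each property comfortably within its
  sampling error.

## Known limitations

- The pseudo-count bridge to the CMH test is a modeling choice; the original
  analysis does not state what counts entered its test, and p-values scale
  with `pseudo_n`.
- The Golgi segmentation assumes a usable Golgi-marker channel; fields
  without one would require thresholding the reporter, which is undefined
  for fully ER-retained cells.
- The generator's geometric realism is qualitative. Estimator behavior under
  optical blur, bleed-through, or imperfect ROIs is out of scope.
- TGF-β1 normalization is applied to all records; whether the original
  normalization touched only CM is unknown and configurable in principle
  via the correction order.

## A minimal run

```{r, eval = FALSE}
cfg <- default_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "clutraffic_out", verbose = TRUE)
res$summary$cm_cl_proportions
res$comparisons
```

The bundle contains `cells.csv` (one row per cell with ratio, Pearson,
exclusion flag), `secretion_estimates.csv` (per-experiment and pooled CM/CL
amounts and fractions), `comparisons.csv` (Tukey and CMH rows with
Bonferroni calls), and `summary.json` (medians/quartiles per genotype,
stacked CM/CL proportions, significance calls, seed and config hash).
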