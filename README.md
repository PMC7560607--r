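# synscreen

Tools for synapse type-specific proteomics and extracellular interactome
screening. The package covers four analysis stages that together go from
spectral-count tables to validated ligand-receptor candidates:

1. **NSAF enrichment** — label-free comparison of sorted mossy-fiber (MF)
   synaptosomes against the crude P2 synaptosome reference. Proteins need
   at least 3 peptide identifications across the six samples; counts are
   normalized per sample as
   `NSAF_i = (SpC_i / L_i) / Σ_j (SpC_j / L_j)`; missing observations are
   imputed as 0; enrichment is the log2 ratio of group-mean NSAF; per-
   protein two-sided Student's t tests plus Benjamini–Hochberg q values
   define high-confidence enrichment at 5% FDR, with exclusive detections
   (`+Inf` fold change) kept testable.
2. **ELISA screen calling** — pairwise AP-bait x Fc-prey plates are
   background-corrected by the mean of ≥30 blank wells; wells above 5-fold
   over background (FOB) are positives unless the prey is promiscuous
   (signal in every bait, or against the AP-only control); pairs detected
   at least twice across experiments/orientations are accepted and
   assembled into an interaction network with connected-component modules
   and novelty flags.
3. **Pull-down filters** — ecto-Fc affinity-purification hits by spectral
   counts: absent from Fc controls (whole-brain mode) or ≤1 control count
   (MF mode), and ≥2 counts in every bait experiment.
4. **BLI affinity** — one-site steady-state fit
   `R(C) = R_max · C / (K_D + C)` by Levenberg–Marquardt, with reference
   subtraction, replicate averaging, optional drift term and robust loss.

Every stage has a seeded generator (`gen_spectral_counts`,
`gen_elisa_screen`, `gen_pulldown`, `gen_bli_series`) that emulates its
input with the study's stated parameters (e.g. plate background
0.07 ± 0.027 OD650, ~50 FOB dynamic range, 34→0.133 µM twofold BLI
ladder), so the full pipeline runs and is tested without any external
data. The audience is proteomics/interactomics analysts who want the
calling rules as reusable, tested functions rather than spreadsheet
conventions.

## Worked example

```r
library(synscreen)

sim <- gen_spectral_counts(count_sim_config(
  seed = 1, n_proteins = 500, n_enriched = 10, n_exclusive = 5,
  enrichment_fold = 8, baseline_mean = 30, dispersion = 100))
res <- run_enrichment(sim$counts)
enrichment_summary(res)[c("n_significant_enriched", "n_exclusive_significant",
                          "n_high_confidence")]
#> $n_significant_enriched
#> [1] 13
#> $n_exclusive_significant
#> [1] 5
#> $n_high_confidence
#> [1] 14
```

Thirteen shared proteins come out significantly MF-enriched (p ≤ 0.05
with positive fold change) and all five planted MF-exclusive proteins are
significant; 14 proteins clear the stricter 5%-FDR high-confidence
cutoff, 11 of them planted effects.

```r
ser <- gen_bli_series(bli_sim_config(seed = 5, kd_true = 1.4, noise_sd = 0.02))
fit_one_site(ser)
#> One-site steady-state fit
#>   K_D    = 1.402 uM (stderr 0.0899)
#>   R_max  = 1 nm
#>   RSS    = 0.00328 over 9 points; converged: TRUE
```

The fitted dissociation constant (1.40 µM) recovers the simulated 1.4 µM
affinity from a nine-point twofold titration with 0.02 nm response noise.

## Analysis workflow

The `analysis/` scripts run the whole study-scale workflow over simulated
inputs and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # all four synthetic datasets + truth labels
Rscript analysis/02_enrichment.R   # NSAF enrichment table + recovery metrics
Rscript analysis/03_interactome.R  # screen calls, network modules, novelty
Rscript analysis/04_pulldown.R     # both pull-down filter modes
Rscript analysis/05_bli.R          # affinity fit + 50-seed recovery study
```

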