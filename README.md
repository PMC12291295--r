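# mpaehr

Microbiome-derived mycophenolate reactivation and enterohepatic
recirculation analysis.

## The problem

Mycophenolic acid (MPA), the active moiety of the immunosuppressant
mycophenolate mofetil, is conjugated in the liver to its glucuronide
(MPAG) and excreted in bile. Gut-bacterial β-glucuronidases (β-GUS) cleave
the glucuronide, regenerating MPA for reabsorption — enterohepatic
recirculation (EHR) that shows up as a secondary plasma peak 6–10 h after
dosing and drives much of the large between-patient variability in MPA
exposure after kidney transplantation.

`mpaehr` is for pharmacomicrobiomics analysts working with three layers of
data on the same subjects:

* **fecal-lysate assay time courses** — triplicate MPA/MPAG concentrations
  during a 0–2 h incubation with 200 µM MPAG. The reactivation rate is the
  OLS slope of MPA (µM) vs time (h), with LLOQ and blank-baseline handling
  and positive/negative-control QC (`estimate_reactivation_rate()`,
  `qc_controls()`);
* **12-h MPA plasma profiles** — non-compartmental analysis with
  trapezoidal AUCs, detection of the recirculation onset *n*, and the
  degree of EHR, `100·AUC(n–12)/AUC(0–12)` (`degree_ehr()`);
* **metagenomic tables** — β-GUS gene-marker RPKM screens against
  reactivation rates with prevalence filtering and BH correction
  (`compute_rpkm()`, `prevalence_filter()`,
  `correlate_markers_with_rates()`), plus community statistics: Shannon
  diversity, Bray–Curtis dissimilarity, PERMANOVA with factor or
  continuous predictors, restriction-filtered differential-abundance
  screening (`shannon()`, `bray_curtis()`, `permanova()`,
  `differential_abundance_screen()`).

A synthetic-cohort generator (`simulate_cohort()` and friends) encodes the
published cohort conditions — group rate means/SDs, a Gaussian-copula rank
coupling of 0.76 between a subject's reactivation rate and its recycled
drug fraction, a two-component Bateman plasma model with a 6–10 h
secondary peak, and marker/taxa tables with known causal structure — so
the whole chain runs end to end with known ground truth.

## Worked example

```r
library(mpaehr)

design <- cohort_design(seed = 42)           # study-condition defaults
report <- run_pipeline(pipeline_config(design = design, n_perm = 199))
report
#> Pipeline run (seed 42 )
#>   77 subjects in 5 groups
#>   control QC CV: 4.20%
#>   rate-EHR Spearman rho: 0.808 (p = 6.24e-19)
#>   top-ranked marker: FP_GUS_A1
```

The control CV is the between-series precision of 11 simulated
positive-control runs (the study's bound is < 7%); the Spearman rho is the
cohort-level correlation between assay-estimated reactivation rates and
NCA-estimated EHR%, which recovers the configured coupling of 0.76 up to
sampling noise at n = 77; and the top-ranked marker is the planted causal
*F. prausnitzii*-like β-GUS variant.

Single-subject pieces work standalone:

```r
tc <- simulate_assay_timecourse(49.5, "sample", design, seed = 7)
estimate_reactivation_rate(tc, warn_depletion = FALSE)
#> Reactivation rate estimate for 'sample'
#>   rate: 50.48 uM/h (SE 1.178), intercept 0.61 uM, R^2 0.9914
#>   n = 18 points; 0 below LLOQ; baseline subtracted: FALSE

subj <- simulate_cohort(design)[1, ]          # true rate 52.5, fraction 0.50
degree_ehr(simulate_pk_profile(subj, design, seed = 7))
#> NCA for 'pre_tx_001' (pre_tx)
#>   AUC(0-12) 63.64 mg*h/L; Cmax 9.67 mg/L at 6.97 h; C12 2.14 mg/L
#>   onset n = 6.00 h; AUC(n-12) 35.93; degree of EHR 56.5%
```

The degree of EHR upper-bounds the recycled fraction because the primary
tail after the onset is included in the partial AUC; see the methods
vignette (`vignettes/mpaehr-methods.Rmd`) for the model, the onset rule
and its limitations.

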