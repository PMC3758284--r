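# restppi

Physiophysiological interaction (PPI) analysis for resting-state fMRI:
where in the brain does the functional connectivity between two seed
regions depend on a third region's activity?

Standard resting-state connectivity fits, per voxel,
`y = β0 + β1·x1 + ε` and calls `β1` the coupling between the voxel and a
seed. `restppi` implements the three-region extension

```
y = β0 + β1·x1 + β2·x2 + β3·(x1 · x2) + ε
```

whose interaction coefficient `β3` measures how the voxel-to-seed-2
coupling changes with seed 1's activity — a *modulatory* interaction. The
key subtlety is that the multiplicative coupling lives at the neuronal
level while fMRI measures its hemodynamic filtering, so the interaction
regressor is built by deconvolving each seed's BOLD eigenvariate with the
canonical double-gamma HRF, detrending and multiplying the neuronal
estimates on a microtime grid, and reconvolving with the HRF. Subject-level
voxel-wise GLMs (seed main effects, PPI term, WM/CSF eigenvariates, six
motion parameters, discrete-cosine 1/100 Hz high-pass drift, intercept)
feed a group one-sample t-test, cluster forming at one-sided p < 0.001,
random-field-theory or sign-flip-permutation cluster p-values, and
cluster-level (topological) FDR at q = 0.05.

The package is intended for neuroimaging methodologists who want a tested,
scriptable implementation of this pipeline, and ships a synthetic-data
module that generates multi-subject 4D NIfTI cohorts with *known*
modulatory coupling so every stage is verifiable without scanner data.

## Worked example

Simulate one subject with neuronal coupling weights (β1, β2, β3) =
(1, 1, 0.5) at target temporal SNR 1, run the subject-level analysis, and
inspect the interaction t statistic at the planted target:

```r
library(restppi)

sim  <- simulation_config(seed = 42)      # 230 volumes, TR 2 s, 24^3 grid
ds   <- simulate_subject(sim, subject_seed = 123)
sub  <- run_subject(ds, pipeline_config(variant = "both"))

tgt  <- which(as.vector(sphere_mask(sim$target_center_mm, 1,
                                    sim$affine, sim$grid_shape)))
sub$variants$deconv$t[tgt]
#> [1] 3.312873
ppi_term_correlation(sub$variants$deconv$ppi, sub$variants$raw$ppi)
#> [1] 0.7627074
```

The planted interaction is detected at the target voxel (t = 3.3 with 207
residual dof in a single subject), and the deconvolved and raw interaction
regressors correlate at r = 0.76 — similar in spirit to the moderate
correlations seen on real data, where the raw product mixes hemodynamic
and neuronal nonlinearity.

A full cohort, group inference included:

```r
cohort <- run_simulated_cohort(simulation_config(n_subjects = 20, seed = 7),
                               pipeline_config())
cohort$group
#> <ppi_group> n = 20 subjects, 14 cluster(s), 1 surviving FDR q = 0.05
#> # A tibble: 1 x 7
#>   sign             p_fdr voxels peak_t peak_x peak_y peak_z
#>   <chr>            <dbl>  <int>  <dbl>  <dbl>  <dbl>  <dbl>
#> 1 positive 0.00000000868     82   11.9    7.5  -19.5   -1.5
```

Exactly one cluster survives cluster-level FDR: the 82-voxel target
sphere, peaking next to its true center (1.5, −16.5, 1.5) mm. Group-level
results are tibbles in the publication table format (sign, FDR-corrected
cluster p, extent, peak t — negative for negative modulations — and peak
MNI coordinates); `autoplot()` methods cover kernels, series and group
maps, and `tidy()`/`glance()` summarise fitted GLMs.

Analyses of real data follow the same path: `read_volume()` /
`read_motion_params()` for NIfTI and motion inputs, `roi_table()` for the
bundled eight-network seed-pair table (PCC/MPFC for the default-mode
network, etc.), and `run_subject()` / `run_group()` /
`run_deconv_comparison()` for the three analysis stages.

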