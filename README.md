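# nirnoise

Multivariate measurement-error analysis for replicated reflectance spectra
from miniaturized NIR sensors.

Portable near-infrared spectrometers are cheap and easy to use, and their
spectra are almost always fed to multivariate models. Model quality hinges
on separating information from noise, yet the *structure* of the raw-data
measurement error — not just its size — is rarely examined. `nirnoise` is a
toolkit for doing exactly that from replicated spectra: it characterizes
how errors at different wavelength channels co-vary, which noise types
(offset, multiplicative, shot, independent) dominate, and how acquisition
conditions (analytical session, background timing) feed the error budget.
It is aimed at chemometricians and food/analytical scientists who run
replicate studies on handheld spectrometers.

## The method

Let `X` be the `n x p` matrix of replicate spectra (percent reflectance)
and group the replicates so that each group shares a true value. The error
matrix takes each replicate's deviation from its group mean,

    e_ij = x_ij - x̄_j(group of i),

and the pooled **error covariance matrix** is

    Σ = EᵀE / (n - #groups)            (p x p),

with one degree of freedom spent per estimated group mean. The diagonal of
`Σ` is the per-channel error variance (flat = homoscedastic; tracking the
mean spectrum = shot noise; tracking its square = multiplicative noise);
the off-diagonal entries are error covariances, and the derived correlation
matrix `R` gives the scale-free picture (an all-ones `R` is the signature
of offset noise). From these, the package computes:

- **Bilinear decomposition of Σ** (uncentered PCA) and of the grand-mean
  residual matrix `Ê`, with the side-by-side variance-percentage table: if
  the per-component percentages agree, the uncorrelated (independent) error
  contribution is small.
- **K redundancy index** of an error matrix — `K = Σ_j |φ_j − 1/p| /
  (2(p−1)/p)` over the correlation-matrix eigenvalue fractions `φ_j` — which
  is 0 for uncorrelated variables and 1 for rank-1 (fully correlated)
  error, together with its **imbedded correlation** floor
  `K_min = (p − n)/(p − 1)` forced by rank when replicates are fewer than
  channels.
- **Hotelling T² / Q screening** of replicates against a mean-centered PCA
  model with 95% F- and Jackson–Mudholkar limits and per-wavelength
  contribution vectors.
- **Reproducibility descriptives**: per-wavelength SD/RSD, per-replicate
  RMS deviation, signal-to-noise ratio.
- A **synthetic-data generator** emulating a two-instrument replication
  design (236 channels over 972–1701 nm; 74 channels over 1351–2559 nm;
  2 background-timing modes × 3 sessions × 15 replicates) with a
  closed-form theoretical `Σ` for validation.

## Worked example

```r
library(nirnoise)

# one sample, NeoSpectra-like instrument, full 6-session design
ds <- simulate_dataset(design_spec(samples = "sugar_lump"),
                       noise_model(), seed = 7)
ds
#> <spectra_dataset> 90 replicate spectra x 74 channels (1351-2559 nm)

print(reproducibility_table(ds), digits = 3)
#>              statistic sugar_lump
#> 1     absolute_sd_mean      0.770
#> 2 relative_sd_mean_pct      7.282
#> 3             rms_mean      0.637
#> 4               rms_sd      0.428
#> 5             snr_mean     14.149
#> 6               snr_sd      2.542

# error covariance over session replicates
Sigma <- error_covariance(error_matrix(ds, replicate_grouping(ds, "per_session")))
Sigma
#> <error_covariance> 74 x 74, dof = 84
#>   diagonal: 0.2895 to 0.4521 (%R)^2

# K index of one session's 15 x 74 error matrix, vs its rank floor
s1 <- subset_spectra(ds, session_id == "1A")
k_index(error_matrix(s1, replicate_grouping(s1, "all")))
#> <k_result> K = 0.8678 (p = 74, n = 15, imbedded floor 0.8082)

# residuals vs error-covariance variance comparison
variance_comparison(residual_matrix(ds),
                    error_covariance(error_matrix(ds, replicate_grouping(ds, "all"))),
                    k = 4)
#>  component pct_residuals pct_sigma difference
#>          1        94.882    99.992     +5.110
#>          2         0.377     0.002     -0.375
#>          3         0.240     0.001     -0.239
#>          4         0.212     0.000     -0.211
#> component-1 gap: +5.110 points
```

Reading the output: the mean absolute SD (0.77 %R) and SNR (~14) summarize
raw repeatability; the session error matrix's K = 0.87 sits above its rank
floor of 0.81, saying the error is strongly correlated across channels
(offset/multiplicative dominated) but not purely rank-1; and the close
agreement of the two variance columns at component 1 shows the independent
noise contribution is small, with the +5.1-point gap quantifying it.

The whole analysis — tables, covariance/correlation CSVs, heatmaps,
diagonal overlays by session and background mode, K table, run manifest —
can be produced in one call with `run_pipeline()`, or from a shell via
`inst/cli/nirnoise-report.R`.

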