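---
title: "Characterizing measurement-error structure in replicated NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing measurement-error structure in replicated NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirnoise)
```

## The problem

A reflectance spectrum from a miniaturized NIR sensor is a vector
measurement: its error is a vector too, and errors at neighbouring
wavelength channels are rarely independent. Chemometric models separate
information from noise, so knowing the error's *structure* — which channels
err together, by how much, and why — matters as much as its size. The
standard experimental route is replication: repeated scans with sample
repositioning, across analytical sessions run under different
background-timing regimes, expose the variance components of routine use.

This vignette documents the model this package implements, the choices
behind its defaults, and what its validation does and does not establish.

## Error matrices and the pooled covariance

Given `n` replicate spectra over `p` channels and a grouping of replicates
(per session, per background mode, or all together), the error matrix is
`e_ij = x_ij − x̄_j(group of i)`, taking the group's arithmetic mean as the
true value. Deviations from the grand mean of *all* spectra form the
residual matrix `Ê` instead; the difference between the two is exactly the
between-group structure.

The pooled error covariance is `Σ = EᵀE/(n − G)` for `G` groups: each
group's mean costs one degree of freedom, and this divisor makes the pooled
estimator unbiased (the per-group divisor `n` vs `n−1` is not prescribed by
common usage; we take the unbiased pooled form throughout). `Σ`'s diagonal
is the per-channel error variance; `cov2cor` of `Σ` gives the scale-free
correlation picture. Channels with numerically zero variance (relative
tolerance `1e-12` of the largest diagonal entry) are excluded from the
correlation matrix and reported, never silently dropped.

Which grouping to use is a scientific, not statistical, choice: grouping by
session removes session and background effects from the error; pooling
keeps them in. Comparing the two diagonals shows how much error the
session-to-session variability contributes.

## Noise taxonomy and the bilinear decomposition

Reflectance errors are typically dominated by a few correlated components:

- **offset noise** — an additive constant per scan; contributes
  `σ² J` (all-ones matrix) to `Σ`, i.e. a flat covariance and near-1
  correlations;
- **multiplicative noise** — a per-scan gain error; contributes
  `σ² μμᵀ` with `μ` the mean spectrum;
- **shot noise** — channel noise with variance proportional to the signal;
  diagonal contribution `σ² diag(μ)`;
- **independent noise** — `σ² I`.

Because the correlated components are low-rank, an eigendecomposition of
`Σ` exposes them. `Σ` is a second-moment object, not a data table, so it is
decomposed *uncentered*; centering it first would distort the rank-1 offset
structure it exists to reveal. Two variance-fraction conventions are
reported: linear (`λ_i/Σλ`, the trace share) and squared (`λ_i²/Σλ²`, the
squared-Frobenius share). The comparison table puts the squared-convention
fractions of `Σ` beside the linear fractions of `Ê`'s PCA. When
`Σ = ÊᵀÊ/dof` the two share eigenvectors and the `Σ` column is exactly the
squared-renormalized `Ê` column — so for strongly correlated error both
columns approach 100% at component 1 and their difference ("gap", in
percentage points) isolates the independent-noise contribution. The
package's tests verify this identity to `1e-10` on random data and verify
that the gap is ~0 under purely correlated simulated error and grows
monotonically with the independent-noise share.

Component count for interpretation is deliberately left to the analyst: the
package reports the `log10`-eigenvalue curve and the cumulative variance,
the two curves whose joint elbow is the usual selection heuristic, and
imposes no automatic rule.

## The K index and its rank floor

The K redundancy index condenses a correlation matrix's eigenvalue
fractions `φ_j` to `K = Σ_j|φ_j − 1/p| / (2(p−1)/p)`: 0 when the spectrum
is flat (identity correlation), 1 when it is rank-1. Zero eigenvalues stay
in the sum, each contributing `1/p`. That matters because an error matrix
of `n` replicates over `p > n` channels has correlation rank at most `n`:
the flattest achievable spectrum puts `p/n` on `n` eigenvalues, whose K
closes to `(p − n)/(p − 1)` — the *imbedded correlation*, the floor below
which no `n × p` data matrix can fall. For 15 replicates this floor is
0.94 at 236 channels and 0.81 at 74 channels: with few replicates and many
channels, most of a reported K is geometry, not instrument behaviour, which
is why the package always reports the floor next to the index. Tables
round K to 2 decimals but full precision is kept internally (session-level
differences can sit in the third decimal).

## Outlier screening

Replicates are screened against a PCA model of mean-centered spectra
(centering only: reflectance channels share units, and autoscaling would
inflate quiet channels; autoscaling remains available as an option).
Hotelling's `T² = Σ_a t_a²/λ_a` measures distance within the model plane,
`Q` the squared residual off it. Limits at confidence `1 − α` use the
F-form `k(n−1)/(n−k)·F(k, n−k)` for `T²` and the Jackson–Mudholkar
approximation on the residual eigenvalues for `Q` (the specific Q
approximation is a choice; JM is the common chemometric default).
Per-wavelength contribution vectors use the loadings-weighted score
decomposition for `T²` — the convention that sums exactly to the statistic.
The default flagging rule requires exceedance of *both* limits, the
conservative criterion for discarding a replicate; removal is never
automatic in the pipeline, since the error analysis with and without a
flagged replicate are both informative.

One structural point the tests document: a single gross outlier included
in the PCA fit is a rank-1 perturbation that one component can absorb, so
`Q` alone may not see it. The reliable protocol — and the one validated in
the test suite — fits the model on reference replicates and screens new
spectra against it, which is also the natural monitoring workflow for a
deployed sensor.

## The synthetic generator

No public replicated-spectra corpus accompanies this methodology, so the
package ships a generator that emulates the study design it targets: two
instrument geometries (236 channels over 972–1701 nm; 74 channels over
1351–2559 nm), two background-timing modes (A: background before each
sample; B: background at session start, with whatever drift the intervening
activity causes), 3 sessions per mode, 15 repositioning replicates per
session — 90 rows per sample. The base spectrum is a smooth positive
band-over-baseline curve; per-sample gain/offset tweaks differentiate
samples. The generative model is

    x_ij = μ_j(1 + m_i) + o_i + u_k + b_k + σ_shot √μ_j η_ij + ε_ij

with all components Gaussian (the noise taxonomy names types, not
distributions; Gaussian is the neutral choice), `u_k` drawn once per
session and `b_k` once per mode-B session. Shot noise is implemented as
variance `∝ μ_j` on the reflectance scale — a detector-count analogy, a
modeling choice rather than radiometric physics. Its closed-form
counterpart `theoretical_ecm()` returns
`Σ = σ_off²J + σ_mult²μμᵀ + σ_shot²diag(μ) + σ_iid²I`, plus
`(σ_session² + w_B δ_background²)J` for groupings that pool sessions — the
many-sessions idealization; with `S` pooled sessions the sampled
between-session contribution is deflated by `(1 − 1/S)`, so exact-recovery
tests use per-session grouping where the closed form is exact.

Default noise levels (`σ_offset = 0.5 %R`, `σ_mult = 0.02`,
`σ_shot = 0.05`, `σ_iid = 0.05 %R`, `σ_session = 0.3 %R`,
`δ_background = 0.4 %R`) were chosen once so that the descriptive
statistics land in the qualitative ranges reported for miniaturized
instruments on granular foodstuffs (RSD of a few to a few tens of percent,
SNR of order 10), with correlated components dominating independent ones as
NIR reflectance errors do. No drift magnitude for the mode-B background
delay is established in the literature we model, so `δ_background` is a
free parameter of similar order to the session effect.

What passing tests show — and what they do not: the generator validates the
estimators (parameter recovery at Frobenius relative error < 15% at 2,000
replicates and < 5% at 20,000; diagonal shapes tracking `μ` and `μ²` under
shot and multiplicative noise; K monotone in the correlated-to-independent
ratio). It does not reproduce any physical instrument's absolute error
values: real spectra of real samples are required for that, and the
methodology is designed to be rerun on them via the CSV interface.

## Numerical and interface choices

- Loadings signs are fixed (largest-magnitude element positive) so repeated
  runs are bit-identical; `T²`, `Q` and all variance fractions are invariant
  to this arbitrary sign.
- Eigenvalues below `1e-12` of the largest are treated as exact zeros in
  decompositions, so rank-deficient spectra truncate cleanly.
- The CSV dialect is one header row — five metadata columns
  (`sample_id, session_id, background_mode, replicate_index,
  instrument_id`), then one numeric column per wavelength labeled in nm —
  one spectrum per row. Values outside [0, 100] %R warn but are kept (real
  detectors clip and overshoot); missing values are rejected at validation,
  as no imputation step belongs in an error analysis.
- Reported problem sizes in the test suite (up to 20,000 simulated
  replicates for covariance recovery, 500 for limit calibration, 200 random
  matrices for the K floor) were chosen as the smallest sizes at which the
  Monte-Carlo error is comfortably inside each stated tolerance.

## Limitations

Beyond PCA-based decomposition, no maximum-likelihood or shrinkage ECM
estimation is provided; the mean is always arithmetic (no robust centers);
there is no preprocessing (SNV, MSC, derivatives) because the object of
study is the raw-data error itself; and vendor file formats are out of
scope — export to CSV first.
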