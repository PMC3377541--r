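# postvar

Occupational exposure variability is commonly summarized by the variance
components of a three-level random-effects model fitted to minute-level
posture recordings (for example right upper-arm elevation measured over full
working shifts):

```
y_ijk = mu + a_i + b_j(i) + e_k(ij)
```

where `a_i ~ N(0, sigma2_BS)` is the effect of subject `i`, `b_j(i) ~ N(0,
sigma2_BD)` the effect of day `j` within subject, and `e_k(ij)` the
minute-to-minute error with variance `sigma2_WD`. These components — between
subjects, between days, within day — feed power calculations, measurement
strategy design and studies of exposure variation in its own right. But real
posture series are strongly autocorrelated within a day (lag-1 minute
correlations above 0.5 are typical), and when exposure is sampled in a few
long contiguous blocks rather than spread across the day, the standard
estimators become biased: the ordinary sample variance of `n` autocorrelated
observations has expectation

```
E[s^2] = sigma2 * ( 1 - 2/(n(n-1)) * sum_{k=1}^{n-1} (n-k) rho(k) )
```

which is below `sigma2` for positive `rho`, so the within-day component is
under-estimated and the deficit reappears as a positive bias in the
between-days component.

`postvar` is a toolkit for quantifying exactly this: it generates synthetic
balanced "parent" data sets with calibrated hierarchical structure and
within-day autocorrelation (a mixture of two AR(1) processes), enumerates
block sampling strategies (number of subjects `n_s`, total minutes per
subject `t_tot`, days `n_d`, block size `t_b`, random or fixed-interval
block dispersion), and measures each strategy's accuracy (bias) and
precision (90% prediction intervals) for all three variance components by a
three-level block bootstrap: subjects resampled with replacement, days and
within-day minutes without replacement. Utilities for turning 1-Hz
inclinometer interval codes into minute-level exposure variables and for
standardizing ragged working days to a balanced 480-minute parent are
included, so the full pipeline from raw interval codes to a strategy
performance report is covered.

## Worked example

```r
library(postvar)

prof <- default_profile("car_mechanics_pct_gt90")
prof
#> Posture exposure profile 'pct_above_90' [% of time]
#>   mu = 4.7, var_bs = 3, var_bd = 4, var_wd = 164.7 (estimate scale)
#>   latent model variances: bs = 3, bd = 2.045, wd = 166.7
#>   ACF mixture: w = 0.395, phi1 = 0.867, phi2 = 0.311 (day length 480)
```

The profile describes the percentage of time car mechanics spend with the
arm elevated above 90 degrees: mean 4.7% of time, components 3.0 / 4.0 /
164.7 (%)², lag-1 within-day autocorrelation 0.52. The "latent" line shows
the de-biased model parameters actually used by the generator so that
standard estimators recover the stated values in expectation (see the
vignette).

```r
parent <- generate_parent(prof, n_subjects = 23, n_days = 4, day_length = 480, seed = 42)
estimate_varcomp(parent)
#> Balanced nested variance components ('pct_above_90'; 23 subjects x 4 days x 480 minutes)
#>   mu     = 4.84
#>   var_bs = 6.162
#>   var_bd = 3.334
#>   var_wd = 166

within_day_acf(parent)
#> Mean within-day sample ACF over 92 day series:
#>      1      2      3      4      5     10
#> 0.5216 0.3413 0.2582 0.2164 0.1825 0.0772
```

One full synthetic parent gives estimates scattered around the profile
values (the between-subjects component is noisy with only 23 subjects), and
the day-averaged sample ACF matches the calibration targets. Now simulate a
sparse strategy — 10 subjects, 120 minutes each over 2 days, collected in
single 60-minute blocks:

```r
st <- sampling_strategy(10, 120, 2, 60, "random")
run_strategy(parent, st, n_reps = 500, seed = 1)
#> Bootstrap result ('pct_above_90', 500 reps, seed 1): n_s=10 t_tot=120 n_d=2 t_b=60 random
#>   bs  bias +0.975  90% PI [-6.16, 14.8]  (truth 6.16)
#>   bd  bias +13.1  90% PI [1.5, 29.5]  (truth 3.33)
#>   wd  bias -12  90% PI [-27.1, 3.01]  (truth 166)
```

The signature pattern of block sampling under autocorrelation: the
within-day component is biased down by about 12 (%)², the between-days
component up by a similar amount, and the prediction intervals are wide
relative to the truth. The analytic deflation factor explains the
within-day bias directly:

```r
expected_block_variance_factor(60, prof)
#> [1] 0.915
```

i.e. a single 60-minute block is expected to capture only ~91.5% of the
within-day variance. With `t_b = 1` (minutes spread over the whole day) the
bias essentially vanishes; `run_grid()` crosses a whole
`enumerate_strategies()` grid with several exposure variables and writes a
tidy report (`write_report_csv()`).

A thin command-line front end over the same functions is available at
`inst/cli/postvar.R` (`calibrate`, `generate`, `estimate`, `simulate`,
`report` subcommands).

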