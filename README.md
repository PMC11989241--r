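# actihurst

Digital mental biomarkers from actigraphy: variational Hurst-exponent
estimation, windowed complexity profiling with bipolar-disorder episode
indexing, mood-state probabilities from the complexity density, and
stochastic extrapolation of the complexity trajectory.

## The problem

Mood episodes in bipolar disorder are today rated with subjective clinical
scales. Wrist-worn accelerometers record rest–activity behaviour
continuously and objectively, and the *complexity* of those recordings
carries diagnostic signal: erratic, anti-persistent movement accompanies
mania, while long-memory, persistent movement accompanies depression.
actihurst operationalizes this as a pipeline for clinicians' analysts and
methods researchers working with actigraphy:

1. **Microscale → mesoscale.** Each 120-minute window of each acceleration
   axis is reduced to its Hurst exponent \(H \in (0,1)\), estimated by a
   variational scaling principle: the dyadic midpoint variations
   \(\Delta_k = \sum_i |x_i - \tfrac12(x_{i-1}+x_{i+1})|\) of the window's
   cumulated path are matched by least squares to the power law
   \(a\,N_k\,\tau_k^{\,2-h}\) across resolution levels \(k\). The fitted
   exponent equals the fractal dimension of the series' graph
   (\(\mathrm{fd} = 2 - H\)).
2. **Episode indexing.** \(H < 1/3\) mania, \([1/3,1/2)\) mild mania,
   \([1/2,2/3)\) stable (Wiener-like), \(\ge 2/3\) depression.
3. **Mood states.** A kernel density of the windowed exponents is cut at
   its inflection points \(\{x_i : \mathrm{PDF}''(x_i) = 0\}\); each
   interval's probability is \(\int_{x_i}^{x_{i+1}} \mathrm{PDF}\), and the
   argmax is the *likely observable* episode.
4. **Extrapolation.** A library of fractional-Gaussian-noise scenarios over
   a grid of Hurst parameters is matched to the observed trajectory by the
   \(L^2\) distance between Hurst densities; the best-matching scenario
   continues the trajectory, and the sign of a monotone Hermite
   interpolant's derivative reads the mood trend (falling H → manic states
   expected, rising H → depressive states expected).

Because no patient recording is publicly deposited, the package ships a
synthetic actigraphy generator (`synth_actigraphy()`) that reproduces the
study conditions: 16 depression / 7 mania / 8 stable windows of 120
one-minute epochs, three axes, per-axis jitter, tri-modal complexity
density.

## Worked example

```r
library(actihurst)

# a 62-hour synthetic recording: 16 depression / 7 mania / 8 stable episodes
stream <- synth_actigraphy(seed = 42)
profile <- profile_actigraphy(stream$data)
print(profile[1:4, c("window_index", "h_x", "h_y", "h_z", "h_mean", "label_mean")],
      digits = 3)
#> # A tibble: 4 × 6
#>   window_index   h_x   h_y   h_z h_mean label_mean
#>          <int> <dbl> <dbl> <dbl>  <dbl> <chr>
#> 1            1 0.790 0.727 0.990  0.836 depression
#> 2            2 0.757 0.980 0.844  0.861 depression
#> 3            3 0.638 0.850 0.809  0.765 depression
#> 4            4 0.862 0.789 0.989  0.880 depression
```

Per window: one Hurst exponent per axis, their mean, and the episode label.
The first windows were generated as depression (true \(H = 0.9\)); the
estimates near 0.8–0.9 index them correctly.

```r
density <- estimate_density(profile$h_mean)
states <- mood_state_probabilities(density)
states
#> <mood_states> 5 states, tail mass 0.088
#>   state lower upper midpoint probability label      extremum
#> 1     1 0.139 0.263    0.201       0.138 mania      meta_stable
#> 2     2 0.263 0.471    0.367       0.102 mania      stable
#> 3     3 0.471 0.603    0.537       0.168 stable     meta_stable
#> 4     4 0.603 0.790    0.697       0.145 depression stable
#> 5     5 0.790 0.943    0.866       0.360 depression meta_stable
#> likely observable: state 5 (depression), probability 0.360
```

The tri-modal density yields six inflection points, hence five states; the
depression pocket holds the largest probability mass (0.36), i.e. sparse
clinical observation of this stream would most likely catch a depressive
episode — manic windows, though present, are the less observable state.

```r
observed <- profile$h_mean[1:20]
library_fgn <- build_library(n_scenarios = 50, length = 32 * 120,
                             variance = var(observed), seed = 7)
forecast <- extrapolate(observed, library_fgn, horizon = 10)
forecast
#> <hurst_forecast> 20 observed + 10 extrapolated windows
#>   selected scenario 45 (h = 0.875), L^2 distance 0.7668
```

The first 20 windows are depression-dominated, and density matching selects
a persistent scenario (\(h = 0.875\)) to continue the trajectory.
`mood_trend(forecast$extended)` then reads the expected mood direction off
each segment, and `autoplot()` methods draw the profile, density and
forecast.

A shell wrapper with `synth | hurst | profile | episodes | forecast | run`
subcommands lives at `inst/cli/dmb.R`; `run_pipeline()` chains all stages
and writes `profile.tsv`, `states.json`, `forecast.json` and a run log.

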