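# ramanmcr

Constrained multivariate curve resolution for time-resolved Raman
line-focus imaging of solid-state dehydration.

## What problem this solves, and for whom

Pharmaceutical hydrates dehydrate through short-lived **metastable
intermediates** whose spectra never appear pure: every spectrum acquired
while a particle converts is a mixture of the coexisting solid-state forms.
Line-focus Raman microscopy records hundreds of spectra along a laser line
(220 positions over 1.8 mm) at each time point of an isothermal hold, giving
a (time x position x wavenumber) hyperspectral cube — but extracting the
hidden forms from that cube is a chemometrics problem. This package is for
solid-state spectroscopists and chemometricians who need that analysis chain
as tested, scriptable R:

* a **ground-truthed synthetic generator** for isothermal dehydration
  line scans (pseudo-Voigt band synthesis, sequential first-order kinetics
  with defect heterogeneity, Poisson-Gaussian detector noise), with
  theophylline-like (`TP4`) and nitrofurantoin-like (`NF4`) presets;
* **stable-form residual maps** that isolate metastable dynamics by
  NNLS-subtracting the known hydrate/anhydrate spectra;
* **library-constrained MCR-ALS** resolving the bilinear model
  `D = C S + E` under non-negativity, closure (row sums of `C` equal 1),
  unimodality of concentration-time profiles, and equality constraints
  pinning the known library rows (`NA` rows are resolved);
* **per-pixel NNLS unmixing** of full line scans and 2-D area maps into
  chemical concentration maps and metastable-only area plots;
* a reproducible **simulate → resolve → map** pipeline with CSV/JSON
  archives and a thin CLI (`inst/scripts/ramanmcr-cli.R`).

Everything user-facing speaks tibbles: fitted objects have `tidy()` /
`glance()` methods and `autoplot()` figures.

## The model

Measured spectra are non-negative bilinear mixtures, `D = C S + E`. MCR-ALS
alternates per-observation non-negative least squares for `C` (then closure
and unimodal projection along time) with per-channel NNLS updates of the
*unknown* rows of `S` (stable-form rows stay bit-identical), until the
relative change in lack of fit,

    LoF = 100 * sqrt( sum((D - C S)^2) / sum(D^2) )   [%],

falls below `tol` (default `1e-6`). Fit quality is also reported as the
averaged relative residual `100 * mean|D - C S| / mean|D|`. Rank is chosen
by the LoF elbow over truncated-SVD models; unknown rows are initialized by
SIMPLISMA-style purity picks on the stable-subtracted residuals.

## Worked example

```r
library(ramanmcr)

sim  <- simulate_scenario(default_scenario("TP4"), seed = 42)   # 46 x 220 x 976 cube
best <- select_best_position(snr_per_position(sim$scan, t = 1)) # -> 58
trace <- extract_trace(sim$scan, best)

estimate_rank(trace, k_max = 6)
#> <rank_selection> k = 4
#> # A tibble: 6 × 3
#>       k   lof improvement
#>   <int> <dbl>       <dbl>
#> 1     1 33.2      NA
#> 2     2 11.7       0.648
#> 3     3  3.82      0.672
#> 4     4  2.29      0.401
#> 5     5  2.24      0.0229
#> 6     6  2.19      0.0222
```

Four components: adding a fifth would improve the misfit by only 2 % — the
elbow sits at the generator's true component count (noise floor ~2.3 %).

```r
lib <- mark_unknown(sim$library, c("TP MS1", "TP MS2"))
lib
#> <spectral_library> 4 components x 976 channels (350-2300 cm^-1)
#>   TP MH     [known]
#>   TP MS1    [unknown]
#>   TP MS2    [unknown]
#>   TP AH II  [known]

fit <- mcr_als(trace, lib)
fit
#> <mcr_fit> 46 observations x 4 components
#>   LoF 2.35854% after 104 iterations (converged)
#>   averaged relative residual 4.87885%
```

The stable monohydrate and anhydrate spectra were held fixed while the two
`NA` rows converged to the metastable intermediates (at this noise level the
resolved spectra match the generator's hidden truth with cosine ≥ 0.996; on
noiseless data the averaged relative residual drops below 0.005 %). Then map
the whole line and plot:

```r
maps <- unmix_scan(sim$scan, resolved_library(fit))   # per-pixel NNLS
autoplot(maps)                                        # position-time chemical maps
plot_area_series(metastable_area_plot(maps, c("TP MS1", "TP MS2")))
glance(fit)
#> # A tibble: 1 × 6
#>   n_components n_unknown   lof avg_rel_residual iterations converged
#>          <int>     <int> <dbl>            <dbl>      <dbl> <lgl>
#> 1            4         2  2.36             4.88        104 TRUE
```

The same flow runs from a shell:

```sh
Rscript inst/scripts/ramanmcr-cli.R simulate --scenario TP4 --seed 42 --out run/
Rscript inst/scripts/ramanmcr-cli.R resolve  --data run/ --out run/resolve/
Rscript inst/scripts/ramanmcr-cli.R map      --data run/ \
        --resolved run/resolve/resolved_library.csv --out run/maps/
```

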