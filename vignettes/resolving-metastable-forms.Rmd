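---
title: "Resolving metastable solid-state forms from Raman line-scan data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving metastable solid-state forms from Raman line-scan data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ramanmcr)
```

## The problem

When a crystalline monohydrate is heated, lattice water leaves and the solid
passes through one or more short-lived metastable forms before settling into
its stable anhydrate. Those intermediates matter — they differ in solubility
and stability from both endpoints — but they never appear pure: every
measured spectrum is a mixture of whatever forms coexist at that moment and
place in the particle. A line-focus Raman microscope mitigates the time
problem by acquiring hundreds of spectra simultaneously along a laser line
(220 positions over 1.8 mm here) at each time point of an isothermal hold,
yielding a (time x position x wavenumber) hyperspectral cube.

`ramanmcr` implements the chemometric side of that experiment: a
ground-truthed synthetic generator standing in for the microscope, and the
analysis chain — stable-form residual mapping, library-constrained
multivariate curve resolution by alternating least squares (MCR-ALS), and
per-pixel non-negative least-squares (NNLS) unmixing into chemical maps.
Because the generator knows its own concentration fields and spectra, every
stage can be validated by parameter recovery instead of by eye.

## The bilinear model and its constraints

Each observed spectrum is modelled as a non-negative mixture:

$$D = C\,S + E,$$

with $D$ the (observations x channels) data, $C$ the (observations x $k$)
concentration profiles, $S$ the ($k$ x channels) component spectra, and $E$
noise. MCR-ALS alternates least-squares updates of $C$ and $S$ under the
constraint set that makes the factorization chemically meaningful for
dehydration data:

* **non-negativity** of both $C$ and $S$;
* **closure** — the fractions at each observation sum to 1 (the solid is
  always some mixture of the $k$ forms);
* **unimodality** of concentration-time profiles — a transient intermediate
  grows, peaks once and decays;
* **known-species equality** — the stable hydrate and anhydrate spectra are
  measured independently and pinned; only the unknown (metastable) rows of
  $S$ are updated. Unknown rows are marked `NA` in the input library.

Progress is tracked by the lack of fit,
$\mathrm{LoF} = 100\sqrt{\sum (D - CS)^2 / \sum D^2}$, and the final quality
by the averaged relative residual $100\,\overline{|D - CS|}/\overline{|D|}$.
The averaging convention for the residual is this package's definition; other
conventions exist, so the number should be read together with its formula.

### Where each step lives

| stage | function | notes |
|---|---|---|
| trace selection | `snr_per_position()`, `select_best_position()` | profile resolution uses the single best lateral point |
| metastable isolation | `residual_map()` | NNLS subtraction of stable forms |
| rank selection | `estimate_rank()` | LoF of truncated SVD models, elbow rule |
| initialization | `initialize_unknowns()` | SIMPLISMA-style picks on stable-subtracted residuals |
| resolution | `mcr_als()` | the constrained ALS itself |
| mapping | `unmix_scan()`, `unmix_area_map()` | per-pixel NNLS with the resolved library |

## The synthetic generator

The generator emulates two isothermal dehydration experiments:

* **TP4** — a theophylline-like cascade MH → MS1 → MS2 → AH II at 50 °C,
  46 time points over 90 min. The anhydrate carries its carbonyl doublet at
  1690/1730 cm⁻¹; the two metastables differ near 1150, 1230 and 1750 cm⁻¹.
* **NF4** — a nitrofurantoin-like cascade MH II → MH I → AH α → AH β at
  120 °C; the monohydrates differ at the 1615 cm⁻¹ C=N band, the anhydrates
  across 950–1000, 1200–1300, 1310–1400 and 1550–1650 cm⁻¹.

Component spectra are sums of pseudo-Voigt bands on a shared 350–2300 cm⁻¹
axis (2 cm⁻¹ step, 976 channels) with a common backbone band set per
compound, so the forms are as strongly overlapped as real polymorph spectra.
Nothing is synthesized above 2100 cm⁻¹, which leaves the top of the axis as a
signal-free window for noise estimation.

**Kinetics.** No rate law is established for these cascades; the generator's
default is consecutive first-order steps, optionally Avrami-modified
(hazard $n k^n t^{n-1}$, $n \ge 1$) for induction behaviour, because this is
the simplest model that reproduces the observed phenomenology: a monotone
decaying hydrate, a monotone growing anhydrate, and strictly unimodal
intermediates. Defaults are $k = (0.08, 0.05, 0.03)\,\mathrm{min^{-1}}$ for
TP4 and $(0.10, 0.055, 0.035)$ for NF4, chosen so the intermediates peak at
30–50 % fraction within the 90 min window — the regime in which overlapping
metastables are actually hard to resolve. The first $m-1$ species are
integrated with `deSolve::lsoda` at `rtol = 1e-12`; the terminal species is
$1 - \sum$ others, so closure holds exactly.

**Spatial heterogeneity.** Real particles convert faster at defects. The
rate-multiplier field over the line is piecewise constant: defaults place a
x2.0 defect at 0.45–0.60 mm and a x1.6 defect at 1.20–1.35 mm of the 1.8 mm
line. Because the multiplier field is piecewise constant, positions sharing a
multiplier share one ODE solve.

**Noise.** Scaled-Poisson shot noise (`shot_gain` 1e4 counts at unit
intensity) plus additive Gaussian read noise (sd 2e-3) — about 40 dB SNR at a
unit-height band, typical for a well-exposed CCD spectrum. A slowly varying
baseline is available but off by default. Every draw takes an explicit seed
and restores the global RNG state.

**What the generator does not emulate:** optics (depolarization, laser-line
inhomogeneity), cosmic rays, fluorescence backgrounds, wavenumber
calibration drift, particle morphology, or any coupling between spectra and
temperature. Passing recovery tests here shows the *algorithms* are correct
under the bilinear model with realistic overlap, heterogeneity and detector
noise; it does not certify performance against instrument artefacts the
generator omits.

## Numerical and design choices

**Analysis trace.** Concentration/spectral profiles are resolved from the
single lateral position with the highest SNR, defined as (peak signal in a
band window) / (robust noise from a signal-free window). The noise estimate
is `mad(diff(s))/sqrt(2)` in the signal-free window — insensitive to flat
offsets and slow baselines; ties in the argmax break toward the lowest
index. Default windows split the axis at its top decile (2105 cm⁻¹ on the
default axis).

**Residual maps.** The stable-form contribution is removed per spectrum by a
*simultaneous* NNLS fit of all stable forms (not plain projection), so stable
contributions cannot go negative; the residual intensity is the Euclidean
norm of what is left (integrated absolute intensity is available). Whether
the subtraction should be simultaneous or sequential is an open question in
the source workflow; simultaneous is adopted because it is order-free.

**Rank selection.** `estimate_rank()` computes LoF for truncated-SVD models
$k = 1..k_\max$ and selects the smallest $k$ for which adding one more
component improves LoF by less than 25 % (relative) — the elbow — with an
absolute floor (LoF ≤ 1e-6 %) short-circuiting exactly low-rank data, and
ties resolved toward the smaller $k$ (parsimony).

**Initialization.** Unknown rows are seeded deterministically: stable forms
are NNLS-subtracted from every observation and the most mutually dissimilar
high-purity residual spectra are picked — purity `sd/(mean + 5 % offset)`,
later picks down-weighted by the Gram determinant against those already
chosen. The selection is invariant to observation order.

**ALS details.** The C-step solves per-observation NNLS against the current
$S$, applies closure, then projects the selected profiles onto the unimodal
cone, then re-applies closure — the re-closure keeps the returned row sums at
1 to 1e-9 even though the projection can perturb them (a near-identity
correction at convergence). The unimodal projection itself scores every
split into a non-decreasing prefix and non-increasing suffix, each side by
isotonic regression, and keeps the least-squares best; plateaus are allowed.
By default only the unknown (metastable) profiles are constrained
(`unimodal_components = "all"` extends it). The S-step updates only unknown
rows (per-channel NNLS on the known-subtracted residual), then renormalizes
each unknown row to unit maximum with the compensating rescale absorbed into
its $C$ column — fixing the bilinear scale ambiguity, so "concentration" is
relative, as in the arbitrary-unit maps this workflow produces. Convergence
is declared when the relative LoF change drops below `tol` (default 1e-6)
within `max_iter` (default 200); non-convergence returns the result with
`converged = FALSE` and a warning, never silently. The row-wise NNLS solver
first tries the vectorized unconstrained normal-equation solution and falls
back to Lawson–Hanson exactly for rows with negative coefficients — the
unconstrained optimum, when feasible, *is* the NNLS optimum.

**Mapping.** Full-line and area maps are pixel-separable NNLS solves.
Closure at the mapping stage is optional: on by default for concentration
profiles (fractions), off by default for raw area maps, since it is not
established whether published maps of this kind plot coefficients or closed
fractions — both are retained (`values` vs `raw`). Pixels whose total
coefficient falls below 1e-3 of the median total are flagged empty
(glass/background). Metastable-only area plots always unmix with the *full*
library so stable contributions are accounted for, then emit only the
metastable series.

**Degenerate inputs.** All-zero data matrices are rejected for LoF and rank
estimation; all-zero library columns are rejected by name in NNLS; empty
band tables render all-zero spectra; zero rates freeze the kinetics at the
initial composition.

## Problem sizes and verification

The test suite validates each stage against independent oracles: a
closed-form Bateman solution for consecutive first-order chains (2–4
species, 1e-8 agreement with the integrator), brute-force active-set
enumeration for NNLS (1000 random instances, 1e-8), an exhaustive
mode-search + hand-written PAVA oracle for the unimodal projection (vectors
up to length 12), and ground-truth recovery on the generator: noiseless
cubes invert to machine accuracy, and at 40 dB the 2-known/2-unknown
resolution recovers each hidden spectrum with cosine ≥ 0.99 and a pooled
concentration RMSE ≤ 0.02 across ten seeds per scenario. Fast unit tests run
on a reduced twin of the TP4 scenario (16 time points, 40 positions,
4 cm⁻¹ step); the recovery and rank-selection checks run at the full default
scenario sizes.

## Known limitations

* **Rotational ambiguity.** With two strongly overlapped unknowns, the
  constraint set does not pin the MS1/MS2 split uniquely at finite SNR: for
  some noise realizations the constrained least-squares optimum fits the
  data *better* than the ground truth while differing from it by a few
  percent in the concentration split. Per-seed concentration RMSE therefore
  occasionally exceeds its typical ~0.01 level (worst observed 0.029 at
  40 dB) even though the resolved spectra stay at cosine ≥ 0.996. This is a
  property of the factorization problem, not of the optimizer; fixing it
  would require extra information (hard kinetic modelling, multi-set
  analysis), both out of scope.
* ALS convergence on noiseless data is asymptotic: LoF keeps creeping below
  0.02 % without meeting the relative-change criterion within 200
  iterations; the averaged relative residual is nevertheless orders of
  magnitude under 0.1 %.
* The unimodality projection assumes the acquisition order is the kinetic
  order; permuted data must carry their `time_order`.
* Maximum-likelihood (noise-weighted) MCR, trilinear/multi-set models, and
  hard kinetic fitting inside the ALS are deliberately not implemented.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_scenario(default_scenario("TP4"), seed = 42)
best <- select_best_position(snr_per_position(sim$scan, t = 1))
trace <- extract_trace(sim$scan, best)

estimate_rank(trace, k_max = 6)$k          # 4
lib <- mark_unknown(sim$library, c("TP MS1", "TP MS2"))
fit <- mcr_als(trace, lib)
glance(fit)

maps <- unmix_scan(sim$scan, resolved_library(fit))
autoplot(maps)
plot_area_series(metastable_area_plot(maps, c("TP MS1", "TP MS2")))
```
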