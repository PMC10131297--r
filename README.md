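# feedbacksim

Simulating component density feedback in age-structured populations and
measuring what census-level logistic-growth models recover.

## The problem

Ecologists infer density dependence from abundance time series by
regressing the per-capita growth rate $r_t = \log_e(N_{t+1}/N_t)$ on
abundance — the *ensemble* density feedback.  But density dependence in
real populations acts on individual vital rates (a *component* feedback,
e.g. compensatory survival), and the two signals can decouple when
populations experience catastrophic mortality, harvest, or a fluctuating
carrying capacity.  `feedbacksim` provides a controlled environment to
study that decoupling: it synthesizes life histories for 21 long-lived
vertebrate archetypes (body masses 1.7–2786 kg, generation lengths
2.3–20 y), projects them as stochastic prebreeding Leslie matrices with a
known survival feedback

$$S_{red}(\Sigma n) = \frac{a}{1 + (\Sigma n/b)^c},$$

calibrated so each population is stable at its carrying capacity
$K = D \times 250{,}000\ \mathrm{km}^2$, and then asks four
phenomenological models of the census — random walk, exponential growth,
Ricker ($r \sim N_t$) and Gompertz ($r \sim \ln N_t$) — how much evidence
for, and strength of, ensemble feedback survives nine demographic
scenarios (stable; catastrophes; a 90% mortality pulse; weak and strong
harvest; constant-variance, increasing-variance and declining carrying
capacity; and a feedback-free null stabilised by density-independent
mortality alone).  Evidence is the summed AICc weight of the Ricker and
Gompertz models, Pr(density feedback); strength is the negated Gompertz
slope; nonstationarity is indexed by mean/variance of return times to the
series mean.  Audiences: population ecologists studying density-feedback
inference, and anyone needing a fast, reproducible age-structured
simulation bench with known feedback.

The same model-fitting machinery applies to real censuses via
`fit_census()` (CSV with columns `year,N`).

## Worked example

Calibrate the Tasmanian-devil-sized archetype (SH), simulate one series
under the stable-with-catastrophes scenario, and fit the four models:

```r
library(feedbacksim)

tab <- load_species_table()
sh  <- tab[tab$abbr == "SH", ]
lh  <- synthesize_life_history(sh)
lh
#> Life history for SH (mass 6.1 kg, GL target 3.1 y)
#>   omega = 8, maturity = 1, lambda1 = 1.2533, G = 3.100 y
#>   D = 2.374 km^-2, A = 250000 km^2, K = 5.936e+05 individuals

L   <- build_leslie(lh)
cal <- calibrate_feedback(lh, L, rng_seed = 1)
cal$params
#> Survival feedback S_red = 1 / (1 + (n/915061)^2), applies to survival

series <- project_series(lh, L, cal$params, scenario_preset("ii"),
                         rng_seed = 42)
fit_phenomenological(series)
#> Phenomenological model comparison over 120 transitions:
#>   random_walk  k=1  AICc= -161.396  wAICc=0.0001  beta=+0
#>   exponential  k=2  AICc= -159.351  wAICc=0.0000  beta=+0
#>   ricker       k=3  AICc= -178.875  wAICc=0.6932  beta=-6.9163e-07
#>   gompertz     k=3  AICc= -177.244  wAICc=0.3066  beta=-0.30451
#>   Pr(density feedback) = 0.9998, strength (-beta_Gompertz) = +0.30451

component_strength(series)
#> [1] 0.2722
stationarity_index(return_times(series$N))
#> Return times: M = 25, mean = 3.584, var = 23.12, index = 0.155 (highly nonstationary)
```

Reading the output: the synthesized life history hits its 3.1-year
generation-length target with pre-feedback growth $\lambda_1 = 1.25$; the
calibrated half-saturation abundance $b$ places the stochastic
equilibrium at $K \approx 594{,}000$ individuals.  Over 120 census years
the two feedback models carry essentially all the AICc weight
(Pr(density feedback) ≈ 1.00): the known component feedback (realised
strength 0.27, the mean survival reduction $1 - S_{red}$) is clearly
visible in the census as an ensemble strength of 0.30.  The return-time
index below 1 reflects the catastrophe-driven nonstationarity of the
series.

Whole-study runs go through `run_pipeline()`:

```r
run <- run_pipeline(run_config(species = c("SH", "VU", "DM"),
                               scenarios = c("ii", "ix"),
                               n_reps = 100, base_seed = 1))
run$report$scenario_table
```

which calibrates every requested species, simulates the scenarios, fits
every series, and returns per-series results, species-level percentile
summaries, bootstrapped component-ensemble Spearman correlations and
exponential-plateau fits.

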