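# spikepeel

Calcium-imaging analysis of epileptiform neuronal recruitment in
neuron–astrocyte co-cultures, as an end-to-end, tested R pipeline.

When a culture is challenged with 4-aminopyridine (4-AP), two things can
change: neurons that were already firing fire faster, and neurons that
were silent are *recruited*.  Distinguishing the two requires inferring
spikes from population calcium movies and collapsing them to per-culture
read-outs — the firing rate of individual neurons, the number and
fraction of active neurons (≥ 1 inferred spike), and the global firing
rate (total spikes per unit time in the culture) — before comparing
groups.  `spikepeel` implements that chain for experimentalists and
analysts working with widefield calcium imaging of dissociated cultures:

* **ROI extraction** — Otsu threshold on the time-averaged movie,
  8-connected components, area filter, spatial-mean traces.
* **Trace conditioning** — moving-average smoothing; per-50-s-block
  reference points at the 10th fluorescence percentile; cubic-spline
  baseline F₀; normalization to 100 × (F − F₀)/F₀.
* **Trace classification** — AdaBoost over decision stumps on seven
  interpretable features, with an auditable refinement loop.
* **Peeling spike inference** — greedy detect-and-subtract with a
  single-exponential, non-saturating transient kernel
  k(j) = A·e^(−j/(τf)), A = 1 %ΔF/F, τ = 3 s, shared by all neurons.
  Detection uses the least-squares event amplitude with a local-DC
  nuisance term, which makes it robust to residual baseline error.
* **Metrics and statistics** — per-culture summaries as the statistical
  units; two-factor (genotype × treatment) Type II ANOVA with
  Bonferroni post hoc; Pearson 2×2 chi-square for incidence counts.
* **Synthetic data** — a fully seeded generator (Poisson spike trains,
  rendered traces and movies, artifact traces, multi-culture group
  designs) emulating the basal → 4-AP protocol, so the entire pipeline
  is testable without recordings.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects
have `tidy()`/`glance()` methods and results have plot functions
(`plot_traces()`, `plot_spike_raster()`, `plot_summary_points()`).

## Worked example

Simulate one culture, condition the traces, peel spikes and summarize:

```r
library(spikepeel)

cfg  <- sim_config(n_neurons = 40, duration_s = 300, seed = 7)
st   <- simulate_spike_trains(cfg, "basal")
norm <- render_traces(st, cfg) |> process_traces()
spk  <- infer_spikes(norm, cfg$transient)
summarize_experiment(spk, 300, culture_id = 1)
#> # A tibble: 1 × 7
#>   culture_id window n_neurons mean_firing_rate_hz n_active fraction_active
#>        <dbl> <chr>      <int>               <dbl>    <int>           <dbl>
#> 1          1 basal         40               0.022       20             0.5
```

Half the simulated population is silent at baseline, and peeling finds
exactly the 20 truly active neurons; the mean rate (0.022 Hz) estimates
the generating 0.05 Hz averaged over active *and* silent neurons.

A full recruitment experiment — 10/10/5/5 cultures of 200 neurons with
recruitment probability 0.4 (wt) vs 0 (ko) under 4-AP — and its
genotype × treatment ANOVA on the active-neuron count:

```r
smry <- run_recruitment_experiment(recruitment_design(),
                                   sim_config(seed = 7))
av <- two_way_anova(smry, "n_active", "genotype", "treatment")
tidy(av)
#> # A tibble: 3 × 6
#>   effect      sum_sq    df df_resid statistic  p.value
#>   <chr>        <dbl> <int>    <int>     <dbl>    <dbl>
#> 1 genotype     1673.     1       26      372. 6.25e-17
#> 2 treatment    3345.     1       26      745. 1.16e-20
#> 3 interaction  3345.     1       26      745. 1.16e-20

bonferroni_posthoc(av, list(c("wt:basal", "wt:fourap"),
                            c("ko:basal", "ko:fourap")))
#> # A tibble: 2 × 7
#>   cell_1   cell_2    estimate statistic    df  p.value adj.p.value
#>   <chr>    <chr>        <dbl>     <dbl> <dbl>    <dbl>       <dbl>
#> 1 wt:basal wt:fourap    -44.8     -38.6    26 1.75e-24    3.49e-24
#> 2 ko:basal ko:fourap      0         0      26 1   e+ 0    1   e+ 0
```

The interaction is the recruitment signature: 4-AP adds ~45 active
neurons per wt culture (silent pool of 100 × recruitment 0.4, plus
sampling noise) and none in ko, so the post hoc contrast is significant
only within wt.

See `vignettes/recruitment-pipeline.Rmd` for the model, parameter and
design rationale.

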