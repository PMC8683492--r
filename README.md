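# lettercue

Design, simulation and analysis tools for **partial-report letter
recognition with spatial pre-cues** — the psychophysical paradigm used to
ask how exogenous (reflexive) and endogenous (voluntary) covert attention
shape the encoding of letters within a string, a process fundamental to
reading.

On each trial a string of six consonants is flashed around fixation, a
post-cue then marks one position, and the observer reports the letter that
was there from 12 alternatives (the 6 shown letters plus the 6 unused
letters of the alphabet `B F H K L N P T V X Y Z`). Before the string, a
pre-cue — peripheral and uninformative (exogenous) or central and
informative (endogenous) — directs attention left or right at a variable
cue-target onset asynchrony (CTOA). The package provides:

* **Balanced factorial designs**: 6 positions × CTOAs (50/100/300 ms
  exogenous, 100/300/600 ms endogenous) × validity (valid/invalid/neutral
  exogenous, valid/neutral endogenous) × 10 trials per cell → 540 + 360
  trials per subject, plus the stimulus geometry (0.58° spacing, per-side
  eccentricities 0.58°/1.16°/1.74°, 3.98° string extent).
* **A synthetic cohort generator**: a parametric observer with W-shaped
  positional sensitivity, validity × CTOA attention gains (transient
  exogenous, ramping endogenous), and a two-branch error mixture
  separating position confusions (transpositions) from absent-letter
  reports (misidentifications).
* **M-AFC signal detection**: proportion correct ↔ d′ for an unbiased
  observer choosing among M alternatives,
  `P(correct) = ∫ φ(t − d′) Φ(t)^{M−1} dt`, by deterministic quadrature
  with bracketed inversion, and the 1/(2n) floor/ceiling correction.
* **Cue-effect statistics**: benefit d′(valid) − d′(neutral), cost
  d′(neutral) − d′(invalid), total effect d′(valid) − d′(invalid);
  serial-position, hemifield and crowding ({2,5} vs {1,6}) summaries.
* **Error analysis**: a four-way response taxonomy and the
  probit-linearised Δerror = Φ⁻¹(err_neutral) − Φ⁻¹(err_valid).
* **Reliability**: odd/even split-half d′ with Spearman-Brown correction,
  paired contrasts, Bonferroni-adjusted position-wise families.

## Worked example

```r
library(lettercue)

specs <- list(design_spec("exogenous"), design_spec("endogenous"))
trials <- simulate_experiment(observer_params(), specs,
                              n_subjects = 28, seed = 1)
res <- run_analyze(trials)

res$crowding_benefit
#> # A tibble: 4 × 3
#>   cue_type   crowding  mean_benefit
#>   <chr>      <chr>            <dbl>
#> 1 endogenous crowded          0.628
#> 2 endogenous uncrowded        0.310
#> 3 exogenous  crowded          0.237
#> 4 exogenous  uncrowded        0.145
```

Cue benefits (d′ with a valid minus a neutral pre-cue, at each system's
peak CTOA: 50 ms exogenous, 600 ms endogenous) are about twice as large
at the crowded string positions (2 and 5, flanked on both sides) as at
the outermost positions (1 and 6) — attention helps most where crowding
hurts most. Aggregating the same per-subject records by CTOA instead
traces each system's time course:

```r
dplyr::summarise(dplyr::group_by(res$cue_effects, cue_type, ctoa_ms),
                 benefit = mean(benefit, na.rm = TRUE), .groups = "drop")
#> # A tibble: 6 × 3
#>   cue_type   ctoa_ms benefit
#>   <chr>        <dbl>   <dbl>
#> 1 endogenous     100  0.121
#> 2 endogenous     300  0.361
#> 3 endogenous     600  0.487
#> 4 exogenous       50  0.277
#> 5 exogenous      100  0.221
#> 6 exogenous      300  0.0148
```

The exogenous benefit peaks at the shortest cue-target interval and
decays; the endogenous benefit grows with the interval. `res$reliability`
holds split-half reliabilities (Spearman-Brown corrected), and
`res$delta_error` the linearised neutral-minus-valid error differences by
error type and position.

A thin command-line wrapper is installed at `inst/cli/lettercue.R`:

```sh
Rscript inst/cli/lettercue.R simulate --config cfg.yaml --out trials.csv
Rscript inst/cli/lettercue.R analyze  --trials trials.csv --out results/
Rscript inst/cli/lettercue.R validate --trials trials.csv
```

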