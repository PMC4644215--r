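# gibbsrasch

Bayesian inference for the (extended) marginal Rasch model **without data
augmentation**, for psychometricians and large-scale educational
measurement: item calibration, EAP ability estimation, test equating over
NEAT designs, and polytomous items with fixed integer scoring weights.

## The model and the sampler

The marginal Rasch model integrated over any ability density can be
written in manifest (Cressie–Holland / Tjur) form

    P(x | b, λ) = Π_i b_i^{x_i} · λ_{x+} / Σ_s γ_s(b) λ_s

with item easiness `b_i = exp(-δ_i)`, score parameters `λ_s`, sum score
`x+`, and `γ_s` the elementary symmetric function of order `s`.  The
posterior under power priors touches the data only through the item
totals, the score counts and the respondent count, and its normalizer is
*linear* in every single parameter — so each full conditional is an exact
**scaled Beta prime** distribution (`y = cv/(1+cv) ~ Beta(k, M−k)`), and a
Gibbs sweep needs no latent-variable imputation.  One iteration costs
`O(n²)` in the number of items and **nothing** in the number of
respondents, which is what makes the sampler suitable for surveys with
hundreds of thousands of examinees.  By the Dutch identity
`τ_s = λ_{s+1}/λ_s = E[exp(Θ) | X+ = s]`, so EAP ability estimates (and
their decomposed posterior variances) come directly from the λ draws.

Also included: monotone-τ (log-convex λ) constrained sampling via
double-truncated Beta prime draws, a matched-slope Metropolis step for
anchor items in non-equivalent-groups (NEAT) designs, a sampler for
nominal-response items with known integer weights (partial credit /
OPLM-type), two synthetic-data generators, and the replicated-chain
convergence and autocorrelation diagnostics.

## Worked example

```r
library(gibbsrasch)
set.seed(2024)
delta <- runif(12, -2, 2)                      # item difficulties
X <- simulate_latent_rasch(5000, delta)        # abilities ~ N(0,1)
stats <- sufficient_statistics(X)
stats
#> Rasch sufficient statistics: 5000 persons, 12 items
#> item totals: 1223 3253 1762 1695 2706 1621 2820 3283 1108 3914 1087 921
#> score counts: 92 256 457 635 738 745 664 511 405 249 154 69 25

draws <- gibbs_run(stats, config = chain_config(n_iter = 550,
                                                burn_in = 50, seed = 1))
draws
#> Gibbs draws for the extended marginal Rasch model
#>  items: 12  persons: 5000
#>  stored iterations: 500 (burn-in 50 of 550 total)
```

Item recovery (easiness is reported relative to the reference item, so
`b_1 = 1` by construction):

```r
head(data.frame(b_true = round(exp(-(delta - delta[1])), 3),
                b_hat  = round(colMeans(draws$b), 3),
                sd     = round(apply(draws$b, 2, sd), 3)), 5)
#>     b_true b_hat    sd
#> b_1  1.000 1.000 0.000
#> b_2  7.880 8.067 0.402
#> b_3  1.871 1.855 0.093
#> b_4  1.742 1.726 0.087
#> b_5  4.571 4.672 0.237
```

Ability on the `exp(θ)` scale per sum score — the EAP, its posterior
variance split into a parameter-uncertainty part (shrinks with more
respondents) and a finite-test-length part (shrinks with more items), and
approximate normal-scale summaries:

```r
round(head(ability_summary(draws), 4), 3)
#>   score eap_exp_theta var_parameter var_finite_test var_total     mu sigma2
#> 1     0         0.054             0           0.002     0.002 -3.141  0.439
#> 2     1         0.084             0           0.003     0.003 -2.660  0.360
#> 3     2         0.120             0           0.005     0.006 -2.281  0.324
#> 4     3         0.166             0           0.009     0.010 -1.945  0.298
```

(`eap_exp_theta` rises with the score, as it must; `mu`/`sigma2` are the
log-normal back-transform and are approximations.)  Model fit through the
item-rest regression, whose analytic form `b_i τ_r / (1 + b_i τ_r)` the
model supplies for free:

```r
item_rest_fit(X, draws)
#> Item-rest regression fit; per-item weighted max discrepancy:
#>  item_1  item_2  item_3  item_4  item_5  item_6  item_7  item_8 ...
#>  0.0032  0.0042  0.0031  0.0025  0.0028  0.0021  0.0032  0.0011 ...
```

All discrepancies are tiny here because the data were simulated from the
model; the test suite shows a guessing item breaking its
posterior-predictive band.

A command-line pipeline is available too:

```sh
Rscript -e 'quit(status = gibbsrasch::run_cli())' simulate \
    --persons 100000 --items 30 --seed 1 --output data.csv --truth truth.json
Rscript -e 'quit(status = gibbsrasch::run_cli())' fit \
    --input data.csv --output draws.csv --iters 550 --burnin 50 --seed 2
Rscript -e 'quit(status = gibbsrasch::run_cli())' summarize \
    --input draws.csv --output summary.csv
Rscript -e 'quit(status = gibbsrasch::run_cli())' diagnose \
    --input data.csv --draws draws.csv --output report.json
```

## Identification (read this before small-sample use)

The likelihood is invariant under `(b, λ) → (cb, λ_s/c^s)` and under a
common rescaling of λ.  `chain_config(identification = "rescale")`
(default) updates every parameter and renormalizes each sweep — the
fast-mixing scheme whose replicated chains converge within a few dozen
iterations with negligible autocorrelation beyond lag 1; its identified
draws approach the identified posterior as the sample grows, with an
`O(1/m)` gauge effect at tiny `m`.  `identification = "fixed"` holds
`b[ref] = 1`, `λ_0 = 1` fixed and targets the identified posterior
exactly but mixes slowly.  The methods vignette
(`vignettes/extended-rasch-gibbs.Rmd`) explains the trade-off in detail.

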