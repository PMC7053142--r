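# dropoutsim

Monte Carlo pipeline for a question trial statisticians face constantly:
when a longitudinal randomized trial with a **binary outcome** loses
subjects before the final visit, how much power and accuracy does the usual
**complete-case chi-squared test** give up compared with a
**random-intercept logistic mixed model (GLMM)** that uses the dropouts'
earlier visits?

The package simulates two-arm trials with repeated binary outcomes,
deletes final-visit responses under MCAR or MAR mechanisms at calibrated
per-arm rates, analyzes every replicate with both methods, and aggregates
the replicates into the standard simulation performance measures.

## The model in brief

Outcomes for subject *i* at visit *j* are Bernoulli with a shared latent
baseline probability drawn from a Beta distribution,

    p_i1 ~ Beta(a, b),   E[p_i1] = a/(a+b) = prevalence,
    corr(Y_ij, Y_ik)     = 1/(1+a+b)       = rho,

and the treatment arm's probability rises by delta = 0.05 per visit
(end-of-study risk difference 0.10; under the null it stays flat). MAR
dropout follows `logit Pr(missing) = g1 + g2*y_prev + g3*X` with g2 fixed
at +1.5 or -1.5 and intercepts solved so the expected per-arm rates hit
their targets. The two analyses are

* complete-case 2x2 table at the final visit: uncorrected Pearson
  chi-squared test and log-odds ratio `log(n11*n00 / (n10*n01))` with Wald
  interval;
* logistic GLMM `logit Pr(Y=1|b_i) = b1 + b2*X + b3*t + b4*X*t + b_i`,
  `b_i ~ N(0, s_b^2)`, fitted by restricted pseudo-likelihood (penalized
  quasi-likelihood with a profiled-REML inner step, written from scratch in
  this package), with the treatment effect at the final visit estimated by
  the contrast `b2 + 3*b4` and a Wald z test.

See `vignettes/simulation-design.Rmd` for the full account, including how
near-boundary Beta draws and PQL non-convergence are handled.

## Worked example

One scenario cell: prevalence 0.1, correlation 0.3, MAR dropout that
preferentially removes prior responders (g2 = +1.5) at 20% (control) /
40% (treatment), 200 replicates:

```r
library(dropoutsim)

cfg <- scenario_config(prevalence = 0.1, rho = 0.3, mechanism = "MAR1",
                       dropout_pattern = "unequal1", n_reps = 200, seed = 42)
res <- run_scenario(cfg)
summarize_scenario(res)
```

```
     dataset method mean_log_or relative_bias_pct power_pct coverage_pct model_se empirical_se
1   complete  chisq       0.828              0.00        80         96.5    0.303        0.302
2   complete   glmm       0.882              0.00        84         97.0    0.307        0.288
3 incomplete  chisq       0.869              4.93        66         98.0    0.377        0.384
4 incomplete   glmm       0.948              7.43        77         95.5    0.357        0.341
```

Reading the rows: on complete data the GLMM's subject-specific log-odds
ratio (0.88) sits above the marginal 2x2 estimate (0.83) — that is the
usual conditional-versus-marginal attenuation gap, not a bias. Dropout
costs the complete-case test 14 points of power (80 -> 66) but the GLMM
only 7 (84 -> 77), because dropouts still contribute their first two
visits to the mixed model. Relative bias is measured against each method's
own complete-data mean from the same seeds. The calibrated dropout model is
attached to the result:

```r
attr(res, "mar_model")
#> MAR dropout model: logit Pr(missing) = -1.5913 +1.5000 y_prev +0.9564 X
#>   targets: control 20%, treatment 40%
```

`full_scenario_grid()` builds all 80 cells of the full factorial design
(2 prevalences x 2 correlations x 2 hypotheses x 10 missingness settings),
`run_grid()` executes a grid and writes per-replicate results, summaries,
rendered tables and a run log, and `inst/cli/dropoutsim.R` is a small
command-line front end over the same functions. Scenario grids can be kept
in plain-text config files (`read_scenario_grid()`; see
`inst/extdata/example_scenarios.dcf`).

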