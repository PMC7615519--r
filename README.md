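# alphastream

Online error rate control for streams of hypothesis tests.

When p-values arrive one at a time — A/B tests shipped weekly, treatment
arms added to a platform trial over years, hypotheses tested against a
growing data repository — each decision must be made immediately, using only
the current p-value and the record of past rejections. Classical corrections
(Benjamini–Hochberg, Bonferroni over a known family) need all p-values at
once. `alphastream` implements the *generalized alpha-investing* family of
online procedures instead: a test level

```
α_t = f(R_1, …, R_{t−1}),    reject H_t  iff  P_t ≤ α_t
```

is emitted before each p-value is seen. Testing spends alpha-wealth,
rejections earn it back, and the ledger `W(t) = W(t−1) − φ_t + R_t·ψ_t`
stays non-negative, which keeps the false discovery rate
`FDR(T) = E[V(T)/(R(T)∨1)]` below a preset `α` at every time `T`
(for monotone rules, under independent nulls).

Implemented policies:

| policy | controls | key idea |
|---|---|---|
| `alpha_spending()` | FWER | Bonferroni-type, `α_t = α·γ_t` |
| `online_sidak()` | FWER | `α_t = 1 − (1−α)^{γ_t}`, dominates spending |
| `lord()`, `lordpp()` | FDR | rewards per rejection spread over future tests |
| `saffron()` | FDR | adaptive: candidates (`P ≤ λ`) never spend wealth |
| `addis()` | FDR | adaptive + discards conservative nulls (`P > η`) |
| `alpha_investing()` | FDR | monotone alpha-investing, `α_t = b_t/(1+b_t)` |
| `uncorrected()`, `bh_procedure()` | — | comparators (no control / offline BH) |

All policies share non-increasing spending sequences `{γ_t}` summing to one
(`spending_sequence()`: the default LORD schedule
`γ_t ∝ log(t∨2)/(t·e^{√log t})`, power laws `t^{−s}`, uniform), including
*bounded* variants that renormalize the first `M` weights for a known
testing horizon. A Gaussian simulation testbed (`sim_config()`,
`generate_stream()`, `run_experiment()`) and Monte-Carlo error-rate
estimators (`fdr_estimate()`, `power_estimate()`, `fdx_estimate()`, …)
reproduce the standard power/FDR experiments.

## Worked example: a platform trial

Seven treatment-versus-control p-values from the STAMPEDE prostate-cancer
platform trial are packaged as a fixture, in arrival order B, C, E, D, F, G,
H. Running bounded SAFFRON (horizon `M = 20`, `α = 0.05`, defaults
`w0 = α/2`, `λ = 0.5`, `γ_t ∝ t^{−1.6}` renormalized):

```r
library(alphastream)
st  <- stampede_fixture()
log <- run_stream(st$pval, saffron(alpha = 0.05, bound = 20), ids = st$id)
log
#> Decision log: 7 hypotheses, 2 rejection(s) [saffron, alpha = 0.05]
#>   index id  pval    alpha reject  wealth
#> 1     1  B 0.450 0.006208      0 0.01250
#> 2     2  C 0.006 0.006208      1 0.02500
#> 3     3  E 0.022 0.012415      0 0.02500
#> 4     4  D 0.847 0.012415      0 0.01258
#> 5     5  F 0.130 0.004096      0 0.01258
#> 6     6  G 0.001 0.004096      1 0.03758
#> 7     7  H 0.266 0.016511      0 0.03758
```

SAFFRON rejects arms C and G (docetaxel, abiraterone): each p-value is
compared to the level `alpha` emitted *before* it was seen, and each
rejection earns wealth that raises later levels — visible in the `wealth`
column and in the jump of the level after C's rejection. The footer reports
the level an eighth treatment arm would face:

```
#> next-hypothesis level: 0.0165108 (rounded: 0.0165)
```

Bounded ADDIS and alpha-spending reject only G (next levels 0.0016 and
0.0025), bounded LORD++ rejects nothing (0.0002), uncorrected testing
rejects C, E and G (0.0500), and offline BH agrees with SAFFRON on {C, G} —
the full comparison is asserted in `tests/testthat/test-acceptance.R`.

On the simulation testbed (T = 1000, 30% non-nulls, conservative nulls
`F0 = N(−0.5, sd 0.1)`), the adaptive rules' power advantage is clear while
all control FDR at 0.05:

```r
cfg <- sim_config(T = 1000, pi1 = 0.3, reps = 200, seed = 1)
run_experiment(cfg, c("lordpp", "saffron", "addis"), pi1 = 0.3)
#>   pi1 algorithm power power_se     fdr   fdr_se    mfdr reps
#> 1 0.3    lordpp 0.517  0.00254 0.00165 0.000218 0.00164  200
#> 2 0.3   saffron 0.632  0.00255 0.00928 0.000487 0.00933  200
#> 3 0.3     addis 0.709  0.00228 0.01624 0.000696 0.01632  200
```

## Command line

```sh
alphastream run --alg saffron --alpha 0.05 --bound 20 \
    --input pvals.csv --output log.csv      # CSV: id,pval[,batch]
alphastream simulate --T 1000 --pi1 0.1,0.5 --reps 2000 --seed 1 \
    --algs lordpp,saffron,addis --out results.csv
alphastream fixtures cat stampede
```

(`exec/alphastream` after install, or `alphastream_cli()` in R.)

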