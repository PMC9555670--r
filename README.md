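# proxnet

Contact networks from wearable proximity sensors, and Bayesian comparison
of behavioural conditions with a dyadic random-effects logistic model.

## The problem

Field experiments on physical distancing instrument a public space (for
example a supermarket) with wearable ultra-wideband tags that log, at 1 Hz,
the distance in centimetres between every pair of nearby tags. Turning that
raw stream into an answer to "did the intervention reduce contacts?"
requires a chain of non-trivial steps:

1. **Sessionization** — physical tags are reused by many customers in one
   day, so each tag's activity must be split into per-customer wearing
   sessions to obtain unique participant ids.
2. **Group detection** — households shop together and are allowed to be
   close; within-group pairs must be found and excluded. Two participants
   are assigned to the same group when they meet at least two of three
   criteria: at least 10 seconds of records within 80 cm, being closer
   than 1.5 m for at least 25% of their visit, and exiting at most
   60 seconds apart. Groups are closed transitively.
3. **Contact extraction** — a contact is a second during which two
   participants from different groups are closer than 1.5 m (the
   distancing regulation); per-dyad durations sum all such seconds.
4. **Network comparison** — contacts form an undirected, unweighted
   network per condition. Contact counts between actors are not
   independent observations, so conditions are compared with a dyadic
   network model rather than a naive count test.

`proxnet` implements this pipeline, the comparison model, the supporting
descriptive statistics (Mann-Whitney U with an exact small-sample mode,
Welch t, simple regression with F and R²), and a synthetic tag-stream
generator with planted ground truth for validating every stage.

## The b2 model

The core estimator is the *b2* model, an undirected, unweighted reduction
of the multilevel p2 family for dyadic network data. For each eligible
dyad (i, j):

    y_ij ~ Bernoulli( logit⁻¹( μ + Σ_k γ_k (x_ik + x_jk) + A_i + A_j ) )
    A_i  ~ Normal(0, σ_A²)

* μ — density intercept (log-odds of a contact between two baseline
  actors),
* γ_k — actor-level covariate effects; a condition dummy enters through
  both actors, and `exp(γ)` is reported as the odds ratio with a central
  95% credible interval,
* A_i — one random effect per actor, shared across that actor's dyads
  (identical sender and receiver roles; no reciprocity, no dyadic
  covariates, no network-level effects),
* dyads between actors of different conditions, who were never
  co-present, are structurally excluded from the likelihood rather than
  treated as observed zeros.

Estimation is Metropolis-within-Gibbs MCMC (random-walk proposals for μ,
γ and each A_i, a conjugate inverse-gamma draw for σ_A², adaptive proposal
scales frozen after burn-in), implemented in C++ for speed, with split-R̂
and effective-sample-size diagnostics and a Newton maximum-likelihood
oracle for the σ_A = 0 limit.

## Worked example

Simulate two conditions — a control day and a day on which customers are
rewarded for keeping distance (planted as a reduction in encounter
propensity) — then run the full pipeline and compare:

```r
library(proxnet)

cfg <- pipeline_config(
  conditions = list(
    control = list(stream = list(duration_s = 1800, arrival_rate = 2.5,
                                 encounter_rate = 0.08)),
    reward  = list(stream = list(duration_s = 1800, arrival_rate = 2.5,
                                 encounter_rate = 0.08,
                                 contact_logodds_shift = -0.7))),
  output_dir = file.path(tempdir(), "demo"),
  b2 = list(n_chains = 2, n_burnin = 500, n_iter = 1500),
  seed = 1)

cfg    <- pipeline_simulate(cfg)
report <- pipeline_compare(cfg, "control", "reward")
print(report)
```

```
Condition comparison: control vs reward 
  control: 65 participants, 304 contact dyads, median degree 9
  reward: 72 participants, 258 contact dyads, median degree 7
  OR = 0.80, 95% CI [0.68, 0.93] 
  durations: U = 34570.5, p = 0.01528
```

Participants in the reward condition had fewer unique contacts (median 7
vs 9); the b2 odds ratio of 0.80 with a credible interval excluding 1
says the per-dyad odds of a contact were about 20% lower per rewarded
actor. `summary(attr(report, "fit"))` shows the full posterior:

```
            mean    sd   2.5%  97.5%  rhat     ess
mu        -1.876 0.092 -2.061 -1.699 1.020 100.248
condition -0.223 0.077 -0.384 -0.077 1.025  96.985
sigma_a    0.413 0.056  0.306  0.523 1.003 135.869
```

Lower-level entry points (`parse_raw_log()`, `sessionize()`,
`detect_groups()`, `extract_contacts()`, `build_network()`, `fit_b2()`,
`mann_whitney_u()`, …) expose each stage individually; see the methods
vignette in `vignettes/` for the modelling choices behind them.

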