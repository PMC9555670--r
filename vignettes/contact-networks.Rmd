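---
title: "Methods: proximity-sensor contact networks and the b2 model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity-sensor contact networks and the b2 model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the modelling and design choices behind `proxnet`:
what each pipeline stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical details of the MCMC sampler. It states no
empirical claims beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## Data model

The raw input is a 1 Hz stream of pairwise distance assessments from
wearable ultra-wideband tags: each record carries an integer time stamp in
seconds, the reporting tag id, the opposing tag id, and the distance in
centimetres. Tags report only peers within a finite horizon (a few metres),
so absence of a record is not evidence of absence of a person. Timestamps
are treated as integer seconds from an arbitrary epoch; sub-second input is
floored. All intervals on the 1 Hz grid are closed `[start, end]` for
sessions (duration `end - start + 1`) and half-open `[t0, t1)` for analysis
windows — the two conventions that make durations additive and hourly
windows disjoint.

## Pre-processing choices

**Sessionization (`gap_threshold_s`, default 120 s).** A physical tag is
handed to several customers over a day and sits in a charger between uses.
A tag's appearance timeline (in either reporting role) is split wherever
two consecutive appearances are more than the threshold apart. 120 s is
long enough to bridge brief signal dropouts inside one visit and much
shorter than a realistic charger turnaround; it is configurable because it
is a heuristic, not an observed constant. A tag worn but never within
recording range of any other tag produces no records and hence no session —
an accepted limitation of presence-by-proximity sensing that is logged, not
silently ignored.

**Reciprocal reports.** Both tags of a pair may report the same second,
and the two reports need not agree. They are merged by taking the
*minimum* distance. For a distancing analysis this is the conservative
direction: measurement disagreement can only move a pair *into* contact
range, never out of it, so contacts are not undercounted.

**Group detection.** Households may legitimately be close, so within-group
pairs must not count as contacts. Two participants are linked when they
meet at least 2 of 3 criteria (all thresholds configurable via
`group_params()`):

* `c_close`: at least 10 s of records at ≤ 80 cm ("within" read as
  inclusive);
* `c_prox`: seconds at < 1.5 m amounting to at least 25% of the visit
  duration. The denominator is the *shorter* of the two visits: a
  household member who leaves early should still qualify with respect to
  the time they were actually present. (The overlap of the two visits is
  an alternative denominator; the shorter visit was chosen because it is
  monotone in the evidence and never exceeds the overlap-based fraction's
  denominator by construction of co-entry.)
* `c_coexit`: session end times at most 60 s apart.

The proximity criterion uses the same strict `< 150 cm` convention as the
contact definition, for consistency. Groups are the *connected components*
of the qualifying-pair graph: in a three-person household where only
adjacent pairs qualify, all three must end up in one group, so pairwise
assignment alone would be incoherent. Criteria are evaluated for every
pair of session-overlapping participants (a pair with no proximity records
can still co-exit); pairs whose sessions do not overlap cannot be a
shopping group and are skipped.

The heuristic has a known failure mode: two strangers who happen to exit
within a minute of each other *and* spend a large fraction of a very short
visit near each other will be folded into one group. The test suite
characterises when this cannot happen (sustained ≤ 50 cm planted groups,
rare short background encounters) and the pipeline excludes such pairs
symmetrically in both conditions, so the comparison is not biased in
either direction.

**Contacts (`threshold_cm = 150`, strict).** A (pair, second) is a contact
iff the merged distance is strictly below 150 cm and the pair spans two
groups. "< 1.5 m" and "within 1.5 m" conflict at exactly 150 cm; the
strict reading is adopted and configurable. Contact duration sums all
qualifying seconds of a dyad whether or not they are contiguous. No
minimum-duration filter is applied by default (`min_contact_seconds = 1`);
a threshold of 2 s can be set where single-second range blips should be
discounted. Dyad durations (not per-participant aggregates) feed the
Mann-Whitney comparison: the dyad is the natural unit of the duration
distribution and matches the unit of the network model.

## The b2 model

For eligible dyads $(i,j)$:

$$y_{ij} \sim \text{Bernoulli}\!\left(\text{logit}^{-1}\big(\mu +
\textstyle\sum_k \gamma_k (x_{ik}+x_{jk}) + A_i + A_j\big)\right),
\qquad A_i \sim N(0, \sigma_A^2).$$

The model is the undirected, unweighted member of the p2 family: contacts
are symmetric, so sender and receiver effects collapse into one actor
effect; reciprocity is meaningless; duration is deliberately not modelled
(a contact is binary).

**Eligibility.** When two condition networks are stacked
(`combine_networks()`), cross-condition dyads involve people who were
never in the building at the same time. Coding them as observed zeros
would deflate the density estimate with fake non-contacts, so they are
structurally excluded via a dyad mask and contribute nothing to the
likelihood.

**Covariate coding and the odds ratio.** An actor-level condition dummy
enters each dyad through $x_i + x_j$: within the baseline condition the
shift is 0, within the treated condition it is $2\gamma$. The reported
odds ratio is $e^{\gamma}$ — the per-actor convention, interpreting
$\gamma$ as each actor's contribution to the dyad's log-odds. Readers who
prefer the per-dyad contrast can square it; the package reports the
convention explicitly rather than leaving the exponent ambiguous.

**Priors.** $N(0, 10^2)$ on $\mu$ and each $\gamma_k$ and
Inverse-Gamma(0.001, 0.001) on $\sigma_A^2$ — the conventional diffuse
choices for this model family, all configurable through `b2_spec()`. With
thousands of dyads the fixed-effect posterior is likelihood-dominated.

**Sampler.** Metropolis-within-Gibbs, implemented in C++:

* random-walk normal proposals for $\mu$, each $\gamma_k$, and each $A_i$,
  evaluated through incremental updates of the dyad linear predictor (an
  actor update touches only its incident dyads);
* a conjugate inverse-gamma draw for $\sigma_A^2\,|\,A$;
* per-parameter proposal scales adapted every 50 burn-in sweeps toward
  ~35% acceptance (inside the 20–50% band that is efficient for
  one-dimensional random walks) and *frozen* after burn-in, so the
  post-burn-in chain satisfies detailed balance;
* identifiability: after each sweep the actor effects are re-centred and
  their mean absorbed into $\mu$ ($\eta$ is invariant under this move),
  preventing slow drift between the intercept and the random-effect mean;
* initialisation at the empirical log-odds of the density with effects at
  zero; degenerate networks (no edges or all edges) proceed with a
  warning that the intercept is weakly identified.

Draws use R's RNG, so a seed fixes every chain exactly. `sigma_fixed = 0`
pins all actor effects at zero, reducing the model to plain dyadic
logistic regression; the Newton oracle `logistic_mle_oracle()` fits that
limit independently and the test suite requires posterior means to agree
with it to 0.05 on the log-odds scale.

**Summaries and diagnostics.** The OR point estimate is the posterior
mean of $e^{\gamma}$; the interval is the central 95% percentile interval
(the simplest convention consistent with "credible interval"; HPD would
differ only for skewed posteriors). Convergence is monitored by split-R̂
and an effective sample size from averaged split-chain autocorrelations
with Geyer's initial-monotone truncation; R̂ > 1.05 triggers a warning.

## Supporting statistics

All three tests are implemented from first principles (their exact
small-sample behaviour is part of the package's contract) and are
cross-checked against `wilcox.test`, `t.test` and `lm` in the test suite.

* **Mann-Whitney U**: $U = \#\{x_i < y_j\} + \tfrac12\#\{x_i = y_j\}$.
  Exact mode uses the classical count recurrence (Gaussian-binomial
  coefficients) when the pooled sample is tie-free, and full enumeration
  of group assignments when ties are present and the assignment count is
  small; otherwise the tie-corrected normal approximation with continuity
  correction is used (and always when $n_1 n_2 > 10{,}000$, where
  permutation enumeration is infeasible). Two-sided p-values are defined
  as the null probability of a statistic at least as far from
  $n_1 n_2/2$ as observed.
* **Welch t** with Satterthwaite degrees of freedom; equal variances and
  equal sizes collapse the df to $n_1+n_2-2$ exactly. Zero variance with
  equal means returns $t=0,\ p=1$; with unequal means the infinite
  statistic is flagged.
* **Simple linear regression** in closed form with
  $F = \frac{R^2}{1-R^2}(n-2)$ on $(1, n-2)$ df, used for the
  crowdedness-versus-median-hourly-contacts relation
  (`hourly_summary()` produces the per-hour pairs).

Two-sided p-values are used throughout.

## The synthetic-data generator

No raw tag data from the motivating study design is publicly available,
so validation rests on simulation at two levels.

`simulate_b2_network()` draws networks directly from the b2 generative
model — the right tool for estimator tests (oracle equivalence, parameter
recovery, CI coverage, posterior contraction).

`simulate_tag_stream()` emulates the observable stream of a study day:

* parties (households) arrive as a Poisson process; sizes follow
  `group_size_probs` (default 70/25/5% for 1/2/3 — most customers shop
  alone); visit durations are log-normal with mean ≈ 10 min;
* party members stay at ≈ `group_proximity_cm` (default 60 cm, jitter
  10 cm — the nominal ranging-accuracy scale) for their whole overlap and
  exit within `max_coexit_lag_s` (default 10 s) of each other;
* cross-party pairs have rare, short encounters (log-normal durations,
  mean ≈ 8 s; distances 60–149 cm); the probability that a co-present
  pair meets at all is shifted on the log-odds scale by
  `contact_logodds_shift`, which plants a condition effect with known
  sign for end-to-end tests;
* co-present cross-party pairs also log *ambient* mid-range records
  (default 2% of overlap seconds at 150–400 cm): customers in a store
  constantly pass within the recording horizon without coming into
  contact range. These records are what anchor observed sessions to the
  full visit — without them a customer with a single 3 s encounter would
  appear to "visit" for 3 seconds, and any short encounter would
  dominate their visit fraction;
* physical tags are drawn from a finite pool with a recharge gap
  (default 300 s) between uses; distances are piecewise-constant integer
  centimetres per second, emitted as reciprocal record pairs, and absent
  above a 500 cm horizon.

The generator does **not** emulate pedestrian trajectories, store
geometry, queueing, clock drift, asymmetric or missing reciprocal
reports, or distance-dependent measurement error. Consequently, passing
the recovery tests demonstrates the pipeline's correctness on streams
with the assumed statistical structure, not robustness to sensor
pathologies — those enter real analyses through the configurable
thresholds, not through code paths exercised here.

Every stochastic element of one simulated stream flows from a single seed,
and the pipeline orchestrator derives per-condition seeds from one master
seed, so whole experiments are bit-reproducible.

## Validation problem sizes

The test suite validates: contact extraction against a brute-force
per-(pair, second) oracle on 50 random instances of up to 20 participants
and 1,000 s; exact group recovery on 20 seeded planted-group streams;
oracle equivalence of the sampler at 60 actors; parameter recovery
(mean bias of the posterior-mean condition effect within 0.1, ≥ 80%
coverage of 95% intervals) over 20 replications at 150 actors with
$\mu=-2.5$, $\gamma=-0.2$, $\sigma_A=0.6$; sign recovery of a planted
propensity reduction (log-odds shift −0.7, ~70 participants per
condition — chosen a priori so the density contrast carries a Wald z well
above 3, making sign errors binomially negligible) in at least 18 of 20
end-to-end runs; 5% type-I error of all three tests within three binomial
standard errors over 1,000 null simulations; and byte-identical outputs
under repeated seeds. These sizes are the package's chosen validation
conditions; all are configurable upward.

## Known limitations

* Participants invisible to the sensor (never near any other tag) cannot
  be sessionized; compliance estimation is out of scope.
* The group heuristic can fold chance co-exiting strangers on very short
  visits (see above); its audit table (`criteria` output) exists so such
  pairs can be reviewed.
* The b2 model deliberately ignores contact duration and temporal
  structure within the analysis window; it answers "how many distinct
  contacts", not "how long" (the latter is handled nonparametrically).
* Whether an analysis should pool both conditions in one likelihood with
  structural exclusion (as here) or fit per-network likelihoods with
  shared parameters is not settled by the model family; the pooled form
  was chosen because it yields one posterior for the contrast of
  interest.
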