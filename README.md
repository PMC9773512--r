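# doqed

Causal effect screening and quantification for observational discrete
cohorts.

Clinical questions of the form *"would changing this biomarker change the
outcome?"* usually cannot be answered by a randomized trial — cost, time and
ethics get in the way — and plain observational associations conflate
causation with confounding. `doqed` implements, for epidemiologists and
biostatisticians working with such cohorts, a two-stage alternative:

1. **Screening by quasi-experimental design.** Each exposed subject is
   matched to a comparable unexposed control (exact and caliper matching on
   covariates), every pair `(u, v)` gets an outcome sign
   (+1 if `Y_u > Y_v`, −1 if smaller, 0 on ties), and the net outcome

   δ = Σ outcome(u, v) / |P| × 100 %

   summarizes the evidence. A sign test backs it up: among the
   `s = |P| − n₀` non-tied pairs the positive count `m` is Binomial(s, ½)
   under the null, so `z = (m − s/2) / (√s / 2)` is compared with
   `Z_{α/2}`; an exact binomial variant is also provided.

2. **Quantification by do-calculus.** Given a causal DAG over the
   variables (observed and latent nodes), the interventional query
   `P(Y | do(X))` is rewritten with the three rules of the do-calculus —
   each application guarded by a d-separation check on the appropriate
   mutilated graph `G_x̄` / `G_x̲` — into a do-free estimand:
   the plain conditional (no confounding), the back-door adjustment
   `Σ_s P(y|x,s) P(s)`, the front-door formula
   `Σ_m P(m|x) Σ_{x'} P(x') P(y|x',m)`, or an instrumental-variable Wald
   ratio. The estimand is evaluated by plug-in from empirical frequency
   tables, ending in the **average causal effect**

   ACE = P(Y = y | do(X = x′)) − P(Y = y | do(X = x)).

Every estimator is validated against a built-in discrete structural causal
model simulator whose interventional distributions are computed exactly by
enumeration, so the whole chain — identification, derivation trace,
plug-in — is checkable without any external data.

## Worked example

Identification on the mediation graph with a latent confounder
(`U → X`, `U → Y` latent; `X → Z → Y` observed — the shape of an
inflammation-marker / performance-status / survival analysis):

```r
library(doqed)
g  <- causal_graph(list(c("U","X"), c("U","Y"), c("X","Z"), c("Z","Y")),
                   latent = "U")
identify_effect(g, "X", "Y")
#> causal identification for P(Y | do(X))
#>   pattern:   frontdoor
#>   auxiliary: Z
#>   estimand:  sum_{m1 in Z} [P(Z=m1 | X=x) * sum_{x2 in X} [P(X=x2) * P(Y=y | X=x2,Z=m1)]]
#>   derived in 7 steps (bayes-expand, rule2, rule2, rule3, bayes-expand, rule2, rule3)
```

The seven steps are a replayable trace (`replay_trace()`); each `rule2` /
`rule3` application re-checks its independence condition on the mutilated
graph.

Screening and effect arithmetic for a published-style pair table
(35 matched pairs: 22 positive, 10 negative, 3 ties), and a front-door
plug-in whose per-stratum factors are weighted by joint probabilities
`P(Z=z, X=x)`:

```r
sign_test(m_pos = 22, n_zero = 3, n_pairs = 35)
#> sign test: s = 32, mu = 16, sigma = 2.8284, z = 2.1213
#>   critical Z_{alpha/2} = 1.9600 (alpha = 0.05): reject H0

inner <- c(0.173077, 0.453963, 0.699023, 0.864253)   # sum_x' P(y|x',z) P(x')
p0 <- frontdoor_joint_weight_estimate(inner, c(0.047337, 0.195266, 0.426036, 0.100592))
p1 <- frontdoor_joint_weight_estimate(inner, c(0.017751, 0.071006, 0.12426, 0.017751))
ace(p0, p1)
#> ACE = 0.344074 (34.4%)
#>   P(y | do(x'))  = 0.481582
#>   P(y | do(x))   = 0.137508
```

`pair_delta()` on those signs gives δ = 34.286 %: a strong positive net
outcome, and the sign test rejects the null — evidence of a causal link,
quantified as a 34.4-point survival advantage for the control exposure
level.

End-to-end on a synthetic cohort with known ground truth:

```r
paths  <- make_fixtures("nlr_like", n = 1200, seed = 5, out_dir = tempdir())
report <- run_pipeline(paths[["config"]])
print(report)
#> == matched-pair screening ==
#>   299 pairs (+1: 63, -1: 79, 0: 157), delta = -5.351%
#>   sign test: z = -1.3427 vs 1.9600 -> NO causal evidence
#> == identification ==
#>   pattern: frontdoor
#>   estimand: sum_{m1 in Z} [P(Z=m1 | X=x) * sum_{x2 in X} [P(X=x2) * P(Y=y | X=x2,Z=m1)]]
#> == estimation ==
#>   P(Y=1|do(X=0)) = 0.608204
#>   P(Y=1|do(X=1)) = 0.566588
#>   ACE = 0.041615 (4.2%)
#>   note: exploratory: sign test did not reject
```

The preset's exact ACE is 0.0512; the plug-in at n = 1200 lands at 0.0416,
and the screening stage correctly flags that a binary outcome with this
small an effect does not clear the sign test at this sample size — the
estimate is labelled exploratory rather than suppressed.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/doqed.R run      --config config.yaml --out report.json
Rscript inst/cli/doqed.R identify --graph graph.txt --exposure X --outcome Y
Rscript inst/cli/doqed.R fixtures --pattern frontdoor --n 1000 --seed 7 --out-dir fx
```

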