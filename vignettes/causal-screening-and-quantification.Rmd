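---
title: "Screening and quantifying causal effects in observational cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and quantifying causal effects in observational cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doqed)
```

## The problem

An observational cohort records an exposure $X$, an outcome $Y$, and
whatever covariates the clinic happened to measure. Two distinct questions
arise. *Is there a causal link at all?* — a question of evidence, which
`doqed` answers with a matched-pair quasi-experimental comparison. *How
large is the effect?* — a question of identification and estimation, which
it answers by reducing the interventional quantity $P(Y \mid do(X))$ to a
function of observational probabilities via the do-calculus and evaluating
that function from frequency tables. The two stages are deliberately
independent: matching controls for the confounders you measured, the
graphical stage reasons about the ones you did not.

## Stage 1: matched-pair screening

Each treated subject $u$ is paired with an untreated subject $v$ drawn
uniformly at random among the controls that agree exactly on the requested
covariates (e.g. sex) and fall within a caliper on the others (e.g. age
$\pm 5$ years). Pairs get a sign: $+1$ if $Y_u > Y_v$, $-1$ if $Y_u < Y_v$,
$0$ on a tie. The net outcome

$$\delta = \frac{\sum_{(u,v) \in P} \mathrm{outcome}(u,v)}{|P|} \times 100\%$$

lives in $[-100, 100]$; values near $+100$ mean the treated member of
almost every comparable pair did better.

**Matching choices.** Treated units are processed in ascending unit-id
order and controls are consumed without replacement; candidates are drawn
with a run-local seeded generator, so a fixed seed reproduces the pairing
bit for bit without disturbing the caller's RNG stream. A treated unit
with no eligible control is dropped (and the pair count shrinks) rather
than matched badly. When a caliper is requested for age without a
tolerance, $\pm 5$ years is used and echoed in the report. Records with
missing values in a matching covariate are dropped with a warning —
imputation is out of scope. Ties use exact numeric equality by default; a
tie tolerance is available but defaults to 0.

**The sign test.** Among the $s = |P| - n_0$ non-tied pairs the positive
count $m$ is $\mathrm{Binomial}(s, 1/2)$ under the null of no effect,
approximated as normal with mean $s/2$ and standard deviation
$\sqrt{s}/2$; the statistic $z = (m - s/2)/(\sqrt{s}/2)$ is compared
against the upper $\alpha/2$ normal quantile, with no continuity
correction, and the approximation is intended for $s > 20$ (a warning is
issued below). Note the decision rule is *one-sided against a two-sided
critical value*: its actual size is therefore about $\alpha/2$, not
$\alpha$. We keep this rule as the primary output because it is the form
used in the analyses this package operationalizes, and we verify its
calibration in the test suite against the exact binomial law: at $s = 32$,
$\alpha = 0.05$ the rule rejects iff $m \ge 22$, an exact size of
$0.0251$, and a 2,000-replicate null simulation through the full matching
machinery reproduces that rate within 1.5 percentage points.
`sign_test_exact()` offers the orthodox two-sided exact binomial test for
users who want size $\alpha$.

## Stage 2: identification by do-calculus

A causal DAG $G$ declares each variable observed or latent. Latent nodes
participate in paths exactly like observed ones — latency only forbids
conditioning on them in estimands. Interventions are represented by graph
surgery: $G_{\bar{x}}$ deletes arrows into $X$, $G_{\underline{x}}$
arrows out of it. Conditional independence is decided by d-separation,
implemented as a linear-time reachability sweep over (node, direction)
states; the test suite keeps an independent brute-force path enumerator
and checks agreement on hundreds of random DAGs, because the d-separation
predicate is the foundation every rule check stands on.

The three rewrite rules (insertion/deletion of observations,
action/observation exchange, insertion/deletion of actions) are exposed
both as applicability checks and as guarded rewrites: `apply_rule()`
refuses to rewrite when the independence fails, and records every step.
`identify_effect()` tries, in order:

1. **No confounding** — rule 2 applies to the whole query:
   $P(y \mid do(x)) = P(y \mid x)$.
2. **Back-door** — a minimal observed non-descendant set $S$ blocking all
   back-door paths; the derivation expands over $S$, drops $do(x)$ from
   $P(s \mid do(x))$ by rule 3 and exchanges it in the main term by rule 2,
   yielding $\sum_s P(s)\, P(y \mid x, s)$.
3. **Front-door** — a mediator set intercepting every causal path,
   unconfounded with $X$, deconfounded from $Y$ by $X$; the seven-step
   derivation (two expansions, three rule-2 and two rule-3 applications)
   yields $\sum_m P(m \mid x) \sum_{x'} P(x')\, P(y \mid x', m)$.
4. **Instrument** — an observed parent of $X$ with no arrow into $Y$ and
   no open path to $Y$ once $X$'s outgoing edges are cut. No
   nonparametric estimand exists in this pattern; estimation falls to the
   linear Wald ratio, valid under linearity or monotonicity assumptions.

Otherwise the effect is reported as unidentified and the report says the
only remaining option is a randomized experiment.

**Design choices made here.** Among valid adjustment or mediator sets the
minimum-cardinality, lexicographically smallest one is returned —
determinism matters more than optimality for reproducible analyses.
Identification works at variable level; values are bound only at
estimation time. Traces are replayable: `replay_trace()` re-executes every
guarded step from the initial query and must reproduce the estimand
exactly, which the tests assert. We did not implement an open-ended
rewrite search over arbitrary expressions: the dispatcher covers the three
bivariate patterns a two-variable query can present (plus the instrument
fallback), each via a genuine guarded derivation, and a complete
identification algorithm for arbitrary latent-variable graphs is out of
scope. A front-door variant weighted by *joint* probabilities
$P(Z\!=\!z, X\!=\!x)$ instead of conditionals is provided separately
(`frontdoor_joint_weight_estimate()`) because some published analyses
tabulate exactly those factors; its weights sum to $P(X\!=\!x)$, so it is
exempt from the normalization invariant and documented as such.

## Estimation

`empirical_tables()` turns a cohort into a maximum-likelihood joint
frequency table (all levels kept as strings). Estimand evaluation is one
generic tree-walk over the symbolic expression; `backdoor_estimate()` and
`frontdoor_estimate()` are thin named loops that agree with the tree-walk
to machine precision (both routes are tested against each other).

**Numerical policy.** Positivity is treated as an assumption, not a
nuisance: a stratum that the formula actually uses but that has zero
probability raises an error naming the stratum. Products inside estimands
evaluate weight factors first and short-circuit at exact zero, so strata
with zero weight are skipped rather than probed. Additive smoothing
$\lambda$ (added to every cell before normalization) is the opt-in escape;
estimates converge monotonically to the unsmoothed value as
$\lambda \to 0$, which is tested at $\lambda = 1, 0.1, 0.01$. A degenerate
deterministic mediator is a genuine positivity violation — the front-door
functional is undefined there — and errors rather than silently returning
a wrong number.

The average causal effect is reported control-minus-treated:
$ACE = P(Y\!=\!1 \mid do(X\!=\!0)) - P(Y\!=\!1 \mid do(X\!=\!1))$, so a
positive value favours the control exposure level; both interventional
probabilities are always printed alongside, as a fraction and a
percentage, probabilities to 6 decimal places and $\delta$ to 3.

## The synthetic test bed

Because real patient cohorts cannot ship with a package, every estimator
is validated against a discrete structural causal model simulator. An
`scm_spec` is a DAG plus one conditional probability table per node; the
exact joint is computed by enumeration (refused above $10^6$ cells),
interventions replace a mechanism by a point mass and cut incoming arrows,
and `ground_truth_ace()` gives exact interventional probabilities.
Sampling uses one master seed with a deterministic per-node substream, so
adding a node to a model never perturbs the draws of existing nodes.

Four presets cover the canonical patterns. Their CPTs were chosen once as
plausible epidemiological magnitudes and are committed as JSON fixtures
with their exact ground-truth ACEs: `confounder` (observed $U$; exact ACE
$-0.3$), `frontdoor` (latent $U$, binary mediator; $-0.225$), `instrument`
($-0.4$ structural), and `nlr_like`, which mimics the shape of an oncology
cohort — binary exposure with marginal prevalence $39/169 \approx 0.23$
(a high neutrophil-to-lymphocyte ratio), a four-level performance-status
mediator (60/70/80/90), a binary survival outcome split at the cohort
median, and a latent severity confounder (exact ACE $+0.0512$).

**What the simulator does and does not emulate.** It reproduces the
discrete, fully tabulated structure of such analyses — finite CPTs, a
handful of variables, realistic marginals — and therefore exercises
identification, plug-in estimation and their convergence
($n = 50{,}000$ cohorts recover preset ground truth within $0.02$;
null-effect models stay within $0.02$ of zero on average over 20 seeds at
$n = 20{,}000$; problem sizes chosen to make Monte-Carlo error comfortably
smaller than the tolerances). It does not emulate censoring,
continuous-time survival, measurement error, missing-data mechanisms or
selection into the cohort; a passing test suite says the *method* is
implemented correctly, not that any particular clinical dataset satisfies
the positivity, no-interference and graph-correctness assumptions the
method inherits.

## Known limitations

* Identification is restricted to the four bivariate patterns; graphs
  requiring the full identification machinery for arbitrary latent
  structures are reported as unidentified rather than guessed at.
* Plug-in estimates come without confidence intervals; resampling is a
  natural extension but is not included.
* The instrument pattern yields a linear effect estimate, not
  interventional probabilities, and its validity rests on the linearity /
  monotonicity assumption the Wald ratio requires.
* Matching supports one control per treated unit, exact plus caliper
  eligibility only — no propensity scores, no optimal matching.
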