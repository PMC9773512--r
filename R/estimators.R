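#' Evaluate a symbolic estimand against a probability table
#'
#' The single evaluation engine behind every plug-in estimator: a recursive
#' walk of a do-free [prob_expr][p_term()] against a [prob_table()].
#' Summations range over the bound variable's levels in the table; products
#' evaluate left to right and short-circuit at an exact zero, so estimands
#' constructed with their weight factors first (as [identify_effect()] emits
#' them) skip empty strata instead of tripping over undefined conditionals.
#' A conditional evaluated in a stratum with zero mass that is actually
#' reached raises a positivity error naming the stratum.
#'
#' @param expr A do-free `prob_expr`.
#' @param table A [prob_table()].
#' @param env Named list binding the expression's free symbols to levels,
#'   e.g. `list(x = "0", y = "1")`.
#' @return A probability.
#' @export
eval_estimand <- function(expr, table, env = list()) {
  if (!is_do_free(expr)) {
    stop("expression contains do() terms: not estimable from the table")
  }
  eval_expr(expr, table, lapply(env, as.character))
}

eval_expr <- function(expr, table, env) {
  if (inherits(expr, "p_term")) {
    bind <- function(atoms) {
      vals <- lapply(names(atoms), function(sym) {
        if (is.null(env[[sym]])) stop("unbound symbol '", sym, "'")
        env[[sym]]
      })
      stats::setNames(vals, unname(atoms))
    }
    pt_cond(table, bind(expr$targets), bind(expr$given))
  } else if (inherits(expr, "p_sum")) {
    total <- 0
    for (lev in pt_levels(table, expr$var)) {
      env[[expr$sym]] <- lev
      total <- total + eval_expr(expr$child, table, env)
    }
    total
  } else {
    acc <- 1
    for (child in expr$children) {
      acc <- acc * eval_expr(child, table, env)
      if (acc == 0) return(0)
    }
    acc
  }
}

#' Interventional probability from an identification result
#'
#' Evaluates the do-free estimand of a [identify_effect()] result at given
#' exposure and outcome levels.
#'
#' @param ident A `causal_identification` with a non-`NULL` estimand.
#' @param table A [prob_table()] over the observed variables.
#' @param x_value,y_value Levels of the exposure and outcome.
#' @return The plug-in estimate of `P(outcome = y_value | do(exposure =
#'   x_value))`.
#' @export
interventional_probability <- function(ident, table, x_value, y_value) {
  if (is.null(ident$estimand)) {
    stop("pattern '", ident$pattern, "' carries no nonparametric estimand")
  }
  eval_estimand(ident$estimand, table,
                env = list(x = x_value, y = y_value))
}

#' Back-door adjustment estimate
#'
#' The adjustment formula `sum_s P(y | x, s) P(s)` over the strata of the
#' adjustment set. Strata with zero marginal probability contribute nothing
#' and are skipped; a stratum with positive `P(s)` but zero `P(x, s)` is a
#' positivity violation and raises an error naming the stratum (smoothing in
#' [empirical_tables()] is the opt-in escape).
#'
#' @param table A [prob_table()].
#' @param exposure,outcome Variable names in the table.
#' @param x_value,y_value Levels.
#' @param adjust Character vector of adjustment variables (may be empty, in
#'   which case the estimate is the plain conditional `P(y | x)`).
#' @return A probability.
#' @export
backdoor_estimate <- function(table, exposure, outcome, x_value, y_value,
                              adjust = character()) {
  y <- stats::setNames(list(y_value), outcome)
  x <- stats::setNames(list(x_value), exposure)
  if (!length(adjust)) return(pt_cond(table, y, x))
  grid <- expand.grid(table$levels[adjust], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  total <- 0
  for (i in seq_len(nrow(grid))) {
    s <- as.list(grid[i, , drop = FALSE])
    ps <- pt_prob(table, s)
    if (ps == 0) next
    total <- total + pt_cond(table, y, c(x, s)) * ps
  }
  total
}

#' Front-door adjustment estimate (mediator weights conditional)
#'
#' The standard front-door formula
#' `sum_m P(m | x) sum_{x'} P(x') P(y | x', m)`: the outer weights are the
#' mediator's distribution *conditional* on the exposure. Inner strata with
#' zero `P(x')` or outer strata with zero `P(m | x)` are skipped; a reached
#' stratum `(x', m)` with zero mass raises a positivity error.
#'
#' @inheritParams backdoor_estimate
#' @param mediators Character vector of mediator variables (nonempty).
#' @return A probability.
#' @export
frontdoor_estimate <- function(table, exposure, outcome, x_value, y_value,
                               mediators) {
  stopifnot(length(mediators) >= 1L)
  y <- stats::setNames(list(y_value), outcome)
  x <- stats::setNames(list(x_value), exposure)
  m_grid <- expand.grid(table$levels[mediators], KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  total <- 0
  for (i in seq_len(nrow(m_grid))) {
    m <- as.list(m_grid[i, , drop = FALSE])
    pmx <- pt_cond(table, m, x)
    if (pmx == 0) next
    inner <- 0
    for (xp in pt_levels(table, exposure)) {
      x2 <- stats::setNames(list(xp), exposure)
      px2 <- pt_prob(table, x2)
      if (px2 == 0) next
      inner <- inner + px2 * pt_cond(table, y, c(x2, m))
    }
    total <- total + pmx * inner
  }
  total
}

#' Front-door variant with joint mediator weights
#'
#' A front-door style plug-in in which each mediator stratum's inner
#' adjustment sum is weighted by a *joint* probability `P(Z = z, X = x)`
#' rather than the conditional `P(Z = z | X = x)` of the standard formula
#' ([frontdoor_estimate()]). The weights therefore need not sum to one (they
#' sum to `P(X = x)`), and the result is not guaranteed to be a normalized
#' interventional distribution over the outcome; it is provided because some
#' published analyses tabulate exactly these factors. With weights
#' renormalized to sum to one the result is a proper mixture of the inner
#' sums.
#'
#' @param inner Numeric vector: the inner adjustment sums
#'   `sum_{x'} P(y | x', z) P(x')`, one per mediator stratum.
#' @param weight Numeric vector of nonnegative weights, one per stratum.
#' @return `sum(inner * weight)`.
#' @examples
#' frontdoor_joint_weight_estimate(
#'   c(0.173077, 0.453963, 0.699023, 0.864253),
#'   c(0.047337, 0.195266, 0.426036, 0.100592))
#' @export
frontdoor_joint_weight_estimate <- function(inner, weight) {
  if (length(inner) != length(weight)) stop("inner and weight must align")
  if (any(!is.finite(inner)) || any(!is.finite(weight))) {
    stop("inputs must be finite")
  }
  if (any(inner < 0) || any(weight < 0)) stop("inputs must be nonnegative")
  sum(inner * weight)
}

#' Instrumental-variable (Wald) estimate
#'
#' Under linearity or monotonicity a binary instrument identifies the effect
#' as the Wald ratio `(E[Y | I = 1] - E[Y | I = 0]) / (E[X | I = 1] - E[X |
#' I = 0])`. Works on a [prob_table()] with numeric-coded levels or directly
#' on a cohort data frame (continuous variables allowed).
#'
#' @param data A [prob_table()] or a data frame.
#' @param instrument,exposure,outcome Variable names; the instrument must
#'   take exactly two levels.
#' @return The Wald ratio.
#' @export
iv_wald_estimate <- function(data, instrument, exposure, outcome) {
  if (inherits(data, "prob_table")) {
    ilev <- pt_levels(data, instrument)
    if (length(ilev) != 2L) stop("instrument must be binary")
    ilev <- ilev[order(as.numeric(ilev))]
    cond_mean <- function(var, ival) {
      iv <- stats::setNames(list(ival), instrument)
      lev <- pt_levels(data, var)
      vals <- as.numeric(lev)
      if (anyNA(vals)) stop("levels of '", var, "' are not numeric")
      sum(vals * vapply(lev, function(l) {
        pt_cond(data, stats::setNames(list(l), var), iv)
      }, 1))
    }
    dy <- cond_mean(outcome, ilev[2L]) - cond_mean(outcome, ilev[1L])
    dx <- cond_mean(exposure, ilev[2L]) - cond_mean(exposure, ilev[1L])
  } else {
    i <- as.numeric(data[[instrument]])
    lev <- sort(unique(i))
    if (length(lev) != 2L) stop("instrument must be binary")
    y <- as.numeric(data[[outcome]])
    x <- as.numeric(data[[exposure]])
    dy <- mean(y[i == lev[2L]]) - mean(y[i == lev[1L]])
    dx <- mean(x[i == lev[2L]]) - mean(x[i == lev[1L]])
  }
  if (abs(dx) < 1e-12) stop("null or weak instrument: zero denominator")
  dy / dx
}

#' Average causal effect
#'
#' The difference between two interventional outcome probabilities,
#' `P(Y = y | do(X = x')) - P(Y = y | do(X = x))`. The headline convention
#' throughout this package puts the control level first (`x'` = control,
#' `x` = treated), so a positive ACE means the outcome is more probable
#' under the control level of the exposure.
#'
#' @param p_do_x_prime Interventional probability at the first (reference /
#'   control) exposure level.
#' @param p_do_x Interventional probability at the second (treated) level.
#' @return An object of class `ace_result` with elements `ace` (fraction),
#'   `percent`, `p_do_x_prime`, `p_do_x`.
#' @examples
#' ace(0.481582, 0.137509) # 0.344073
#' @export
ace <- function(p_do_x_prime, p_do_x) {
  for (p in c(p_do_x_prime, p_do_x)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("interventional probabilities must lie in [0, 1]")
    }
  }
  structure(list(ace = p_do_x_prime - p_do_x,
                 percent = (p_do_x_prime - p_do_x) * 100,
                 p_do_x_prime = p_do_x_prime, p_do_x = p_do_x),
            class = "ace_result")
}

#' @export
print.ace_result <- function(x, ...) {
  cat(sprintf("ACE = %.6f (%.1f%%)\n", x$ace, x$percent))
  cat(sprintf("  P(y | do(x'))  = %.6f\n  P(y | do(x))   = %.6f\n",
              x$p_do_x_prime, x$p_do_x))
  invisible(x)
}
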