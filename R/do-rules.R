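#' The three do-calculus rule applicability checks
#'
#' Each rule of the do-calculus licenses one rewrite of an interventional
#' term `P(y | do(x), z, w)` and is applicable exactly when a conditional
#' independence holds in a mutilated graph:
#'
#' * Rule 1 (insertion/deletion of observations): drop or add the observed
#'   conditioning `z` iff `Y` and `Z` are d-separated by `X` and `W` in the
#'   graph with arrows into `X` deleted.
#' * Rule 2 (action/observation exchange): replace `do(z)` by observing `z`
#'   (or back) iff the separation holds with arrows into `X` and arrows out
#'   of `Z` deleted.
#' * Rule 3 (insertion/deletion of actions): drop or add `do(z)` iff the
#'   separation holds with arrows deleted into `X` and into `Z(W)`, the
#'   subset of `Z` nodes that are not ancestors of any `W` node once the
#'   arrows into `X` are removed.
#'
#' @param g A [causal_graph()].
#' @param y,z,x,w Pairwise disjoint node sets (`x`, `w` may be empty): `y`
#'   the targets, `z` the nodes being inserted/deleted/exchanged, `x` the
#'   remaining intervention set, `w` the remaining observed conditioning.
#' @return `TRUE` iff the rule's independence condition holds.
#' @seealso [apply_rule()] for the guarded rewrites, [d_separated()].
#' @export
rule1_check <- function(g, y, z, x = character(), w = character()) {
  check_rule_sets(g, y, z, x, w)
  d_separated(mutilate(g, overline = x), y, z, union(x, w))
}

#' @rdname rule1_check
#' @export
rule2_check <- function(g, y, z, x = character(), w = character()) {
  check_rule_sets(g, y, z, x, w)
  d_separated(mutilate(g, overline = x, underline = z), y, z, union(x, w))
}

#' @rdname rule1_check
#' @export
rule3_check <- function(g, y, z, x = character(), w = character()) {
  check_rule_sets(g, y, z, x, w)
  zw <- z_not_ancestors_of_w(g, z, w, overline_x = x)
  d_separated(mutilate(g, overline = union(x, zw)), y, z, union(x, w))
}

check_rule_sets <- function(g, y, z, x, w) {
  sets <- list(y = y, z = z, x = x, w = w)
  for (nm in names(sets)) check_nodes(g, sets[[nm]], what = nm)
  all_nodes <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_nodes)) {
    stop("the sets y, z, x, w must be pairwise disjoint")
  }
  invisible(TRUE)
}

#' Rewrite one term of an expression under a do-calculus rule
#'
#' Applies a single guarded rewrite to the leaf at `path`: rule 1 drops or
#' adds observed conditioning, rule 2 exchanges `do(z)` with observed `z`,
#' rule 3 drops or adds an action `do(z)`. The applicability condition is
#' checked first ([rule1_check()] and friends) and a refusal error is raised
#' when it fails, so an expression can never be rewritten unsoundly. The
#' original expression is not modified; the returned expression carries the
#' recorded step as attribute `"last_step"` for assembling a
#' [derivation trace][replay_trace].
#'
#' @param expr A `prob_expr`.
#' @param path Integer vector addressing the leaf to rewrite (see
#'   [identify_effect()] traces); `integer(0)` addresses the root.
#' @param rule One of `"rule1"`, `"rule2"`, `"rule3"`.
#' @param g The [causal_graph()] the independence conditions are checked on.
#' @param z Named character vector `c(sym = "Var", ...)`: the atoms moved by
#'   the rule.
#' @param direction `"drop"`/`"add"` for rules 1 and 3; `"to_obs"`/`"to_do"`
#'   for rule 2. Defaults to the direction that removes structure.
#' @return The rewritten expression (with attribute `"last_step"`).
#' @examples
#' g <- causal_graph(list(c("X", "Z"), c("Z", "Y")))
#' q <- p_term(c(z = "Z"), do = c(x = "X"))
#' apply_rule(q, integer(0), "rule2", g, z = c(x = "X")) # P(Z | X)
#' @export
apply_rule <- function(expr, path, rule = c("rule1", "rule2", "rule3"),
                       g, z, direction = NULL) {
  rule <- match.arg(rule)
  z <- as_atoms(z)
  leaf <- expr_get(expr, path)
  if (!inherits(leaf, "p_term")) stop("path must address a probability term")
  in_do <- all(z %in% leaf$do)
  in_given <- all(z %in% leaf$given)
  if (is.null(direction)) {
    direction <- switch(rule,
      rule1 = if (in_given) "drop" else "add",
      rule2 = if (in_do) "to_obs" else "to_do",
      rule3 = if (in_do) "drop" else "add")
  }
  # partition for the independence check: variables, not symbols
  drop_vars <- function(atoms) atoms[!(atoms %in% z)]
  y_set <- unname(leaf$targets)
  z_set <- unname(z)
  x_set <- unname(drop_vars(leaf$do))
  w_set <- unname(drop_vars(leaf$given))
  ok <- switch(rule,
    rule1 = rule1_check(g, y_set, z_set, x_set, w_set),
    rule2 = rule2_check(g, y_set, z_set, x_set, w_set),
    rule3 = rule3_check(g, y_set, z_set, x_set, w_set))
  if (!ok) {
    stop(sprintf(
      "%s not applicable: (%s _||_ %s | %s, %s) fails in the mutilated graph",
      rule, paste(y_set, collapse = ","), paste(z_set, collapse = ","),
      paste(x_set, collapse = ","), paste(w_set, collapse = ",")))
  }
  new_leaf <- leaf
  if (rule == "rule1") {
    if (direction == "drop") {
      stopifnot(in_given)
      new_leaf$given <- drop_vars(leaf$given)
    } else {
      new_leaf$given <- c(leaf$given, z)
    }
  } else if (rule == "rule2") {
    if (direction == "to_obs") {
      stopifnot(in_do)
      new_leaf$do <- drop_vars(leaf$do)
      new_leaf$given <- c(leaf$given, z)
    } else {
      stopifnot(in_given)
      new_leaf$given <- drop_vars(leaf$given)
      new_leaf$do <- c(leaf$do, z)
    }
  } else {
    if (direction == "drop") {
      stopifnot(in_do)
      new_leaf$do <- drop_vars(leaf$do)
    } else {
      new_leaf$do <- c(leaf$do, z)
    }
  }
  new_leaf <- p_term(new_leaf$targets, new_leaf$given, new_leaf$do)
  out <- expr_set(expr, path, new_leaf)
  attr(out, "last_step") <- list(
    rule = rule, path = path, vars = z, direction = direction,
    check = list(y = y_set, z = z_set, x = x_set, w = w_set, holds = TRUE))
  out
}

#' Expand a term by summing over auxiliary variables
#'
#' The chain-rule ("Bayes") expansion used between rule applications:
#' `P(t | C) = sum_s P(s | C) P(t | C, s)`, with the weight factor placed
#' first in the product. With several atoms the summations nest in order.
#'
#' @inheritParams apply_rule
#' @param vars Named character vector of atoms to sum over.
#' @return The expanded expression (with attribute `"last_step"`).
#' @export
expand_term <- function(expr, path, vars) {
  vars <- as_atoms(vars)
  stopifnot(length(vars) >= 1L)
  leaf <- expr_get(expr, path)
  if (!inherits(leaf, "p_term")) stop("path must address a probability term")
  if (any(unname(vars) %in% unlist(lapply(leaf, unname)))) {
    stop("expansion variables must be new to the term")
  }
  weight <- p_term(vars, leaf$given, leaf$do)
  main <- p_term(leaf$targets, c(leaf$given, vars), leaf$do)
  body <- prod_of(weight, main)
  for (i in rev(seq_along(vars))) {
    body <- sum_over(names(vars)[i], unname(vars[i]), body)
  }
  out <- expr_set(expr, path, body)
  attr(out, "last_step") <- list(rule = "bayes-expand", path = path,
                                 vars = vars, direction = "expand",
                                 check = NULL)
  out
}

#' Replay a derivation trace
#'
#' A derivation trace is the ordered list of rewrite steps recorded by
#' [identify_effect()]. Replaying it from the initial query re-executes every
#' guarded rewrite (re-checking each independence on the graph) and must
#' reproduce the final estimand exactly.
#'
#' @param query The initial `p_term`.
#' @param trace A list of steps as recorded by [apply_rule()]/[expand_term()].
#' @param g The [causal_graph()].
#' @return The final `prob_expr`.
#' @export
replay_trace <- function(query, trace, g) {
  expr <- query
  for (step in trace) {
    expr <- if (step$rule == "bayes-expand") {
      expand_term(expr, step$path, step$vars)
    } else {
      apply_rule(expr, step$path, step$rule, g, step$vars, step$direction)
    }
  }
  attr(expr, "last_step") <- NULL
  expr
}
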