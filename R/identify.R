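#' Search for a back-door adjustment set
#'
#' A valid back-door set for the effect of `exposure` on `outcome` is an
#' observed set containing no descendant of the exposure that blocks every
#' back-door path (paths entering the exposure through an incoming arrow).
#' Blocking is checked by d-separation in the graph with the exposure's
#' outgoing edges removed. Among valid sets, the minimum-cardinality,
#' lexicographically smallest one is returned so results are deterministic.
#'
#' @param g A [causal_graph()].
#' @param exposure,outcome Observed node labels, distinct.
#' @return A character vector (possibly empty: no adjustment needed), or
#'   `NULL` when no observed set qualifies.
#' @export
find_backdoor_set <- function(g, exposure, outcome) {
  check_query_nodes(g, exposure, outcome)
  cand <- sort(setdiff(observed_nodes(g),
                       c(exposure, outcome, descendants_of(g, exposure))))
  g_out <- mutilate(g, underline = exposure)
  for (k in 0:length(cand)) {
    sets <- subsets_of_size(cand, k)
    for (s in sets) {
      if (d_separated(g_out, exposure, outcome, s)) return(s)
    }
  }
  NULL
}

#' Search for a front-door mediator set
#'
#' A valid front-door set `M` intercepts every directed causal path from the
#' exposure to the outcome, has no unblocked back-door path from the exposure
#' to `M`, and has all back-door paths from `M` to the outcome blocked by the
#' exposure. The last two conditions are checked by d-separation on the
#' graphs with the exposure's (respectively `M`'s) outgoing edges removed.
#' The minimum-cardinality, lexicographically smallest observed set wins.
#'
#' @inheritParams find_backdoor_set
#' @return A nonempty character vector, or `NULL` when none qualifies.
#' @export
find_frontdoor_set <- function(g, exposure, outcome) {
  check_query_nodes(g, exposure, outcome)
  cand <- sort(setdiff(observed_nodes(g), c(exposure, outcome)))
  if (!length(cand)) return(NULL)
  g_out_x <- mutilate(g, underline = exposure)
  for (k in 1:length(cand)) {
    for (m in subsets_of_size(cand, k)) {
      intercepts <- !has_directed_path(g, exposure, outcome, avoiding = m)
      if (!intercepts) next
      if (!d_separated(g_out_x, exposure, m, character(0))) next
      g_out_m <- mutilate(g, underline = m)
      if (!d_separated(g_out_m, m, outcome, exposure)) next
      return(m)
    }
  }
  NULL
}

#' Search for an instrumental variable
#'
#' An instrument is an observed node with an arrow into the exposure, no
#' arrow into the outcome, and no open path to the outcome once the
#' exposure's outgoing edges are removed (the exclusion restriction: the
#' instrument moves the outcome only through the exposure). The
#' lexicographically first qualifying node is returned.
#'
#' @inheritParams find_backdoor_set
#' @return A single node label, or `NULL`.
#' @export
find_instrument <- function(g, exposure, outcome) {
  check_query_nodes(g, exposure, outcome)
  cand <- sort(setdiff(observed_nodes(g), c(exposure, outcome)))
  g_out_x <- mutilate(g, underline = exposure)
  has_edge <- function(a, b) any(g$edges[, 1L] == a & g$edges[, 2L] == b)
  for (i in cand) {
    if (!has_edge(i, exposure)) next
    if (has_edge(i, outcome)) next
    if (!d_separated(g_out_x, i, outcome, character(0))) next
    return(i)
  }
  NULL
}

check_query_nodes <- function(g, exposure, outcome) {
  check_nodes(g, c(exposure, outcome))
  if (identical(exposure, outcome)) stop("exposure and outcome must differ")
  if (exposure %in% g$latent || outcome %in% g$latent) {
    stop("exposure and outcome must be observed")
  }
  invisible(TRUE)
}

subsets_of_size <- function(x, k) {
  if (k == 0L) return(list(character(0)))
  if (k > length(x)) return(list())
  # combn on a sorted vector enumerates in lexicographic order
  idx <- utils::combn(length(x), k, simplify = FALSE)
  lapply(idx, function(i) x[i])
}

#' Identify the interventional estimand P(y | do(x))
#'
#' Reduces the causal query `P(outcome | do(exposure))` to a do-free
#' expression over observed variables by trying, in order: (1) no open
#' back-door path, giving the plain conditional `P(y | x)`; (2) a back-door
#' adjustment set `S`, giving `sum_s P(y | x, s) P(s)`; (3) a front-door
#' mediator set `M`, giving `sum_m P(m | x) sum_{x'} P(x') P(y | x', m)`;
#' (4) an instrumental variable (no nonparametric estimand; estimation is
#' deferred to the linear Wald estimator, [iv_wald_estimate()]); otherwise
#' the effect is reported as unidentified, in which case only a randomized
#' experiment can settle the question.
#'
#' For patterns (1)-(3) the estimand is not asserted but *derived*: the query
#' is rewritten step by step with [expand_term()] and [apply_rule()], each
#' do-calculus rule application guarded by its independence check on the
#' mutilated graph, and the ordered steps are returned as a trace that
#' [replay_trace()] can re-execute.
#'
#' @inheritParams find_backdoor_set
#' @return An object of class `causal_identification`: a list with elements
#'   `pattern` (one of `"no-confounding"`, `"backdoor"`, `"frontdoor"`,
#'   `"instrument"`, `"unidentified"`), `auxiliary` (adjustment/mediator set
#'   or instrument), `estimand` (a do-free `prob_expr`, or `NULL`), `trace`,
#'   `query`, `exposure`, `outcome`. The estimand's free symbols are `x`
#'   (exposure level) and `y` (outcome level).
#' @examples
#' g <- causal_graph(list(c("U", "X"), c("X", "Z"), c("Z", "Y"), c("U", "Y")),
#'                   latent = "U")
#' identify_effect(g, "X", "Y")
#' @export
identify_effect <- function(g, exposure, outcome) {
  check_query_nodes(g, exposure, outcome)
  if (outcome %in% ancestors_of(g, exposure)) {
    stop("outcome is an ancestor of exposure: effect direction ill-posed")
  }
  query <- p_term(c(y = outcome), do = c(x = exposure))

  result <- function(pattern, auxiliary, steps = NULL, expr = NULL) {
    if (!is.null(expr)) {
      stopifnot(is_do_free(expr))
      attr(expr, "last_step") <- NULL
    }
    structure(list(pattern = pattern, exposure = exposure, outcome = outcome,
                   auxiliary = auxiliary, estimand = expr, trace = steps,
                   query = query),
              class = "causal_identification")
  }
  take <- function(expr, steps) {
    steps[[length(steps) + 1L]] <- attr(expr, "last_step")
    steps
  }

  # (1) no open back-door: do(x) exchanges directly for observing x
  if (rule2_check(g, outcome, exposure)) {
    expr <- apply_rule(query, integer(0), "rule2", g, z = c(x = exposure))
    return(result("no-confounding", character(0), take(expr, list()), expr))
  }

  # (2) back-door adjustment
  s <- find_backdoor_set(g, exposure, outcome)
  if (!is.null(s)) {
    s_atoms <- stats::setNames(s, paste0("s", seq_along(s)))
    steps <- list()
    expr <- expand_term(query, integer(0), s_atoms)
    steps <- take(expr, steps)
    pre <- rep(1L, length(s))
    expr <- apply_rule(expr, c(pre, 1L), "rule3", g, z = c(x = exposure))
    steps <- take(expr, steps)
    expr <- apply_rule(expr, c(pre, 2L), "rule2", g, z = c(x = exposure))
    steps <- take(expr, steps)
    return(result("backdoor", s, steps, expr))
  }

  # (3) front-door mediation, mirroring the classic seven-step derivation
  m <- find_frontdoor_set(g, exposure, outcome)
  if (!is.null(m)) {
    fd <- tryCatch(derive_frontdoor(g, query, exposure, outcome, m),
                   error = function(e) NULL)
    if (!is.null(fd)) {
      return(result("frontdoor", m, fd$steps, fd$expr))
    }
  }

  # (4) instrumental variable: linear estimation only
  i <- find_instrument(g, exposure, outcome)
  if (!is.null(i)) return(result("instrument", i))

  result("unidentified", character(0))
}

# The seven-step front-door derivation:
#   P(y|do x)
#   = sum_m P(m|do x) P(y|do x, m)              [bayes-expand]
#   = sum_m P(m|do x) P(y|do x, do m)           [rule 2, m: obs -> do]
#   = sum_m P(m|x)    P(y|do x, do m)           [rule 2, x: do -> obs]
#   = sum_m P(m|x)    P(y|do m)                 [rule 3, drop do x]
#   = sum_m P(m|x) sum_{x'} P(x'|do m) P(y|do m, x')   [bayes-expand]
#   = sum_m P(m|x) sum_{x'} P(x'|do m) P(y|m, x')      [rule 2, m -> obs]
#   = sum_m P(m|x) sum_{x'} P(x')      P(y|m, x')      [rule 3, drop do m]
derive_frontdoor <- function(g, query, exposure, outcome, m) {
  m_atoms <- stats::setNames(m, paste0("m", seq_along(m)))
  x_atom <- c(x = exposure)
  x2_atom <- c(x2 = exposure)
  pre <- rep(1L, length(m))
  steps <- list()
  take <- function(expr) {
    steps[[length(steps) + 1L]] <<- attr(expr, "last_step")
    expr
  }
  expr <- take(expand_term(query, integer(0), m_atoms))
  expr <- take(apply_rule(expr, c(pre, 2L), "rule2", g, m_atoms, "to_do"))
  expr <- take(apply_rule(expr, c(pre, 1L), "rule2", g, x_atom, "to_obs"))
  expr <- take(apply_rule(expr, c(pre, 2L), "rule3", g, x_atom, "drop"))
  expr <- take(expand_term(expr, c(pre, 2L), x2_atom))
  expr <- take(apply_rule(expr, c(pre, 2L, 1L, 2L), "rule2", g, m_atoms,
                          "to_obs"))
  expr <- take(apply_rule(expr, c(pre, 2L, 1L, 1L), "rule3", g, m_atoms,
                          "drop"))
  list(expr = expr, steps = steps)
}

#' @export
print.causal_identification <- function(x, ...) {
  cat("causal identification for P(", x$outcome, " | do(", x$exposure,
      "))\n", sep = "")
  cat("  pattern:   ", x$pattern, "\n", sep = "")
  if (length(x$auxiliary)) {
    cat("  auxiliary: ", paste(x$auxiliary, collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$estimand)) {
    cat("  estimand:  ", format(x$estimand), "\n", sep = "")
    cat("  derived in ", length(x$trace), " steps (",
        paste(vapply(x$trace, `[[`, "", "rule"), collapse = ", "), ")\n",
        sep = "")
  } else if (x$pattern == "instrument") {
    cat("  no nonparametric estimand; use the linear Wald estimator\n")
  } else if (x$pattern == "unidentified") {
    cat("  not identified from this graph; a randomized experiment is needed\n")
  }
  invisible(x)
}
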