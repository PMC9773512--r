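#' Discrete probability tables
#'
#' A `prob_table` stores a joint distribution over discrete variables as a
#' full grid of level combinations with nonnegative weights normalized to
#' sum to one. All levels are kept as character strings; numeric cohort
#' values are coerced on entry and compared as strings throughout, so `"0"`
#' and `"1"` are stable level names for binaries.
#'
#' @param assignments Data frame of level combinations (one column per
#'   variable).
#' @param p Numeric weights, recycled rows aggregated.
#' @param levels Optional named list fixing the level set of each variable;
#'   defaults to the sorted observed values.
#' @return An object of class `prob_table` with elements `vars`, `levels`,
#'   `grid`, `p`.
#' @export
prob_table <- function(assignments, p, levels = NULL) {
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  if (!nrow(assignments) || !ncol(assignments)) stop("empty table")
  assignments[] <- lapply(assignments, as.character)
  if (length(p) != nrow(assignments)) stop("p must match the rows")
  if (any(p < 0) || anyNA(p)) stop("weights must be nonnegative")
  vars <- names(assignments)
  if (is.null(levels)) {
    levels <- lapply(assignments, function(col) sort(unique(col)))
  } else {
    levels <- lapply(levels, as.character)
    stopifnot(setequal(names(levels), vars))
    levels <- levels[vars]
  }
  # aggregate onto the full grid
  grid <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(df) do.call(paste, c(df, sep = "\r"))
  w <- stats::setNames(rep(0, nrow(grid)), key(grid))
  obs_key <- key(assignments)
  if (anyNA(match(obs_key, names(w)))) stop("assignment outside declared levels")
  for (i in seq_along(obs_key)) {
    w[[obs_key[[i]]]] <- w[[obs_key[[i]]]] + p[[i]]
  }
  total <- sum(w)
  if (total <= 0) stop("total weight must be positive")
  structure(list(vars = vars, levels = levels, grid = grid,
                 p = unname(w) / total),
            class = "prob_table")
}

#' @export
print.prob_table <- function(x, ...) {
  cat("prob_table over ", paste(x$vars, collapse = ", "), " (",
      nrow(x$grid), " cells)\n", sep = "")
  df <- cbind(x$grid, p = round(x$p, 6))
  print(utils::head(df[x$p > 0, , drop = FALSE], 20), row.names = FALSE)
  invisible(x)
}

#' Empirical joint frequency table from a cohort
#'
#' Maximum-likelihood cell frequencies over the requested discrete
#' variables, with optional additive (Laplace) smoothing: `smooth` is added
#' to every cell count before normalization. Smoothing is the opt-in escape
#' from the strict positivity policy of the plug-in estimators; the default
#' of 0 reports the raw frequencies.
#'
#' @param cohort Data frame.
#' @param variables Column names to tabulate.
#' @param smooth Additive smoothing constant, >= 0 (default 0).
#' @return A [prob_table()].
#' @export
empirical_tables <- function(cohort, variables, smooth = 0) {
  if (!nrow(cohort)) stop("empty cohort")
  miss <- setdiff(variables, names(cohort))
  if (length(miss)) stop("cohort lacks variable(s): ", paste(miss, collapse = ", "))
  stopifnot(smooth >= 0)
  cols <- lapply(cohort[variables], as.character)
  for (v in variables) {
    if (length(unique(cols[[v]])) < 2L) {
      warning("variable '", v, "' has a single observed level")
    }
  }
  levels <- lapply(cols, function(col) sort(unique(col)))
  grid <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(df) do.call(paste, c(df, sep = "\r"))
  counts <- table(factor(key(as.data.frame(cols, stringsAsFactors = FALSE)),
                         levels = key(grid)))
  prob_table(grid, as.numeric(counts) + smooth, levels = levels)
}

match_rows <- function(t, assign) {
  vars <- names(assign)
  unknown <- setdiff(vars, t$vars)
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  sel <- rep(TRUE, nrow(t$grid))
  for (v in vars) sel <- sel & (t$grid[[v]] == as.character(assign[[v]]))
  sel
}

#' Query a probability table
#'
#' `pt_prob` returns the marginal probability of a partial assignment;
#' `pt_cond` the conditional probability of `target` given `given`, raising
#' a positivity error naming the stratum when the conditioning event has
#' zero mass; `pt_margin` marginalizes onto a subset of variables;
#' `pt_levels` lists a variable's levels.
#'
#' @param t A [prob_table()].
#' @param assign,target,given Named vectors / lists `c(Var = "level")`.
#' @param vars Variables to keep.
#' @param var A single variable name.
#' @export
pt_prob <- function(t, assign) {
  sum(t$p[match_rows(t, assign)])
}

#' @rdname pt_prob
#' @export
pt_cond <- function(t, target, given = NULL) {
  if (is.null(given) || !length(given)) return(pt_prob(t, target))
  pg <- pt_prob(t, given)
  if (pg <= 0) {
    stop("positivity violation: stratum {",
         paste(sprintf("%s=%s", names(given), unlist(given)), collapse = ", "),
         "} has zero probability")
  }
  pt_prob(t, c(target, given)) / pg
}

#' @rdname pt_prob
#' @export
pt_margin <- function(t, vars) {
  unknown <- setdiff(vars, t$vars)
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  prob_table(t$grid[, vars, drop = FALSE], t$p, levels = t$levels[vars])
}

#' @rdname pt_prob
#' @export
pt_levels <- function(t, var) {
  if (!var %in% t$vars) stop("unknown variable: ", var)
  t$levels[[var]]
}
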