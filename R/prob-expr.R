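#' Symbolic probability terms and expressions
#'
#' Identification manipulates symbolic expressions built from probability
#' terms `P(targets | given, do(do))`. Each of the three slots is a named
#' character vector mapping a *symbol* (the name, e.g. `"x2"`) to a *graph
#' variable* (the value, e.g. `"X"`). Symbols are bound either by an
#' enclosing summation or by the evaluation environment; identification works
#' at variable level and values are bound only at estimation time. An
#' expression is *do-free* when every leaf has an empty `do` slot, i.e. it is
#' estimable from observational data alone.
#'
#' @param targets,given,do Named character vectors `c(sym = "Var", ...)`;
#'   `targets` must be nonempty and the three slots pairwise variable-disjoint.
#' @return `p_term` returns an object of class `c("p_term", "prob_expr")`.
#' @examples
#' p_term(c(y = "Y"), do = c(x = "X")) # the query P(Y = y | do(X = x))
#' @export
p_term <- function(targets, given = NULL, do = NULL) {
  slots <- list(targets = as_atoms(targets), given = as_atoms(given),
                do = as_atoms(do))
  if (!length(slots$targets)) stop("a probability term needs targets")
  vars <- unlist(lapply(slots, unname))
  if (anyDuplicated(vars)) {
    stop("targets, given and do must involve disjoint variables")
  }
  syms <- unlist(lapply(slots, names))
  if (anyDuplicated(syms)) stop("symbols must be unique within a term")
  structure(slots, class = c("p_term", "prob_expr"))
}

as_atoms <- function(x) {
  if (is.null(x) || !length(x)) {
    return(stats::setNames(character(0), character(0)))
  }
  x <- vapply(x, as.character, "")
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("atoms must be named: c(sym = \"Var\")")
  }
  x
}

#' @rdname p_term
#' @param sym Symbol bound by the summation.
#' @param var Graph variable whose levels the summation ranges over.
#' @param child Expression under the summation.
#' @export
sum_over <- function(sym, var, child) {
  stopifnot(is.character(sym), is.character(var), inherits(child, "prob_expr"))
  if (!sym %in% expr_syms(child)) {
    stop("bound symbol '", sym, "' does not occur under the summation")
  }
  structure(list(sym = sym, var = var, child = child),
            class = c("p_sum", "prob_expr"))
}

#' @rdname p_term
#' @param ... Child expressions of a product. Products are evaluated left to
#'   right and short-circuit at an exact zero, so weight factors placed first
#'   guard conditional factors against empty strata.
#' @export
prod_of <- function(...) {
  children <- list(...)
  stopifnot(all(vapply(children, inherits, TRUE, "prob_expr")))
  structure(list(children = children), class = c("p_prod", "prob_expr"))
}

expr_syms <- function(expr) {
  if (inherits(expr, "p_term")) {
    unique(unlist(lapply(expr, names)))
  } else if (inherits(expr, "p_sum")) {
    unique(c(expr$sym, expr_syms(expr$child)))
  } else {
    unique(unlist(lapply(expr$children, expr_syms)))
  }
}

#' Is an expression free of interventional terms?
#' @param expr A `prob_expr`.
#' @return `TRUE` iff no leaf carries a `do()` slot.
#' @export
is_do_free <- function(expr) {
  if (inherits(expr, "p_term")) return(length(expr$do) == 0L)
  if (inherits(expr, "p_sum")) return(is_do_free(expr$child))
  all(vapply(expr$children, is_do_free, TRUE))
}

# Tree addressing: a path is an integer vector; on a p_sum the only child is
# index 1, on a p_prod index i selects children[[i]].
expr_get <- function(expr, path) {
  for (i in path) {
    expr <- if (inherits(expr, "p_sum")) {
      stopifnot(i == 1L)
      expr$child
    } else if (inherits(expr, "p_prod")) {
      expr$children[[i]]
    } else {
      stop("path descends below a leaf")
    }
  }
  expr
}

expr_set <- function(expr, path, value) {
  if (!length(path)) return(value)
  i <- path[1L]
  if (inherits(expr, "p_sum")) {
    stopifnot(i == 1L)
    expr$child <- expr_set(expr$child, path[-1L], value)
  } else if (inherits(expr, "p_prod")) {
    expr$children[[i]] <- expr_set(expr$children[[i]], path[-1L], value)
  } else {
    stop("path descends below a leaf")
  }
  expr
}

format_atoms <- function(atoms) {
  paste(sprintf("%s=%s", unname(atoms), names(atoms)), collapse = ",")
}

#' @export
format.prob_expr <- function(x, ...) {
  if (inherits(x, "p_term")) {
    body <- format_atoms(x$targets)
    cond <- character(0)
    if (length(x$do)) cond <- c(cond, sprintf("do(%s)", format_atoms(x$do)))
    if (length(x$given)) cond <- c(cond, format_atoms(x$given))
    if (length(cond)) {
      sprintf("P(%s | %s)", body, paste(cond, collapse = ", "))
    } else {
      sprintf("P(%s)", body)
    }
  } else if (inherits(x, "p_sum")) {
    sprintf("sum_{%s in %s} %s", x$sym, x$var, format(x$child))
  } else {
    paste0("[", paste(vapply(x$children, format, ""), collapse = " * "), "]")
  }
}

#' @export
print.prob_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Serialize an expression to plain lists / JSON
#'
#' The document form is nested objects: `{"sum": {"sym": ..., "var": ...},
#' "of": ...}`, `{"prod": [...]}` and
#' `{"P": {"targets": ..., "given": ..., "do": ...}}` with each atom as
#' `{"var": ..., "sym": ...}`.
#'
#' @param expr A `prob_expr`.
#' @return `expr_to_list` a nested list; `expr_to_json` a JSON string;
#'   `expr_from_list` the inverse of `expr_to_list`.
#' @export
expr_to_list <- function(expr) {
  atoms_list <- function(a) {
    unname(lapply(seq_along(a), function(i) {
      list(var = unname(a[[i]]), sym = names(a)[[i]])
    }))
  }
  if (inherits(expr, "p_term")) {
    list(P = list(targets = atoms_list(expr$targets),
                  given = atoms_list(expr$given),
                  do = atoms_list(expr$do)))
  } else if (inherits(expr, "p_sum")) {
    list(sum = list(sym = expr$sym, var = expr$var),
         of = expr_to_list(expr$child))
  } else {
    list(prod = lapply(expr$children, expr_to_list))
  }
}

#' @rdname expr_to_list
#' @export
expr_to_json <- function(expr) {
  jsonlite::toJSON(expr_to_list(expr), auto_unbox = TRUE)
}

#' @rdname expr_to_list
#' @param x A nested list produced by `expr_to_list`.
#' @export
expr_from_list <- function(x) {
  atoms <- function(a) {
    if (!length(a)) return(NULL)
    stats::setNames(vapply(a, `[[`, "", "var"), vapply(a, `[[`, "", "sym"))
  }
  if (!is.null(x$P)) {
    p_term(atoms(x$P$targets), atoms(x$P$given), atoms(x$P$do))
  } else if (!is.null(x$sum)) {
    sum_over(x$sum$sym, x$sum$var, expr_from_list(x$of))
  } else {
    do.call(prod_of, lapply(x$prod, expr_from_list))
  }
}
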