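#' Dichotomize a numeric variable at a cut-off
#'
#' Exposure and outcome variables are analysed as binaries: a
#' neutrophil-to-lymphocyte ratio is typically split at 5, a survival time at
#' its cohort median. Boundary handling matters for values sitting exactly on
#' the cut-off, so the direction is explicit: `"ge"` codes `value >= cutoff`
#' as 1, `"gt"` codes `value > cutoff` as 1.
#'
#' @param values Numeric vector.
#' @param cutoff Finite numeric cut-off.
#' @param direction `"ge"` (boundary inclusive) or `"gt"` (exclusive).
#' @return Integer vector of 0/1, same length as `values`.
#' @examples
#' dichotomize(c(3, 5, 7), 5, "ge") # 0 1 1
#' dichotomize(c(3, 5, 7), 5, "gt") # 0 0 1
#' @export
dichotomize <- function(values, cutoff, direction = c("ge", "gt")) {
  direction <- match.arg(direction)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    stop("cutoff must be a single finite number")
  }
  num <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(num))
  if (length(bad)) {
    stop("non-numeric value in row ", bad[1L], ": '",
         as.character(values)[bad[1L]], "'")
  }
  as.integer(if (direction == "ge") num >= cutoff else num > cutoff)
}

#' Matched pair sets
#'
#' A `matched_pair_set` holds treated/control pairs with their outcome signs:
#' +1 when the treated unit's outcome exceeds its matched control's, -1 when
#' smaller, 0 on a tie. The net-outcome statistic delta is the mean sign
#' expressed as a percentage, `(m_pos - m_neg) / |P| * 100`; a clearly
#' positive (negative) delta is evidence that the exposure pushes the outcome
#' up (down) among comparable subjects.
#'
#' @param pairs A data frame with columns `u_id`, `v_id`, `y_u`, `y_v` (or at
#'   least a `sign` column).
#' @param signs Alternatively, a bare vector of signs in `{-1, 0, 1}`.
#' @param tie_tol Absolute tolerance under which an outcome difference counts
#'   as a tie (default 0: exact equality only).
#' @return An object of class `matched_pair_set` with elements `pairs`,
#'   `m_pos`, `m_neg`, `n_zero`, `n_pairs`, `delta`.
#' @export
matched_pair_set <- function(pairs = NULL, signs = NULL, tie_tol = 0) {
  if (is.null(pairs) && is.null(signs)) stop("supply pairs or signs")
  if (is.null(pairs)) {
    signs <- as.integer(signs)
    if (!all(signs %in% c(-1L, 0L, 1L))) stop("signs must be in {-1, 0, 1}")
    pairs <- data.frame(u_id = sprintf("u%d", seq_along(signs)),
                        v_id = sprintf("v%d", seq_along(signs)),
                        y_u = rep(NA_real_, length(signs)),
                        y_v = rep(NA_real_, length(signs)), sign = signs,
                        stringsAsFactors = FALSE)
  } else if (!"sign" %in% names(pairs)) {
    d <- pairs$y_u - pairs$y_v
    pairs$sign <- ifelse(abs(d) <= tie_tol, 0L, ifelse(d > 0, 1L, -1L))
  }
  m_pos <- sum(pairs$sign == 1L)
  m_neg <- sum(pairs$sign == -1L)
  n_zero <- sum(pairs$sign == 0L)
  n <- nrow(pairs)
  structure(list(pairs = pairs, m_pos = m_pos, m_neg = m_neg,
                 n_zero = n_zero, n_pairs = n,
                 delta = if (n > 0) (m_pos - m_neg) / n * 100 else NA_real_),
            class = "matched_pair_set")
}

#' @export
print.matched_pair_set <- function(x, ...) {
  cat("matched_pair_set: ", x$n_pairs, " pairs (+1: ", x$m_pos,
      ", -1: ", x$m_neg, ", 0: ", x$n_zero, ")\n", sep = "")
  cat(sprintf("  delta = %.3f%%\n", x$delta))
  invisible(x)
}

#' Match treated units to controls on covariates
#'
#' Builds a matched-pair set from a cohort: each treated unit is paired with
#' at most one distinct control (matching without replacement) drawn
#' uniformly at random among the controls that agree exactly on every
#' `exact_on` covariate and differ by at most the stated tolerance on every
#' `caliper_on` covariate. Treated units are processed in ascending unit-id
#' order and the eligible controls are sampled with a run-local seeded
#' generator, so a fixed seed reproduces the pairing bit for bit. Treated
#' units with no eligible control are dropped from the pair set. Records
#' with missing values in any matching covariate are dropped with a warning.
#'
#' @param cohort Data frame with columns `unit_id`, `treatment` (0/1),
#'   `outcome`, plus covariates.
#' @param exact_on Covariate names that must agree exactly.
#' @param caliper_on Named numeric vector of covariate tolerances, e.g.
#'   `c(age = 5)`.
#' @param seed Integer seed for the run-local generator.
#' @param tie_tol Passed to [matched_pair_set()].
#' @return A [matched_pair_set()].
#' @export
match_pairs <- function(cohort, exact_on = character(),
                        caliper_on = NULL, seed = 1L, tie_tol = 0) {
  req <- c("unit_id", "treatment", "outcome")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  caliper_on <- if (is.null(caliper_on)) numeric(0) else unlist(caliper_on)
  if (length(caliper_on) && (is.null(names(caliper_on)) ||
                             any(!nzchar(names(caliper_on))))) {
    stop("caliper_on must be a named numeric vector")
  }
  if (any(caliper_on < 0)) stop("caliper tolerances must be >= 0")
  covs <- c(exact_on, names(caliper_on))
  unknown <- setdiff(covs, names(cohort))
  if (length(unknown)) {
    stop("unknown covariate name(s): ", paste(unknown, collapse = ", "))
  }
  if (!all(cohort$treatment %in% c(0, 1))) {
    stop("treatment must be coded 0/1")
  }
  if (length(covs)) {
    incomplete <- !stats::complete.cases(cohort[, covs, drop = FALSE])
    if (any(incomplete)) {
      warning(sum(incomplete),
              " record(s) dropped for missing matching covariates")
      cohort <- cohort[!incomplete, , drop = FALSE]
    }
  }
  treated <- cohort[cohort$treatment == 1, , drop = FALSE]
  control <- cohort[cohort$treatment == 0, , drop = FALSE]
  if (!nrow(treated) || !nrow(control)) {
    stop("cohort needs at least one treated and one control unit")
  }
  treated <- treated[order(treated$unit_id), , drop = FALSE]
  used <- rep(FALSE, nrow(control))
  out <- vector("list", nrow(treated))
  with_seed(as.integer(seed), {
    for (i in seq_len(nrow(treated))) {
      u <- treated[i, ]
      ok <- !used
      for (cv in exact_on) ok <- ok & (control[[cv]] == u[[cv]])
      for (cv in names(caliper_on)) {
        ok <- ok & (abs(as.numeric(control[[cv]]) - as.numeric(u[[cv]])) <=
                      caliper_on[[cv]])
      }
      idx <- which(ok)
      if (!length(idx)) next
      pick <- if (length(idx) == 1L) idx else sample(idx, 1L)
      used[pick] <- TRUE
      v <- control[pick, ]
      out[[i]] <- data.frame(u_id = u$unit_id, v_id = v$unit_id,
                             y_u = as.numeric(u$outcome),
                             y_v = as.numeric(v$outcome),
                             stringsAsFactors = FALSE)
    }
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) stop("no treated unit could be matched to a control")
  matched_pair_set(do.call(rbind, out), tie_tol = tie_tol)
}

# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' The matched-pair net-outcome statistic delta
#'
#' `(m_pos - m_neg) / |P| * 100`, a signed percentage in \[-100, 100\]. The
#' counts are integers, so the sum of signs is computed in integer arithmetic
#' before the single division.
#'
#' @param x A [matched_pair_set()], or a bare vector of signs.
#' @return The delta percentage.
#' @examples
#' pair_delta(matched_pair_set(signs = c(rep(1, 22), rep(-1, 10), rep(0, 3))))
#' @export
pair_delta <- function(x) {
  if (!inherits(x, "matched_pair_set")) x <- matched_pair_set(signs = x)
  if (x$n_pairs < 1L) stop("empty pair set")
  (x$m_pos - x$m_neg) / x$n_pairs * 100
}

#' Sign test for the matched-pair comparison
#'
#' Under the null hypothesis that the exposure has no effect, the number of
#' positive pairs `m` among the `s = |P| - n_zero` non-tied pairs is
#' Binomial(s, 1/2), approximated by a normal with mean `s/2` and standard
#' deviation `sqrt(s)/2`. The test statistic is `z = (m - s/2) / (sqrt(s)/2)`
#' and the null is rejected when `z` exceeds the upper `alpha/2` standard
#' normal quantile -- a one-sided decision rule against a two-sided critical
#' value, applied exactly as stated; its actual size is therefore about
#' `alpha/2`, and [sign_test_exact()] offers the orthodox two-sided exact
#' binomial test as an alternative. No continuity correction is applied. The
#' normal approximation is intended for `s > 20`; a warning is issued below.
#'
#' @param m_pos Number of positive pairs.
#' @param n_zero Number of tied (zero) pairs.
#' @param n_pairs Total number of pairs.
#' @param alpha Significance level in (0, 1).
#' @return An object of class `sign_test` with elements `s`, `mu`, `sigma`,
#'   `z`, `alpha`, `critical`, `reject`, `m_pos`, `m_neg`, `n_zero`.
#' @examples
#' sign_test(m_pos = 22, n_zero = 3, n_pairs = 35)
#' @export
sign_test <- function(m_pos, n_zero, n_pairs, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  m_pos <- as.integer(m_pos); n_zero <- as.integer(n_zero)
  n_pairs <- as.integer(n_pairs)
  m_neg <- n_pairs - n_zero - m_pos
  if (m_neg < 0L) stop("counts inconsistent: implied negative-pair count < 0")
  s <- n_pairs - n_zero
  if (s == 0L) stop("no non-tied pairs: sign test undefined")
  if (s <= 20L) {
    warning("effective sample size s = ", s,
            " <= 20: normal approximation unreliable")
  }
  mu <- s / 2
  sigma <- sqrt(s) / 2
  z <- (m_pos - mu) / sigma
  critical <- stats::qnorm(1 - alpha / 2)
  structure(list(s = s, mu = mu, sigma = sigma, z = z, alpha = alpha,
                 critical = critical, reject = z > critical,
                 m_pos = m_pos, m_neg = m_neg, n_zero = n_zero),
            class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat("sign test: s = ", x$s, ", mu = ", x$mu,
      sprintf(", sigma = %.4f, z = %.4f", x$sigma, x$z), "\n", sep = "")
  cat(sprintf("  critical Z_{alpha/2} = %.4f (alpha = %g): %s H0\n",
              x$critical, x$alpha,
              if (x$reject) "reject" else "fail to reject"))
  invisible(x)
}

#' Exact two-sided binomial sign test
#'
#' The orthodox alternative to the normal-approximation decision rule of
#' [sign_test()]: an exact two-sided binomial test of `m_pos` successes in
#' `s` non-tied pairs against p = 1/2, via [stats::binom.test()].
#'
#' @inheritParams sign_test
#' @return An `htest` object.
#' @export
sign_test_exact <- function(m_pos, n_zero, n_pairs) {
  s <- as.integer(n_pairs) - as.integer(n_zero)
  if (s <= 0L) stop("no non-tied pairs: sign test undefined")
  stats::binom.test(as.integer(m_pos), s, p = 0.5,
                    alternative = "two.sided")
}
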