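#' Read a cohort CSV
#'
#' Header row required; the columns `unit_id`, `treatment` and `outcome` are
#' mandatory, every other column is treated as a covariate (the mediator is
#' named in the run configuration).
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("unit_id", "treatment", "outcome"), names(cohort))
  if (length(miss)) {
    stop("cohort file lacks column(s): ", paste(miss, collapse = ", "))
  }
  cohort
}

#' Run configuration
#'
#' Collects everything one analysis needs: variable roles, cut-offs,
#' matching covariates, the significance level, smoothing and the seed.
#' `read_run_config` reads the same fields from a flat YAML file. Every
#' default is echoed into the run report so no behaviour is silent.
#'
#' @param exposure,outcome Graph node / cohort column names (must differ).
#' @param exposure_cutoff,outcome_cutoff Optional numeric cut-off for
#'   dichotomization; `outcome_cutoff` may be the string `"median"`. `NULL`
#'   means the column is already discrete.
#' @param exposure_direction,outcome_direction `"ge"` or `"gt"` (see
#'   [dichotomize()]). Defaults: `"ge"` for the exposure (a ratio at or
#'   above the cut-off counts as exposed), `"gt"` for the outcome (survival
#'   strictly beyond the median counts as long).
#' @param mediator Optional mediator column/node name.
#' @param match_exact Covariates that must match exactly.
#' @param match_caliper Named numeric tolerances (an unnamed `"age"` entry
#'   gets the default +/- 5 years caliper).
#' @param alpha Significance level in (0, 1).
#' @param smooth Additive smoothing for [empirical_tables()], >= 0.
#' @param seed Integer seed.
#' @param cohort,graph File paths (optional when objects are passed to
#'   [run_pipeline()] directly).
#' @return An object of class `run_config`.
#' @export
run_config <- function(exposure, outcome, exposure_cutoff = NULL,
                       exposure_direction = "ge", outcome_cutoff = NULL,
                       outcome_direction = "gt", mediator = NULL,
                       match_exact = character(), match_caliper = NULL,
                       alpha = 0.05, smooth = 0, seed = 1L,
                       cohort = NULL, graph = NULL) {
  if (identical(exposure, outcome)) stop("exposure and outcome must differ")
  stopifnot(alpha > 0, alpha < 1, smooth >= 0)
  if (!is.null(match_caliper)) {
    match_caliper <- unlist(match_caliper)
    nm <- names(match_caliper) %||% rep("", length(match_caliper))
    fix <- !nzchar(nm) & match_caliper == "age"
    if (any(fix)) { # bare "age" entry: default caliper of +/- 5 years
      nm[fix] <- "age"
      match_caliper[fix] <- 5
    }
    names(match_caliper) <- nm
    match_caliper <- stats::setNames(as.numeric(match_caliper), nm)
  }
  structure(list(exposure = exposure, outcome = outcome,
                 exposure_cutoff = exposure_cutoff,
                 exposure_direction = exposure_direction,
                 outcome_cutoff = outcome_cutoff,
                 outcome_direction = outcome_direction,
                 mediator = mediator,
                 match_exact = as.character(match_exact),
                 match_caliper = match_caliper,
                 alpha = alpha, smooth = smooth, seed = as.integer(seed),
                 cohort = cohort, graph = graph),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, y)
}

#' Run the full screening-and-quantification pipeline
#'
#' Executes the stages in order on a cohort and its causal graph:
#' dichotomize the exposure and outcome, build matched pairs, compute the
#' net-outcome delta, run the sign test, identify the interventional
#' estimand on the graph, and evaluate it from the empirical frequency
#' tables, ending in the average causal effect (control-level interventional
#' probability minus treated-level). When the sign test fails to reject, the
#' report carries a prominent `no_causal_evidence` flag but estimation still
#' runs, labelled exploratory. When the effect is unidentified the
#' estimation block instead says so and recommends a randomized experiment.
#'
#' @param config A [run_config()], or the path to a YAML config file.
#' @param cohort Optional cohort data frame (else read from
#'   `config$cohort`).
#' @param graph Optional [causal_graph()] (else read from `config$graph`).
#' @return An object of class `run_report` (a nested list; see
#'   [write_report()]).
#' @export
run_pipeline <- function(config, cohort = NULL, graph = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cohort <- cohort %||% read_cohort(config$cohort)
  graph <- graph %||% read_graph_file(config$graph)

  get_col <- function(name) {
    if (!name %in% names(cohort)) stop("cohort lacks column '", name, "'")
    cohort[[name]]
  }
  exposure_bin <- if (!is.null(config$exposure_cutoff)) {
    dichotomize(get_col(config$exposure), config$exposure_cutoff,
                config$exposure_direction)
  } else {
    v <- get_col(config$exposure)
    if (!all(v %in% c(0, 1))) stop("exposure is not binary; give a cutoff")
    as.integer(v)
  }
  out_raw <- as.numeric(get_col(config$outcome))
  outcome_cut <- config$outcome_cutoff
  if (identical(outcome_cut, "median")) outcome_cut <- stats::median(out_raw)
  outcome_bin <- if (!is.null(outcome_cut)) {
    dichotomize(out_raw, outcome_cut, config$outcome_direction)
  } else {
    if (!all(out_raw %in% c(0, 1))) stop("outcome is not binary; give a cutoff")
    as.integer(out_raw)
  }

  qed_cohort <- data.frame(unit_id = get_col("unit_id"),
                           treatment = exposure_bin, outcome = out_raw,
                           stringsAsFactors = FALSE)
  covs <- unique(c(config$match_exact, names(config$match_caliper)))
  for (cv in covs) qed_cohort[[cv]] <- get_col(cv)
  pairs <- match_pairs(qed_cohort, exact_on = config$match_exact,
                       caliper_on = config$match_caliper, seed = config$seed)
  st <- sign_test(pairs$m_pos, pairs$n_zero, pairs$n_pairs,
                  alpha = config$alpha)

  ident <- identify_effect(graph, config$exposure, config$outcome)

  est_cohort <- data.frame(row.names = seq_along(exposure_bin))
  est_cohort[[config$exposure]] <- exposure_bin
  est_cohort[[config$outcome]] <- outcome_bin
  table_vars <- c(config$exposure, config$outcome)
  if (!is.null(config$mediator)) {
    est_cohort[[config$mediator]] <- get_col(config$mediator)
    table_vars <- c(table_vars, config$mediator)
  }
  for (v in ident$auxiliary) {
    if (!v %in% table_vars) {
      est_cohort[[v]] <- get_col(v)
      table_vars <- c(table_vars, v)
    }
  }
  tab <- empirical_tables(est_cohort, table_vars, smooth = config$smooth)

  estimation <- if (!is.null(ident$estimand)) {
    p_ctl <- interventional_probability(ident, tab, "0", "1")
    p_trt <- interventional_probability(ident, tab, "1", "1")
    a <- ace(p_ctl, p_trt)
    list(p_do_control = p_ctl, p_do_treated = p_trt,
         ace = a$ace, ace_percent = a$percent,
         note = if (!st$reject) "exploratory: sign test did not reject" else "")
  } else if (ident$pattern == "instrument") {
    eff <- iv_wald_estimate(tab, ident$auxiliary, config$exposure,
                            config$outcome)
    list(wald_effect = eff,
         note = paste("linear instrumental-variable estimate;",
                      "interventional probabilities not nonparametrically",
                      "identified"))
  } else {
    list(note = paste("effect not identified from this graph;",
                      "run a randomized controlled trial"))
  }

  report <- list(
    pairs = list(n_pairs = pairs$n_pairs, m_pos = pairs$m_pos,
                 m_neg = pairs$m_neg, n_zero = pairs$n_zero,
                 delta_percent = round(pairs$delta, 3)),
    sign_test = list(s = st$s, mu = st$mu, sigma = st$sigma, z = st$z,
                     alpha = st$alpha, critical = st$critical,
                     reject = st$reject),
    no_causal_evidence = !st$reject,
    identification = list(
      pattern = ident$pattern,
      auxiliary = as.list(ident$auxiliary),
      estimand = if (!is.null(ident$estimand)) {
        expr_to_list(ident$estimand)
      },
      estimand_text = if (!is.null(ident$estimand)) format(ident$estimand),
      trace = if (!is.null(ident$trace)) {
        lapply(ident$trace, function(s) {
          list(rule = s$rule, path = as.list(s$path),
               vars = as.list(s$vars), direction = s$direction)
        })
      }),
    estimation = estimation,
    provenance = list(config = unclass(config), seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("doqed"))))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  p <- x$pairs
  cat("== matched-pair screening ==\n")
  cat(sprintf("  %d pairs (+1: %d, -1: %d, 0: %d), delta = %.3f%%\n",
              p$n_pairs, p$m_pos, p$m_neg, p$n_zero, p$delta_percent))
  s <- x$sign_test
  cat(sprintf("  sign test: z = %.4f vs %.4f -> %s\n", s$z, s$critical,
              if (s$reject) "causal evidence" else "NO causal evidence"))
  cat("== identification ==\n")
  cat("  pattern: ", x$identification$pattern, "\n", sep = "")
  if (!is.null(x$identification$estimand_text)) {
    cat("  estimand: ", x$identification$estimand_text, "\n", sep = "")
  }
  cat("== estimation ==\n")
  e <- x$estimation
  if (!is.null(e$ace)) {
    cat(sprintf("  P(Y=1|do(X=0)) = %.6f\n  P(Y=1|do(X=1)) = %.6f\n",
                e$p_do_control, e$p_do_treated))
    cat(sprintf("  ACE = %.6f (%.1f%%)\n", e$ace, e$ace_percent))
  } else if (!is.null(e$wald_effect)) {
    cat(sprintf("  Wald effect = %.6f\n", e$wald_effect))
  }
  if (nzchar(e$note %||% "")) cat("  note: ", e$note, "\n", sep = "")
  invisible(x)
}

#' Write / read a run report as JSON
#'
#' Serialization is canonical (stable key order, full precision), so writing
#' a report, parsing it and re-serializing the parsed document is
#' byte-identical.
#'
#' @param report A `run_report` (or the parsed list form).
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string (invisibly when writing).
#' @export
write_report <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                     simplifyVector = FALSE)
}

#' Generate an on-disk fixture set from a synthetic preset
#'
#' Writes four files for the named [scm_preset()]: `cohort.csv` (simulated
#' observed records in the dialect [read_cohort()] expects), `graph.txt`
#' (edge list with latent flags), `config.yaml` (a ready
#' [run_config()]) and `ground_truth.json` (the exact interventional
#' probabilities and ACE). Re-running with the same arguments reproduces the
#' files byte for byte.
#'
#' @param pattern Preset name (see [scm_preset()]).
#' @param n Number of cohort records.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
make_fixtures <- function(pattern, n, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- scm_preset(pattern, seed = as.integer(seed))
  sim <- simulate_cohort(spec, n)
  obs <- setdiff(names(sim), attr(sim, "latent"))
  cohort <- data.frame(unit_id = seq_len(n))
  for (v in obs) cohort[[v]] <- as.numeric(sim[[v]])
  cohort$treatment <- as.integer(sim$X)
  cohort$outcome <- as.numeric(sim$Y)
  paths <- c(cohort = file.path(out_dir, "cohort.csv"),
             graph = file.path(out_dir, "graph.txt"),
             config = file.path(out_dir, "config.yaml"),
             ground_truth = file.path(out_dir, "ground_truth.json"))
  utils::write.csv(cohort, paths[["cohort"]], row.names = FALSE)
  write_graph_file(spec$graph, paths[["graph"]])
  mediator <- if ("Z" %in% obs) "Z"
  cfg <- list(exposure = "X", outcome = "Y", mediator = mediator,
              alpha = 0.05, smooth = 0, seed = as.integer(seed),
              cohort = paths[["cohort"]], graph = paths[["graph"]])
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  yaml::write_yaml(cfg, paths[["config"]])
  gt <- ground_truth_ace(spec, "X", "Y")
  writeLines(jsonlite::toJSON(list(
    pattern = pattern, seed = as.integer(seed),
    p_do_control = gt$p_do_control, p_do_treated = gt$p_do_treated,
    ace = gt$ace), auto_unbox = TRUE, digits = NA, pretty = TRUE),
    paths[["ground_truth"]])
  invisible(paths)
}
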