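#' Discrete structural causal models
#'
#' An SCM couples a [causal_graph()] with one finite conditional probability
#' table (mechanism) per node: the node's distribution over its levels given
#' each configuration of its parents' levels. Interventions replace a
#' mechanism by a point mass and delete the node's incoming edges, giving
#' the manipulated graph; the exact interventional distribution is then
#' computable by enumeration, which is what makes the simulator a ground
#' truth for every estimator in the package.
#'
#' Mechanisms are built with [scm_mechanism()] and validated here: every
#' node needs one, its parent list must equal the node's graph parents, and
#' every CPT row must sum to one within 1e-12.
#'
#' @param graph A [causal_graph()].
#' @param mechanisms Named list of [scm_mechanism()] objects, one per node.
#' @param seed Default integer seed for [simulate_cohort()].
#' @return An object of class `scm_spec`.
#' @export
scm_spec <- function(graph, mechanisms, seed = NULL) {
  stopifnot(inherits(graph, "causal_graph"))
  miss <- setdiff(graph$nodes, names(mechanisms))
  if (length(miss)) stop("missing mechanism(s) for: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(mechanisms), graph$nodes)
  if (length(extra)) stop("mechanism(s) for unknown node(s): ",
                          paste(extra, collapse = ", "))
  for (node in graph$nodes) {
    mech <- mechanisms[[node]]
    if (!inherits(mech, "scm_mechanism")) {
      stop("mechanism for '", node, "' must be an scm_mechanism")
    }
    if (!setequal(mech$parents, parents_of(graph, node))) {
      stop("mechanism parents for '", node, "' disagree with the graph")
    }
    for (p in mech$parents) {
      if (!identical(mechanisms[[p]]$levels, mech$parent_levels[[p]])) {
        stop("parent level mismatch between '", p, "' and mechanism of '",
             node, "'")
      }
    }
    bad <- abs(rowSums(mech$probs) - 1) > 1e-12
    if (any(bad)) {
      stop("mechanism rows for '", node, "' do not sum to 1 (row ",
           which(bad)[1L], ")")
    }
  }
  structure(list(graph = graph, mechanisms = mechanisms, seed = seed),
            class = "scm_spec")
}

#' Conditional probability table for one SCM node
#'
#' @param levels Character vector of the node's levels.
#' @param parents Character vector of parent node names (order fixes the
#'   row layout).
#' @param parent_levels Named list of the parents' level vectors.
#' @param fun Function taking a named list (one parent configuration) and
#'   returning the probability vector over `levels`; called for every row of
#'   the configuration grid (first parent varying fastest). For root nodes
#'   call with `parents = NULL` and have `fun` ignore its argument, or pass
#'   `probs` directly.
#' @param probs Alternatively, the row matrix itself.
#' @return An object of class `scm_mechanism`.
#' @examples
#' scm_mechanism(c("0", "1"), probs = matrix(c(0.7, 0.3), nrow = 1))
#' @export
scm_mechanism <- function(levels, parents = NULL, parent_levels = list(),
                          fun = NULL, probs = NULL) {
  levels <- as.character(levels)
  parents <- as.character(parents %||% character(0))
  parent_levels <- lapply(parent_levels, as.character)
  if (length(parents)) {
    stopifnot(all(parents %in% names(parent_levels)))
    parent_levels <- parent_levels[parents]
  } else {
    parent_levels <- list()
  }
  grid <- if (length(parents)) {
    expand.grid(parent_levels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(row.names = 1L)
  }
  if (is.null(probs)) {
    if (is.null(fun)) stop("supply fun or probs")
    rows <- lapply(seq_len(max(1L, nrow(grid))), function(i) {
      cfg <- if (length(parents)) as.list(grid[i, , drop = FALSE]) else list()
      as.numeric(fun(cfg))
    })
    probs <- do.call(rbind, rows)
  }
  probs <- as.matrix(probs)
  if (ncol(probs) != length(levels)) {
    stop("probs must have one column per level")
  }
  if (nrow(probs) != max(1L, nrow(grid))) {
    stop("probs must have one row per parent configuration")
  }
  if (any(probs < 0) || anyNA(probs)) stop("malformed mechanism: negative or missing probabilities")
  colnames(probs) <- levels
  structure(list(levels = levels, parents = parents,
                 parent_levels = parent_levels, probs = probs),
            class = "scm_mechanism")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorized row lookup: which CPT row does each record's parent config hit?
mech_rows <- function(mech, parent_values) {
  if (!length(mech$parents)) return(rep(1L, max(1L, nrow(parent_values))))
  grid <- expand.grid(mech$parent_levels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key <- function(df) do.call(paste, c(df, sep = "\r"))
  match(key(parent_values[, mech$parents, drop = FALSE]), key(grid))
}

# Deterministic per-node substream so adding a node never perturbs the
# draws of existing nodes under the same master seed.
node_substream <- function(master, node) {
  h <- 0
  for (k in utf8ToInt(node)) h <- (h * 131 + k) %% 2147483647
  as.integer((h * 31 + as.numeric(master)) %% 2147483647)
}

#' Simulate a cohort from an SCM
#'
#' Draws `n` independent records in topological order, each node sampled
#' from its mechanism given the already-sampled parent values. Latent nodes
#' are sampled too (they drive the dependence structure) but are flagged in
#' the `"latent"` attribute so downstream code can drop them; an analyst
#' never gets to condition on them. Each node draws from its own
#' deterministic substream of the master seed, so runs are bit-reproducible
#' and unrelated nodes' draws never interleave.
#'
#' @param spec An [scm_spec()].
#' @param n Number of records (>= 1).
#' @param seed Master seed; defaults to the spec's.
#' @return A data frame of character levels, one column per node, with
#'   attribute `"latent"`.
#' @export
simulate_cohort <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "scm_spec"), n >= 1)
  seed <- seed %||% spec$seed
  if (is.null(seed)) stop("a seed is required (spec carries none)")
  order <- topological_order(spec$graph)
  out <- as.data.frame(matrix(NA_character_, nrow = n, ncol = length(order)),
                       stringsAsFactors = FALSE)
  names(out) <- order
  for (node in order) {
    mech <- spec$mechanisms[[node]]
    u <- with_seed(node_substream(seed, node), stats::runif(n))
    rows <- mech_rows(mech, out)
    cum <- t(apply(mech$probs, 1L, cumsum))
    idx <- rowSums(u > cum[rows, , drop = FALSE]) + 1L
    out[[node]] <- mech$levels[idx]
  }
  out <- out[, spec$graph$nodes, drop = FALSE]
  attr(out, "latent") <- spec$graph$latent
  out
}

#' Exact joint distribution of an SCM by enumeration
#'
#' The product of mechanism rows over every joint level assignment, then
#' (by default) marginalized onto the observed nodes. Refuses joint state
#' spaces above one million cells.
#'
#' @param spec An [scm_spec()].
#' @param observed_only Marginalize out latent nodes (default `TRUE`).
#' @return A [prob_table()].
#' @export
exact_joint <- function(spec, observed_only = TRUE) {
  stopifnot(inherits(spec, "scm_spec"))
  levels <- lapply(spec$mechanisms, `[[`, "levels")[spec$graph$nodes]
  cells <- prod(vapply(levels, length, 1L))
  if (cells > 1e6) stop("joint state space too large (", cells, " cells)")
  grid <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (node in spec$graph$nodes) {
    mech <- spec$mechanisms[[node]]
    rows <- mech_rows(mech, grid)
    p <- p * mech$probs[cbind(rows, match(grid[[node]], mech$levels))]
  }
  keep <- if (observed_only) observed_nodes(spec$graph) else spec$graph$nodes
  prob_table(grid[, keep, drop = FALSE], p, levels = levels[keep])
}

#' Intervene on an SCM node
#'
#' Replaces the node's mechanism with a point mass at `value` and deletes
#' its incoming edges (the manipulated graph); every other mechanism is
#' untouched, so an intervention can only affect the node's descendants.
#'
#' @param spec An [scm_spec()].
#' @param node Node name.
#' @param value One of the node's levels.
#' @return A new `scm_spec`.
#' @export
intervene <- function(spec, node, value) {
  stopifnot(inherits(spec, "scm_spec"))
  check_nodes(spec$graph, node)
  mech <- spec$mechanisms[[node]]
  value <- as.character(value)
  if (!value %in% mech$levels) {
    stop("'", value, "' is not a level of node '", node, "'")
  }
  point <- matrix(as.numeric(mech$levels == value), nrow = 1L)
  spec$mechanisms[[node]] <- scm_mechanism(mech$levels, probs = point)
  spec$graph <- mutilate(spec$graph, overline = node)
  spec
}

#' Exact interventional ground truth of an SCM
#'
#' Computes `P(outcome | do(exposure = x))` exactly for the control and
#' treated exposure levels by enumerating the intervened model, and the ACE
#' as the control-level probability minus the treated-level probability
#' (see [ace()] for the sign convention).
#'
#' @param spec An [scm_spec()].
#' @param exposure,outcome Node names.
#' @param y_value Outcome level of interest.
#' @param x_treated,x_control Exposure levels.
#' @return An object of class `scm_ground_truth` with the full
#'   interventional distributions, both probabilities and the ACE.
#' @export
ground_truth_ace <- function(spec, exposure, outcome, y_value = "1",
                             x_treated = "1", x_control = "0") {
  dist_for <- function(x) {
    jt <- exact_joint(intervene(spec, exposure, x))
    m <- pt_margin(jt, outcome)
    stats::setNames(m$p, m$grid[[outcome]])
  }
  d_control <- dist_for(x_control)
  d_treated <- dist_for(x_treated)
  y_value <- as.character(y_value)
  if (!y_value %in% names(d_control)) stop("unknown outcome level: ", y_value)
  p_c <- unname(d_control[[y_value]])
  p_t <- unname(d_treated[[y_value]])
  structure(list(
    dist = list(control = d_control, treated = d_treated),
    p_do_control = p_c, p_do_treated = p_t,
    ace = p_c - p_t,
    query = list(exposure = exposure, outcome = outcome, y_value = y_value,
                 x_treated = x_treated, x_control = x_control)),
    class = "scm_ground_truth")
}

#' @export
print.scm_ground_truth <- function(x, ...) {
  q <- x$query
  cat(sprintf("P(%s=%s | do(%s=%s)) = %.6f   [control]\n",
              q$outcome, q$y_value, q$exposure, q$x_control, x$p_do_control))
  cat(sprintf("P(%s=%s | do(%s=%s)) = %.6f   [treated]\n",
              q$outcome, q$y_value, q$exposure, q$x_treated, x$p_do_treated))
  cat(sprintf("exact ACE (control - treated) = %.6f\n", x$ace))
  invisible(x)
}

#' Ready-made synthetic SCMs for the canonical identification patterns
#'
#' Four fully synthetic generative models with documented CPTs:
#'
#' * `"confounder"` -- `U -> X`, `U -> Y`, `X -> Y` with `U` observed by
#'   default: the back-door scenario.
#' * `"frontdoor"` -- `U -> X`, `U -> Y` latent, `X -> Z -> Y`: the
#'   front-door scenario with a binary mediator.
#' * `"instrument"` -- adds an observed `I -> X` to a latent-confounder
#'   pair: the instrumental-variable scenario.
#' * `"nlr_like"` -- the front-door topology shaped like an oncology cohort:
#'   binary exposure with marginal prevalence 39/169 (a high
#'   neutrophil-to-lymphocyte ratio), a four-level performance-status
#'   mediator (60/70/80/90) and a binary survival outcome, confounded by a
#'   latent severity node.
#'
#' The CPTs are fixed package constants (also shipped as JSON under
#' `inst/extdata/presets/`, with their exact ground-truth ACE beside them).
#'
#' @param pattern One of `"confounder"`, `"frontdoor"`, `"instrument"`,
#'   `"nlr_like"`.
#' @param seed Optional default seed stored in the spec.
#' @param latent_confounder Should the confounder `U` be flagged latent?
#'   Defaults to `FALSE` for `"confounder"` and `TRUE` otherwise.
#' @return An [scm_spec()].
#' @export
scm_preset <- function(pattern = c("confounder", "frontdoor", "instrument",
                                   "nlr_like"),
                       seed = NULL, latent_confounder = NULL) {
  pattern <- match.arg(pattern)
  b <- c("0", "1")
  bern <- function(p) scm_mechanism(b, probs = matrix(c(1 - p, p), nrow = 1L))
  lat_default <- pattern != "confounder"
  latent_confounder <- latent_confounder %||% lat_default
  lat <- if (latent_confounder) "U" else character(0)
  if (pattern == "confounder") {
    g <- causal_graph(list(c("U", "X"), c("U", "Y"), c("X", "Y")), latent = lat)
    mech <- list(
      U = bern(0.4),
      X = scm_mechanism(b, "U", list(U = b), function(cfg) {
        p <- if (cfg$U == "1") 0.6 else 0.2
        c(1 - p, p)
      }),
      Y = scm_mechanism(b, c("U", "X"), list(U = b, X = b), function(cfg) {
        p <- 0.2 + 0.3 * (cfg$X == "1") + 0.2 * (cfg$U == "1")
        c(1 - p, p)
      }))
  } else if (pattern == "frontdoor") {
    g <- causal_graph(list(c("U", "X"), c("U", "Y"), c("X", "Z"), c("Z", "Y")),
                      latent = lat)
    mech <- list(
      U = bern(0.5),
      X = scm_mechanism(b, "U", list(U = b), function(cfg) {
        p <- if (cfg$U == "1") 0.65 else 0.25
        c(1 - p, p)
      }),
      Z = scm_mechanism(b, "X", list(X = b), function(cfg) {
        p <- if (cfg$X == "1") 0.75 else 0.3
        c(1 - p, p)
      }),
      Y = scm_mechanism(b, c("U", "Z"), list(U = b, Z = b), function(cfg) {
        p <- 0.2 + 0.5 * (cfg$Z == "1") + 0.2 * (cfg$U == "1")
        c(1 - p, p)
      }))
  } else if (pattern == "instrument") {
    g <- causal_graph(list(c("I", "X"), c("U", "X"), c("U", "Y"), c("X", "Y")),
                      latent = if (length(lat)) lat else "U")
    mech <- list(
      I = bern(0.5),
      U = bern(0.5),
      X = scm_mechanism(b, c("I", "U"), list(I = b, U = b), function(cfg) {
        p <- 0.15 + 0.5 * (cfg$I == "1") + 0.25 * (cfg$U == "1")
        c(1 - p, p)
      }),
      Y = scm_mechanism(b, c("U", "X"), list(U = b, X = b), function(cfg) {
        p <- 0.2 + 0.4 * (cfg$X == "1") + 0.3 * (cfg$U == "1")
        c(1 - p, p)
      }))
  } else {
    kps <- c("60", "70", "80", "90")
    # marginal P(X = 1) = 39/169, the study-shaped exposure prevalence
    p_x1_u1 <- (39 / 169 - 0.7 * 0.15) / 0.3
    g <- causal_graph(list(c("U", "X"), c("U", "Y"), c("X", "Z"), c("Z", "Y")),
                      latent = lat)
    mech <- list(
      U = bern(0.3),
      X = scm_mechanism(b, "U", list(U = b), function(cfg) {
        p <- if (cfg$U == "1") p_x1_u1 else 0.15
        c(1 - p, p)
      }),
      Z = scm_mechanism(kps, "X", list(X = b), function(cfg) {
        if (cfg$X == "1") c(0.10, 0.38, 0.47, 0.05) else c(0.08, 0.27, 0.49, 0.16)
      }),
      Y = scm_mechanism(b, c("U", "Z"), list(U = b, Z = kps), function(cfg) {
        base <- c(`60` = 0.25, `70` = 0.50, `80` = 0.72, `90` = 0.88)
        p <- base[[cfg$Z]] - 0.15 * (cfg$U == "1")
        c(1 - p, p)
      }))
  }
  scm_spec(g, mech, seed = seed)
}

#' Serialize an SCM to / from JSON
#'
#' Graph edge list, latent flags, per-node CPTs (row-major) and the seed.
#'
#' @param spec An [scm_spec()].
#' @param path Optional file path; when `NULL`, the JSON string is returned.
#' @return `scm_to_json` the JSON string (invisibly when writing);
#'   `scm_from_json` the reconstructed `scm_spec`.
#' @export
scm_to_json <- function(spec, path = NULL) {
  doc <- list(
    edges = unname(apply(spec$graph$edges, 1L, as.list)),
    latent = as.list(spec$graph$latent),
    nodes = as.list(spec$graph$nodes),
    seed = spec$seed,
    mechanisms = lapply(spec$mechanisms, function(m) {
      list(levels = as.list(m$levels), parents = as.list(m$parents),
           probs = apply(m$probs, 1L, as.list, simplify = FALSE))
    }))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname scm_to_json
#' @param json JSON string or file path.
#' @export
scm_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  doc <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                            simplifyVector = FALSE)
  edges <- lapply(doc$edges, unlist)
  g <- causal_graph(edges, latent = unlist(doc$latent) %||% character(0),
                    nodes = unlist(doc$nodes) %||% character(0))
  mechs <- lapply(doc$mechanisms, function(m) {
    probs <- do.call(rbind, lapply(m$probs, unlist))
    parents <- as.character(unlist(m$parents) %||% character(0))
    pl <- stats::setNames(lapply(parents, function(p) {
      unlist(doc$mechanisms[[p]]$levels)
    }), parents)
    scm_mechanism(unlist(m$levels), parents = parents, parent_levels = pl,
                  probs = probs)
  })
  scm_spec(g, mechs, seed = doc$seed)
}
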