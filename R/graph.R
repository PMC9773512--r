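#' Construct a causal directed acyclic graph
#'
#' A `causal_graph` is the basic object all identification machinery works on:
#' a DAG whose nodes are study variables, each flagged observed or latent.
#' Latent nodes (typically unmeasured confounders, the exogenous disturbances
#' of a structural model) participate in paths exactly like observed nodes;
#' the latent flag only restricts what the identification and estimation
#' layers may condition on.
#'
#' @param edges Edges as a two-column matrix/data.frame (parent, child), or a
#'   list of length-2 vectors. May be empty.
#' @param latent Character vector of node labels to flag as latent.
#' @param nodes Optional extra (isolated) node labels.
#' @return An object of class `causal_graph` with elements `nodes`, `latent`
#'   and `edges` (a two-column character matrix).
#' @examples
#' g <- causal_graph(list(c("U", "X"), c("U", "Y"), c("X", "Y")), latent = "U")
#' g
#' @export
causal_graph <- function(edges = NULL, latent = character(), nodes = character()) {
  em <- as_edge_matrix(edges)
  labels <- unique(c(as.character(em), as.character(nodes)))
  if (any(!nzchar(labels)) || anyNA(labels)) {
    stop("node labels must be nonempty strings")
  }
  if (any(em[, 1L] == em[, 2L])) {
    bad <- em[em[, 1L] == em[, 2L], 1L][1L]
    stop("self-loop on node '", bad, "' is not allowed")
  }
  if (anyDuplicated(paste(em[, 1L], em[, 2L], sep = "\r"))) {
    em <- em[!duplicated(paste(em[, 1L], em[, 2L], sep = "\r")), , drop = FALSE]
  }
  latent <- unique(as.character(latent))
  unknown <- setdiff(latent, labels)
  if (length(unknown)) {
    stop("latent set names unknown node(s): ", paste(unknown, collapse = ", "))
  }
  g <- structure(
    list(nodes = labels, latent = latent, edges = em),
    class = "causal_graph"
  )
  cyc <- find_cycle(g)
  if (!is.null(cyc)) {
    stop("graph is cyclic: ", paste(cyc, collapse = " -> "))
  }
  g
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.list(edges) && length(edges) == 0L)) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child"))))
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    if (any(vapply(edges, length, 1L) != 2L)) {
      stop("each edge must be a (parent, child) pair")
    }
    edges <- do.call(rbind, lapply(edges, as.character))
  }
  em <- as.matrix(edges)
  if (ncol(em) != 2L) stop("edges must have two columns (parent, child)")
  storage.mode(em) <- "character"
  colnames(em) <- c("parent", "child")
  em
}

# Depth-first search for a directed cycle; returns the node sequence or NULL.
find_cycle <- function(g) {
  state <- stats::setNames(rep(0L, length(g$nodes)), g$nodes) # 0 new, 1 open, 2 done
  stack <- character()
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    state[[v]] <<- 1L
    stack <<- c(stack, v)
    for (w in children_of(g, v)) {
      if (state[[w]] == 1L) {
        i <- match(w, stack)
        result <<- c(stack[i:length(stack)], w)
        return()
      }
      if (state[[w]] == 0L) visit(w)
      if (!is.null(result)) return()
    }
    state[[v]] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in g$nodes) if (state[[v]] == 0L) visit(v)
  result
}

#' @export
print.causal_graph <- function(x, ...) {
  cat("causal_graph: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  obs <- setdiff(x$nodes, x$latent)
  cat("  observed: ", paste(sort(obs), collapse = ", "), "\n", sep = "")
  if (length(x$latent)) {
    cat("  latent:   ", paste(sort(x$latent), collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$edges)) {
    cat("  edges:    ",
        paste(x$edges[, 1L], "->", x$edges[, 2L], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Observed nodes of a causal graph
#' @param g A `causal_graph`.
#' @return Character vector of node labels not flagged latent.
#' @export
observed_nodes <- function(g) setdiff(g$nodes, g$latent)

#' @rdname observed_nodes
#' @export
latent_nodes <- function(g) g$latent

check_nodes <- function(g, nodes, what = "node") {
  nodes <- as.character(nodes)
  unknown <- setdiff(nodes, g$nodes)
  if (length(unknown)) {
    stop("unknown ", what, "(s): ", paste(unknown, collapse = ", "))
  }
  nodes
}

#' Parents and children of nodes
#' @param g A `causal_graph`.
#' @param nodes Character vector of node labels.
#' @return Character vector of parent (child) labels, deduplicated.
#' @export
parents_of <- function(g, nodes) {
  nodes <- check_nodes(g, nodes)
  unique(g$edges[g$edges[, 2L] %in% nodes, 1L])
}

#' @rdname parents_of
#' @export
children_of <- function(g, nodes) {
  nodes <- check_nodes(g, nodes)
  unique(g$edges[g$edges[, 1L] %in% nodes, 2L])
}

#' Topological order of a causal graph
#' @param g A `causal_graph`.
#' @return Character vector of node labels, parents before children.
#' @export
topological_order <- function(g) {
  indeg <- stats::setNames(rep(0L, length(g$nodes)), g$nodes)
  if (nrow(g$edges)) {
    tab <- table(g$edges[, 2L])
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  ready <- sort(names(indeg)[indeg == 0L])
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, v)
    for (w in children_of(g, v)) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) ready <- sort(c(ready, w))
    }
  }
  if (length(out) != length(g$nodes)) stop("graph is cyclic")
  out
}

#' Graph surgery: delete arrows into / out of selected nodes
#'
#' The mutilated graphs of the do-calculus: deleting every arrow pointing into
#' the nodes in `overline` gives the graph in which those nodes are set by
#' external intervention; deleting every arrow emerging from the nodes in
#' `underline` severs their downstream influence. The node set is unchanged.
#'
#' @param g A `causal_graph`.
#' @param overline Nodes whose incoming edges are removed.
#' @param underline Nodes whose outgoing edges are removed.
#' @return A new `causal_graph`.
#' @examples
#' g <- causal_graph(list(c("U", "X"), c("U", "Y"), c("X", "Y")), latent = "U")
#' mutilate(g, overline = "X") # removes U -> X only
#' @export
mutilate <- function(g, overline = character(), underline = character()) {
  overline <- check_nodes(g, overline)
  underline <- check_nodes(g, underline)
  keep <- !(g$edges[, 2L] %in% overline) & !(g$edges[, 1L] %in% underline)
  causal_graph(g$edges[keep, , drop = FALSE], latent = g$latent,
               nodes = g$nodes)
}

reachable <- function(g, from, step_fun) {
  seen <- character(0)
  frontier <- from
  while (length(frontier)) {
    nxt <- setdiff(step_fun(g, frontier), c(seen, from))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Strict ancestors / descendants of a node set
#'
#' @param g A `causal_graph`.
#' @param nodes Character vector of node labels.
#' @return All nodes with a directed path into (out of) the given set. The
#'   input nodes themselves are excluded (a DAG has no self-reaching paths).
#' @export
ancestors_of <- function(g, nodes) {
  nodes <- check_nodes(g, nodes)
  sort(reachable(g, nodes, parents_of))
}

#' @rdname ancestors_of
#' @export
descendants_of <- function(g, nodes) {
  nodes <- check_nodes(g, nodes)
  sort(reachable(g, nodes, children_of))
}

#' The set Z(W) used by do-calculus rule 3
#'
#' Rule 3 deletes an action `do(z)` when Y is separated from Z in the graph
#' with arrows removed into X and into Z(W), where Z(W) is the subset of Z
#' nodes that are not ancestors of any W node after the arrows into X have
#' already been deleted.
#'
#' @param g A `causal_graph`.
#' @param z,w Node sets.
#' @param overline_x Nodes whose incoming edges are removed before the
#'   ancestor computation.
#' @return The subset of `z` that is not an ancestor of any `w` node in the
#'   mutilated graph.
#' @export
z_not_ancestors_of_w <- function(g, z, w, overline_x = character()) {
  z <- check_nodes(g, z)
  w <- check_nodes(g, w)
  gm <- mutilate(g, overline = overline_x)
  anc_w <- ancestors_of(gm, w)
  setdiff(z, anc_w)
}

#' d-separation
#'
#' Tests whether every path between the node sets `a` and `b` is blocked by
#' the conditioning set `c` under the standard junction rules: a chain or fork
#' is blocked when its middle node is in `c`; a collider is blocked unless it
#' or one of its descendants is in `c`. Implemented as a linear-time
#' reachability sweep over (node, travel-direction) states rather than path
#' enumeration, so it scales to graphs where the number of paths explodes.
#'
#' @param g A `causal_graph`.
#' @param a,b,c Pairwise disjoint node sets (`c` may be empty).
#' @return `TRUE` iff `a` and `b` are d-separated given `c`.
#' @examples
#' chain <- causal_graph(list(c("X", "Z"), c("Z", "Y")))
#' d_separated(chain, "X", "Y", "Z") # TRUE
#' d_separated(chain, "X", "Y")     # FALSE
#' @export
d_separated <- function(g, a, b, c = character()) {
  a <- unique(check_nodes(g, a))
  b <- unique(check_nodes(g, b))
  c <- unique(check_nodes(g, c))
  if (length(intersect(a, b)) || length(intersect(a, c)) ||
      length(intersect(b, c))) {
    stop("a, b and c must be pairwise disjoint")
  }
  if (!length(a) || !length(b)) return(TRUE)
  # nodes that are in c or have a descendant in c: a collider there is open
  anc_c <- union(c, ancestors_of(g, c))
  # states: travelling "up" (arrived from a child) or "down" (from a parent)
  queue <- data.frame(node = a, dir = "up", stringsAsFactors = FALSE)
  visited <- character(0)
  while (nrow(queue)) {
    v <- queue$node[1L]
    d <- queue$dir[1L]
    queue <- queue[-1L, , drop = FALSE]
    key <- paste(v, d)
    if (key %in% visited) next
    visited <- c(visited, key)
    if (v %in% b) return(FALSE)
    grow <- function(nodes, dir) {
      if (length(nodes)) {
        queue <<- rbind(queue, data.frame(node = nodes, dir = dir,
                                          stringsAsFactors = FALSE))
      }
    }
    if (d == "up" && !(v %in% c)) {
      grow(parents_of(g, v), "up")
      grow(children_of(g, v), "down")
    } else if (d == "down") {
      if (!(v %in% c)) grow(children_of(g, v), "down")
      if (v %in% anc_c) grow(parents_of(g, v), "up")
    }
  }
  TRUE
}

has_directed_path <- function(g, from, to, avoiding = character()) {
  if (from %in% avoiding) return(FALSE)
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- setdiff(children_of(g, frontier), c(seen, avoiding))
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Read / write a causal graph as a plain-text edge list
#'
#' One `parent<TAB>child` edge per line (any whitespace accepted on read); an
#' optional line `latent: U1,U2` declares latent nodes; `#` starts a comment;
#' an optional line `node: A` declares an isolated node.
#'
#' @param path File path.
#' @param g A `causal_graph` (for writing).
#' @return `read_graph_file` returns a `causal_graph`; `write_graph_file`
#'   returns `path` invisibly.
#' @export
read_graph_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  latent <- character(0)
  nodes <- character(0)
  edges <- list()
  for (ln in lines) {
    if (grepl("^latent\\s*:", ln)) {
      val <- sub("^latent\\s*:", "", ln)
      latent <- c(latent, trimws(strsplit(val, "[,\\s]+", perl = TRUE)[[1L]]))
      latent <- latent[nzchar(latent)]
    } else if (grepl("^node\\s*:", ln)) {
      val <- sub("^node\\s*:", "", ln)
      nodes <- c(nodes, trimws(strsplit(val, "[,\\s]+", perl = TRUE)[[1L]]))
      nodes <- nodes[nzchar(nodes)]
    } else {
      parts <- strsplit(ln, "\\s+")[[1L]]
      if (length(parts) != 2L) {
        stop("malformed edge line: '", ln, "' (expected 'parent<TAB>child')")
      }
      edges[[length(edges) + 1L]] <- parts
    }
  }
  causal_graph(edges, latent = latent, nodes = nodes)
}

#' @rdname read_graph_file
#' @export
write_graph_file <- function(g, path) {
  lines <- character(0)
  if (length(g$latent)) {
    lines <- c(lines, paste0("latent: ", paste(sort(g$latent), collapse = ",")))
  }
  iso <- setdiff(g$nodes, unique(as.character(g$edges)))
  if (length(iso)) lines <- c(lines, paste0("node: ", sort(iso)))
  if (nrow(g$edges)) {
    lines <- c(lines, paste(g$edges[, 1L], g$edges[, 2L], sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
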