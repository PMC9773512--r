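# Brute-force d-separation oracle: enumerate every simple undirected path
# between the sets and test blocking junction by junction. Exponential, but
# the graphs it is used on have at most 6 nodes. Kept deliberately
# independent of the reachability algorithm in the package.
oracle_d_separated <- function(g, a, b, c = character()) {
  edges <- g$edges
  has_edge <- function(p, q) any(edges[, 1L] == p & edges[, 2L] == q)
  nbrs <- function(v) {
    unique(c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L]))
  }
  opens_collider <- function(m) {
    m %in% c || length(intersect(descendants_of(g, m), c)) > 0L
  }
  active <- FALSE
  dfs <- function(path) {
    if (active) return()
    v <- path[length(path)]
    if (v %in% b && length(path) >= 2L) {
      ok <- TRUE
      if (length(path) > 2L) {
        for (i in 2:(length(path) - 1L)) {
          m <- path[i]
          collider <- has_edge(path[i - 1L], m) && has_edge(path[i + 1L], m)
          blocked <- if (collider) !opens_collider(m) else m %in% c
          if (blocked) { ok <- FALSE; break }
        }
      }
      if (ok) active <<- TRUE
      return()
    }
    for (w in nbrs(v)) if (!(w %in% path)) dfs(c(path, w))
  }
  for (s in a) { if (!active) dfs(s) }
  !active
}

# Random DAG on <= max_n nodes: random topological order, each forward pair
# becomes an edge with probability p_edge.
random_dag <- function(max_n = 6L, p_edge = 0.4) {
  n <- sample(2:max_n, 1L)
  labels <- sample(LETTERS[1:n])
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < p_edge) {
        edges[[length(edges) + 1L]] <- c(labels[i], labels[j])
      }
    }
  }
  causal_graph(edges, nodes = labels)
}

# pick a random disjoint (a, b, c) triple of singletons / small sets
random_dsep_query <- function(g) {
  nodes <- sample(g$nodes)
  a <- nodes[1L]
  b <- nodes[2L]
  rest <- nodes[-(1:2)]
  k <- if (length(rest)) sample(0:length(rest), 1L) else 0L
  c <- if (k > 0L) rest[seq_len(k)] else character(0)
  list(a = a, b = b, c = c)
}

# Mediation graph with a latent confounder: U -> X, U -> Y, X -> Z, Z -> Y.
# The front-door scenario every derivation test uses.
frontdoor_graph <- function(latent = "U") {
  causal_graph(list(c("U", "X"), c("U", "Y"), c("X", "Z"), c("Z", "Y")),
               latent = latent)
}
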