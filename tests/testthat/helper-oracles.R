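# Independent oracles used across the test files. These deliberately avoid
# the package's own algorithms: d-separation is checked by exhaustive path
# enumeration with the textbook blocking rules, the Lyapunov solver by
# fixed-point iteration, and backdoor paths by filtering a brute-force
# path enumeration.

# all simple paths between a and b over an edge matrix, ignoring direction
oracle_all_paths <- function(edges, a, b) {
  nbrs <- function(v) unique(c(edges[edges[, 1] == v, 2],
                               edges[edges[, 2] == v, 1]))
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == b) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in setdiff(nbrs(v), path)) walk(c(path, w))
  }
  walk(a)
  out
}

oracle_descendants <- function(edges, v) {
  seen <- v
  repeat {
    nxt <- setdiff(edges[edges[, 1] %in% seen, 2], seen)
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
  }
  seen
}

# is a single path active given Z? (collider in/ancestor-of Z opens,
# non-collider in Z blocks)
oracle_path_active <- function(edges, path, Z) {
  if (length(path) < 3) return(TRUE)
  anz <- unique(unlist(lapply(Z, function(z) {
    anc <- z
    repeat {
      nxt <- setdiff(edges[edges[, 2] %in% anc, 1], anc)
      if (length(nxt) == 0) break
      anc <- c(anc, nxt)
    }
    anc
  })))
  for (i in 2:(length(path) - 1)) {
    prev <- path[i - 1]; v <- path[i]; nxt <- path[i + 1]
    into_prev <- any(edges[, 1] == prev & edges[, 2] == v)
    into_next <- any(edges[, 1] == nxt & edges[, 2] == v)
    collider <- into_prev && into_next
    if (collider) {
      if (!(v %in% anz)) return(FALSE)
    } else {
      if (v %in% Z) return(FALSE)
    }
  }
  TRUE
}

# d-separation by brute force over all simple paths of the latent-expanded
# graph
oracle_d_separated <- function(graph, A, B, Z) {
  ex <- panelcause:::latent_expand(graph)
  for (a in A) for (b in B) {
    for (path in oracle_all_paths(ex$directed, a, b)) {
      if (oracle_path_active(ex$directed, path, Z)) return(FALSE)
    }
  }
  TRUE
}

# random DAG over `labels` with edge probability prob (edges respect a
# random topological order)
random_dag <- function(labels, prob = 0.3) {
  ord <- sample(labels)
  edges <- NULL
  for (i in seq_along(ord)) for (j in seq_along(ord)) {
    if (i < j && stats::runif(1) < prob)
      edges <- rbind(edges, c(ord[i], ord[j]))
  }
  if (is.null(edges)) edges <- matrix(character(), 0, 2)
  causal_graph(labels, edges)
}

# random acyclic linear Gaussian model over a topological order
random_linear_model <- function(p = 5, edge_prob = 0.4) {
  labels <- paste0("V", seq_len(p))
  edges <- list()
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j && stats::runif(1) < edge_prob)
      edges[[length(edges) + 1L]] <-
        list(labels[i], labels[j], stats::runif(1, -1, 1))
  }
  psi <- lapply(seq_len(p), function(i)
    list(labels[i], labels[i], stats::runif(1, 0.5, 2)))
  model_spec(labels, edges, psi)
}

table1_lag_matrix <- function() {
  pr <- insulin_glucose_params()
  matrix(c(pr$c_xx, pr$c_yx, pr$c_xy, pr$c_yy), 2, 2)
}

# blocking in the treatment-out-edges-removed graph, via the brute-force
# path oracle (independent of the package's Bayes-ball implementation)
d_separated_backdoor <- function(graph, x, y, Z) {
  keep <- !(graph$directed[, 1] == x)
  g2 <- causal_graph(graph$nodes, graph$directed[keep, , drop = FALSE],
                     graph$bidirected)
  oracle_d_separated(g2, x, y, Z)
}
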