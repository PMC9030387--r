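#' Causal graph with directed and bidirected edges
#'
#' A light container for the graphical structure of a model: node labels,
#' directed edges, and bidirected edges (each standing for an unobserved
#' common cause of its endpoints). All identification routines operate on
#' the latent expansion of the graph, in which every bidirected edge a <-> b
#' is replaced by a fresh latent common parent `.u_a_b` with edges into a
#' and b; the expanded graph must be (and is checked to be) a DAG.
#'
#' @param nodes character vector of node labels.
#' @param directed two-column matrix or data frame of directed edges
#'   (from, to).
#' @param bidirected two-column matrix or data frame of bidirected edges
#'   (unordered pairs); may be empty.
#' @return an object of class `causal_graph`.
#' @seealso [as_causal_graph()], [d_separated()], [backdoor_paths()],
#'   [minimal_adjustment_sets()]
#' @export
causal_graph <- function(nodes, directed, bidirected = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicated node labels")
  directed <- as_pair_matrix(directed)
  bidirected <- as_pair_matrix(bidirected)
  unknown <- setdiff(unique(c(directed, bidirected)), nodes)
  if (length(unknown) > 0)
    stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
  g <- structure(list(nodes = nodes, directed = directed,
                      bidirected = bidirected),
                 class = "causal_graph")
  # acyclicity of the directed part (the expansion adds only source nodes,
  # so it cannot introduce cycles)
  topological_order(list(variables = nodes,
                         directed_edges = data.frame(
                           from = directed[, 1], to = directed[, 2],
                           coef = 0, stringsAsFactors = FALSE)))
  g
}

as_pair_matrix <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0))
    return(matrix(character(), 0, 2))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.character(x) && is.null(dim(x)) && length(x) == 2)
    x <- matrix(x, 1, 2)
  x <- matrix(as.character(x), ncol = 2)
  x
}

#' @export
print.causal_graph <- function(x, ...) {
  cat("Causal graph:", length(x$nodes), "nodes,", nrow(x$directed),
      "directed and", nrow(x$bidirected), "bidirected edge(s)\n")
  invisible(x)
}

#' Extract the causal graph of a model
#'
#' Directed edges are the structural edges of the model; every nonzero
#' off-diagonal entry of the error covariance becomes a bidirected edge.
#'
#' @param model a [model_spec()].
#' @return a [causal_graph()].
#' @export
as_causal_graph <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  vars <- model$variables
  psi <- model$error_cov
  bi <- which(upper.tri(psi) & psi != 0, arr.ind = TRUE)
  causal_graph(vars,
               cbind(model$directed_edges$from, model$directed_edges$to),
               cbind(vars[bi[, 1]], vars[bi[, 2]]))
}

# Replace each bidirected edge by a fresh latent common parent. Returns a
# list(nodes, directed, synthetic) where `synthetic` are the added parents.
latent_expand <- function(graph) {
  dir <- graph$directed
  synthetic <- character(0)
  if (nrow(graph$bidirected) > 0) {
    for (i in seq_len(nrow(graph$bidirected))) {
      a <- graph$bidirected[i, 1]; b <- graph$bidirected[i, 2]
      u <- paste0(".u_", a, "_", b)
      synthetic <- c(synthetic, u)
      dir <- rbind(dir, c(u, a), c(u, b))
    }
  }
  list(nodes = c(graph$nodes, synthetic), directed = dir,
       synthetic = synthetic)
}

parents_of <- function(dir, v) dir[dir[, 2] == v, 1]
children_of <- function(dir, v) dir[dir[, 1] == v, 2]

# all descendants of `v` (including v) in an edge matrix
descendants_of <- function(dir, v) {
  seen <- v
  frontier <- v
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(lapply(frontier, children_of, dir = dir))),
                   seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

ancestors_of <- function(dir, vs) {
  seen <- vs
  frontier <- vs
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(lapply(frontier, parents_of, dir = dir))),
                   seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Test d-separation
#'
#' Are the node sets `A` and `B` d-separated given `Z` in the graph? The
#' test runs on the latent expansion of the graph (bidirected edges become
#' explicit common parents) using the standard reachability ("Bayes-ball")
#' scheme: a path is blocked iff it contains a non-collider in `Z` or a
#' collider with no descendant in `Z`.
#'
#' For the linear Gaussian models in this package, d-separation of A and B
#' given Z implies a vanishing partial covariance in the implied joint
#' distribution.
#'
#' @param graph a [causal_graph()].
#' @param A,B,Z disjoint character vectors of node labels (`Z` may be
#'   empty).
#' @return `TRUE` if every path between A and B is blocked by Z.
#' @export
d_separated <- function(graph, A, B, Z = character()) {
  stopifnot(inherits(graph, "causal_graph"))
  A <- as.character(A); B <- as.character(B); Z <- as.character(Z)
  unknown <- setdiff(c(A, B, Z), graph$nodes)
  if (length(unknown) > 0)
    stop("unknown node label(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(A, B)) > 0 || length(intersect(A, Z)) > 0 ||
      length(intersect(B, Z)) > 0)
    stop("A, B and Z must be disjoint")
  ex <- latent_expand(graph)
  !reachable_given(ex$directed, A, B, Z)
}

# Reachability along active trails (Koller & Friedman Alg. 3.1). States are
# (node, direction): "up" = entered from a child, "down" = from a parent.
reachable_given <- function(dir, A, B, Z) {
  anz <- ancestors_of(dir, Z)
  queue <- lapply(A, function(a) c(a, "up"))
  visited <- character(0)
  while (length(queue) > 0) {
    st <- queue[[1]]; queue <- queue[-1]
    key <- paste(st, collapse = "|")
    if (key %in% visited) next
    visited <- c(visited, key)
    v <- st[1]; d <- st[2]
    if (!(v %in% Z) && v %in% B) return(TRUE)
    if (d == "up" && !(v %in% Z)) {
      for (p in parents_of(dir, v)) queue <- c(queue, list(c(p, "up")))
      for (ch in children_of(dir, v)) queue <- c(queue, list(c(ch, "down")))
    } else if (d == "down") {
      if (!(v %in% Z))
        for (ch in children_of(dir, v)) queue <- c(queue, list(c(ch, "down")))
      if (v %in% anz)
        for (p in parents_of(dir, v)) queue <- c(queue, list(c(p, "up")))
    }
  }
  FALSE
}

# Enumerate all simple paths (any edge orientation) between x and y on an
# edge matrix; each path is the node sequence. Exponential, fine for the
# small graphs this package handles.
all_paths <- function(dir, x, y) {
  nbrs <- function(v) unique(c(children_of(dir, v), parents_of(dir, v)))
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in setdiff(nbrs(v), path)) walk(c(path, w))
  }
  walk(x)
  out
}

#' Enumerate backdoor paths
#'
#' All simple paths from `treatment` to `outcome` on the latent-expanded
#' graph whose first edge points *into* the treatment. These are the
#' pathways through which a naive regression of outcome on treatment picks
#' up spurious (non-causal) association. Paths through the synthetic
#' common parents introduced for bidirected edges are reported with those
#' parents (named `.u_a_b`) in the node sequence.
#'
#' @param graph a [causal_graph()].
#' @param treatment,outcome distinct node labels.
#' @return list of character vectors (node sequences), ordered
#'   lexicographically.
#' @examples
#' g <- as_causal_graph(insulin_glucose_model())
#' backdoor_paths(g, "X2", "Y3")
#' @export
backdoor_paths <- function(graph, treatment, outcome) {
  stopifnot(inherits(graph, "causal_graph"))
  if (treatment == outcome) stop("treatment and outcome must differ")
  unknown <- setdiff(c(treatment, outcome), graph$nodes)
  if (length(unknown) > 0)
    stop("unknown node label(s): ", paste(unknown, collapse = ", "))
  ex <- latent_expand(graph)
  paths <- all_paths(ex$directed, treatment, outcome)
  into_treatment <- vapply(paths, function(p) {
    any(ex$directed[, 1] == p[2] & ex$directed[, 2] == p[1])
  }, logical(1))
  paths <- paths[into_treatment]
  keys <- vapply(paths, paste, character(1), collapse = " ")
  paths[order(keys)]
}

#' Minimal backdoor adjustment sets
#'
#' All inclusion-minimal sets Z of candidate nodes that block every
#' backdoor path from `treatment` to `outcome`, i.e. that d-separate
#' treatment and outcome in the graph with the treatment's outgoing edges
#' removed. Candidates are the nodes other than treatment and outcome that
#' are not descendants of the treatment; by default latent nodes are
#' excluded, `include_latents = TRUE` admits them (in a random-intercept
#' model every adjustment set must then contain the latent intercepts).
#'
#' @param graph a [causal_graph()].
#' @param treatment,outcome distinct node labels.
#' @param include_latents logical; may latent nodes enter the sets?
#' @param latents character vector naming the latent nodes of `graph`
#'   (defaults to none; pass the model's latents when relevant).
#' @return list of character vectors, sorted by size then
#'   lexicographically; contains `character(0)` if no adjustment is needed.
#' @examples
#' g <- as_causal_graph(insulin_glucose_model())
#' minimal_adjustment_sets(g, "X2", "Y3")[[1]]  # "Y2"
#' @export
minimal_adjustment_sets <- function(graph, treatment, outcome,
                                    include_latents = FALSE,
                                    latents = character()) {
  stopifnot(inherits(graph, "causal_graph"))
  if (treatment == outcome) stop("treatment and outcome must differ")
  unknown <- setdiff(c(treatment, outcome), graph$nodes)
  if (length(unknown) > 0)
    stop("unknown node label(s): ", paste(unknown, collapse = ", "))

  ex <- latent_expand(graph)
  desc <- descendants_of(ex$directed, treatment)
  candidates <- setdiff(graph$nodes, c(treatment, outcome, desc))
  if (!include_latents) candidates <- setdiff(candidates, latents)
  candidates <- sort(candidates)

  # proper backdoor graph: drop edges out of the treatment
  keep <- !(ex$directed[, 1] == treatment)
  bdir <- ex$directed[keep, , drop = FALSE]

  blocked <- function(Z) !reachable_given(bdir, treatment, outcome, Z)

  valid <- list()
  sets_by_size <- function(k) {
    if (k == 0) return(list(character(0)))
    if (k > length(candidates)) return(list())
    cmb <- utils::combn(candidates, k, simplify = FALSE)
    cmb
  }
  for (k in 0:length(candidates)) {
    for (Z in sets_by_size(k)) {
      if (any(vapply(valid, function(v) all(v %in% Z), logical(1))))
        next # superset of a known valid set: not minimal
      if (blocked(Z)) valid[[length(valid) + 1L]] <- Z
    }
  }
  keys <- vapply(valid, function(v)
    sprintf("%03d %s", length(v), paste(v, collapse = " ")), character(1))
  valid[order(keys)]
}
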