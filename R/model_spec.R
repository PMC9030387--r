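#' Construct a linear Gaussian structural equation model specification
#'
#' A `model_spec` holds a fully parameterized linear structural equation
#' model: an ordered set of variable labels, directed edges with structural
#' coefficients, a symmetric error (co)variance matrix (error variances on
#' the diagonal, bidirected-edge covariances off the diagonal), intercepts,
#' and a subset of labels flagged as latent. The directed part must be
#' acyclic and the error covariance positive semidefinite.
#'
#' @param variables character vector of variable labels, in the canonical
#'   order used by all matrices derived from the model.
#' @param directed_edges data frame with columns `from`, `to`, `coef`
#'   (one row per directed edge), or a list of `list(from, to, coef)`.
#' @param error_cov symmetric numeric matrix (rows/cols in `variables`
#'   order), or a data frame / list of triplets `(a, b, value)`; omitted
#'   entries are zero.
#' @param intercepts named numeric vector of intercepts; unnamed entries
#'   default to zero (the models here are mean-centered).
#' @param latents character vector, subset of `variables`, of unobserved
#'   variables (e.g. random intercepts).
#'
#' @return an object of class `model_spec`.
#' @seealso [build_crosslagged()], [implied_moments()], [apply_do()]
#' @export
model_spec <- function(variables, directed_edges, error_cov,
                       intercepts = NULL, latents = character()) {
  variables <- as.character(variables)
  p <- length(variables)
  if (p == 0L) stop("model must contain at least one variable")
  if (anyDuplicated(variables)) stop("duplicated variable labels")

  edges <- as_edge_frame(directed_edges)
  unknown <- setdiff(unique(c(edges$from, edges$to)), variables)
  if (length(unknown) > 0)
    stop("directed edge references unknown variable(s): ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(edges[, c("from", "to")]))
    stop("duplicated directed edge")

  psi <- as_cov_matrix(error_cov, variables)

  b <- stats::setNames(numeric(p), variables)
  if (!is.null(intercepts)) {
    if (is.null(names(intercepts)) && length(intercepts) == p) {
      b[] <- intercepts
    } else {
      bad <- setdiff(names(intercepts), variables)
      if (length(bad) > 0) stop("intercept for unknown variable: ",
                                paste(bad, collapse = ", "))
      b[names(intercepts)] <- intercepts
    }
  }

  latents <- as.character(latents)
  if (length(setdiff(latents, variables)) > 0)
    stop("latent labels must be a subset of the variable labels")

  model <- structure(
    list(variables = variables, directed_edges = edges, error_cov = psi,
         intercepts = b, latents = latents),
    class = "model_spec")
  validate_model_spec(model)
  model
}

as_edge_frame <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("from", "to", "coef") %in% names(x)))
    edges <- data.frame(from = as.character(x$from), to = as.character(x$to),
                        coef = as.numeric(x$coef), stringsAsFactors = FALSE)
  } else if (is.list(x)) {
    edges <- do.call(rbind, lapply(x, function(e) {
      e <- unlist(e, use.names = FALSE)
      if (length(e) != 3) stop("each directed edge needs (from, to, coef)")
      data.frame(from = as.character(e[1]), to = as.character(e[2]),
                 coef = as.numeric(e[3]), stringsAsFactors = FALSE)
    }))
    if (is.null(edges))
      edges <- data.frame(from = character(), to = character(),
                          coef = numeric(), stringsAsFactors = FALSE)
  } else {
    stop("directed_edges must be a data frame or a list of triplets")
  }
  edges
}

as_cov_matrix <- function(x, variables) {
  p <- length(variables)
  if (is.matrix(x)) {
    if (!all(dim(x) == c(p, p)))
      stop("error_cov matrix must be ", p, " x ", p)
    psi <- x
    dimnames(psi) <- list(variables, variables)
  } else {
    psi <- matrix(0, p, p, dimnames = list(variables, variables))
    entries <- if (is.data.frame(x)) {
      lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    } else if (is.list(x)) {
      x
    } else {
      stop("error_cov must be a matrix, data frame, or list of triplets")
    }
    for (e in entries) {
      e <- unlist(e, use.names = FALSE)
      if (length(e) != 3) stop("each error_cov entry needs (a, b, value)")
      a <- as.character(e[1]); bb <- as.character(e[2]); v <- as.numeric(e[3])
      if (!a %in% variables || !bb %in% variables)
        stop("error_cov references unknown variable: ", a, " / ", bb)
      psi[a, bb] <- v
      psi[bb, a] <- v
    }
  }
  psi
}

validate_model_spec <- function(model) {
  psi <- model$error_cov
  if (max(abs(psi - t(psi))) > 1e-8 * max(1, max(abs(psi))))
    stop("error_cov is not symmetric")
  ev <- eigen((psi + t(psi)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop("error_cov is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  topological_order(model) # errors if cyclic
  invisible(model)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Linear Gaussian SEM (", length(x$variables), " variables, ",
      nrow(x$directed_edges), " directed edges, ",
      sum(x$error_cov[upper.tri(x$error_cov)] != 0), " bidirected edges)\n",
      sep = "")
  if (length(x$latents) > 0)
    cat("Latent: ", paste(x$latents, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Kahn's algorithm on the directed part; errors on a cycle.
topological_order <- function(model) {
  vars <- model$variables
  edges <- model$directed_edges
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  queue <- vars[indeg == 0L]
  order <- character(0)
  indeg2 <- indeg
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    out <- edges$to[edges$from == v]
    for (w in out) {
      indeg2[w] <- indeg2[w] - 1L
      if (indeg2[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) != length(vars))
    stop("directed part of the model contains a cycle")
  order
}

# Structural coefficient matrix C with C[target, source] = coefficient,
# so that x = C x + b + e in the variable order of the model.
coef_matrix <- function(model) {
  p <- length(model$variables)
  C <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  e <- model$directed_edges
  for (i in seq_len(nrow(e))) C[e$to[i], e$from[i]] <- e$coef[i]
  C
}

#' Implied joint distribution of a linear Gaussian SEM
#'
#' Computes the reduced form of the model: with coefficient matrix C,
#' intercept vector b and error covariance \eqn{\Psi}, the implied joint
#' distribution over all variables (including latents) is Gaussian with
#' mean \eqn{(I - C)^{-1} b} and covariance
#' \eqn{(I - C)^{-1} \Psi (I - C)^{-T}}. This is the covariance algebra
#' that underlies all interventional and conditional quantities in the
#' package.
#'
#' @param model a [model_spec()].
#' @return a [gaussian_dist()] over all model variables.
#' @examples
#' m <- insulin_glucose_model()
#' j <- implied_moments(m)
#' sqrt(j$cov["X2", "X2"])  # stationary SD of the insulin series, 11.48
#' @export
implied_moments <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  p <- length(model$variables)
  IC <- diag(p) - coef_matrix(model)
  M <- solve(IC)
  mu <- drop(M %*% model$intercepts)
  S <- M %*% model$error_cov %*% t(M)
  S <- (S + t(S)) / 2
  gaussian_dist(model$variables, mu, S)
}

#' Stationary covariance of a bivariate first-order dynamic system
#'
#' Solves the discrete Lyapunov equation \eqn{\Sigma = A \Sigma A^T + Q}
#' for the long-run (covariance-stationary) state covariance of the
#' VAR(1)-type recursion driving the panel process. Used to initialize the
#' first measurement wave at its long-term equilibrium.
#'
#' @param lag_matrix square matrix A of autoregressive and cross-lagged
#'   coefficients (state order X, Y for the bivariate panel model).
#' @param innovation_cov innovation covariance Q, same dimension.
#' @return the stationary covariance matrix.
#' @details The solution exists iff the spectral radius of A is below 1;
#'   otherwise the process has no stationary distribution and an error
#'   reporting the eigenvalue moduli is raised. Solved exactly via
#'   vectorization: \eqn{(I - A \otimes A) vec(\Sigma) = vec(Q)}.
#' @examples
#' A <- matrix(c(0.05, -0.6, 0.4, 1.2), 2, 2)
#' stationary_initial_covariance(A, diag(c(20, 40)))
#' @export
stationary_initial_covariance <- function(lag_matrix, innovation_cov) {
  A <- as.matrix(lag_matrix)
  Q <- as.matrix(innovation_cov)
  stopifnot(nrow(A) == ncol(A), all(dim(Q) == dim(A)))
  mods <- Mod(eigen(A, only.values = TRUE)$values)
  if (max(mods) >= 1)
    stop("system is not stationary: eigenvalue moduli ",
         paste(format(mods, digits = 4), collapse = ", "))
  n <- nrow(A)
  vecS <- solve(diag(n * n) - kronecker(A, A), as.vector(Q))
  S <- matrix(vecS, n, n)
  S <- (S + t(S)) / 2
  resid <- max(abs(S - A %*% S %*% t(A) - Q))
  stopifnot(resid <= 1e-8 * max(1, max(abs(S))))
  S
}

#' Read / write a model specification file
#'
#' Models are serialized as YAML (or JSON) with keys `variables`,
#' `directed_edges` (list of `[from, to, coef]`), `error_cov` (list of
#' `[a, b, value]`; variances on the "diagonal" pairs), `latents`, and
#' optionally `intercepts` (mapping label to value).
#'
#' @param path file path.
#' @return `read_model_spec` returns a [model_spec()];
#'   `write_model_spec` invisibly returns `path`.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  spec <- yaml::read_yaml(path)
  if (is.null(spec$variables)) stop("model file lacks a 'variables' key")
  model_spec(
    variables = unlist(spec$variables),
    directed_edges = if (is.null(spec$directed_edges)) list() else
      spec$directed_edges,
    error_cov = if (is.null(spec$error_cov)) list() else spec$error_cov,
    intercepts = if (is.null(spec$intercepts)) NULL else
      unlist(spec$intercepts),
    latents = if (is.null(spec$latents)) character() else
      unlist(spec$latents))
}

#' @param model a [model_spec()] to serialize.
#' @rdname read_model_spec
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "model_spec"))
  e <- model$directed_edges
  psi <- model$error_cov
  vars <- model$variables
  triplets <- list()
  for (i in seq_along(vars)) for (j in i:length(vars)) {
    if (psi[i, j] != 0)
      triplets[[length(triplets) + 1L]] <-
        list(vars[i], vars[j], psi[i, j])
  }
  out <- list(
    variables = as.list(vars),
    directed_edges = lapply(seq_len(nrow(e)), function(i)
      list(e$from[i], e$to[i], e$coef[i])),
    error_cov = triplets,
    latents = as.list(model$latents))
  if (any(model$intercepts != 0))
    out$intercepts <- as.list(model$intercepts[model$intercepts != 0])
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
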