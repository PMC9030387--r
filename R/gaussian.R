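#' Labelled multivariate normal distribution
#'
#' Container for a multivariate normal distribution over named variables:
#' a label vector, a mean vector and a symmetric covariance matrix.
#' Degenerate (zero-variance) coordinates are allowed; they arise naturally
#' for variables fixed by a do-intervention.
#'
#' @param labels character vector of variable names.
#' @param mean numeric mean vector (same length).
#' @param cov symmetric covariance matrix with eigenvalues >= -1e-8
#'   (relative); small negative eigenvalues from floating-point round-off
#'   are tolerated, genuine indefiniteness is an error.
#' @return an object of class `gaussian_dist` with elements `labels`,
#'   `mean` (named), `cov` (dimnamed).
#' @export
gaussian_dist <- function(labels, mean, cov) {
  labels <- as.character(labels)
  p <- length(labels)
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(length(mean) == p, all(dim(cov) == c(p, p)))
  scale <- max(1, max(abs(cov)))
  if (max(abs(cov - t(cov))) > 1e-8 * scale)
    stop("covariance matrix is not symmetric")
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * scale)
    stop("covariance matrix is not positive semidefinite")
  names(mean) <- labels
  dimnames(cov) <- list(labels, labels)
  structure(list(labels = labels, mean = mean, cov = cov),
            class = "gaussian_dist")
}

#' @export
print.gaussian_dist <- function(x, ...) {
  cat("Gaussian distribution over", length(x$labels), "variable(s)\n")
  tab <- data.frame(mean = x$mean, variance = diag(x$cov),
                    sd = sqrt(pmax(diag(x$cov), 0)))
  print(round(tab, 4))
  invisible(x)
}

#' Marginal of a labelled Gaussian
#'
#' @param dist a [gaussian_dist()].
#' @param labels variables to keep, in the requested order.
#' @return a [gaussian_dist()] over `labels`.
#' @export
marginal_dist <- function(dist, labels) {
  stopifnot(inherits(dist, "gaussian_dist"))
  labels <- as.character(labels)
  check_labels(dist, labels)
  gaussian_dist(labels, dist$mean[labels],
                dist$cov[labels, labels, drop = FALSE])
}

check_labels <- function(dist, labels) {
  unknown <- setdiff(labels, dist$labels)
  if (length(unknown) > 0)
    stop("unknown variable label(s): ", paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Condition a Gaussian distribution on observed values
#'
#' Gaussian conditioning via the Schur complement: for a partition
#' (a = kept, b = observed) the conditional distribution is normal with
#' mean \eqn{\mu_a + \Sigma_{ab}\Sigma_{bb}^{-1}(v - \mu_b)} and covariance
#' \eqn{\Sigma_{aa} - \Sigma_{ab}\Sigma_{bb}^{-1}\Sigma_{ba}}. Evidence may
#' include latent variables (this is how person-specific distributions are
#' obtained). Conditioned variables are dropped from the result.
#'
#' Evidence on a degenerate (zero-variance) coordinate carries no
#' information: if the stated value equals the degenerate mean the
#' coordinate is ignored, otherwise the evidence is inconsistent and an
#' error is raised. A singular (but not degenerate) evidence block is an
#' error — silent pseudo-inversion would mask specification mistakes.
#'
#' @param dist a [gaussian_dist()].
#' @param evidence named numeric vector of observed values, e.g.
#'   `c(X2 = 11.48)`.
#' @return the conditional [gaussian_dist()] over the remaining variables.
#' @examples
#' joint <- implied_moments(insulin_glucose_model())
#' condition_on(joint, c(X2 = 11.48))$mean["Y3"]
#' @export
condition_on <- function(dist, evidence) {
  stopifnot(inherits(dist, "gaussian_dist"))
  if (length(evidence) == 0) return(dist)
  if (is.null(names(evidence)) || any(names(evidence) == ""))
    stop("evidence must be a named numeric vector")
  if (anyDuplicated(names(evidence)))
    stop("duplicated evidence variable")
  b <- names(evidence)
  check_labels(dist, b)

  # Degenerate coordinates: consistent values are vacuous, others impossible.
  vb <- diag(dist$cov)[b]
  tol <- 1e-10 * max(1, max(abs(dist$cov)))
  degen <- vb <= tol
  if (any(degen)) {
    bad <- abs(evidence[degen] - dist$mean[b[degen]]) > 1e-8
    if (any(bad))
      stop("inconsistent evidence on degenerate variable(s): ",
           paste(b[degen][bad], collapse = ", "))
    evidence <- evidence[!degen]
    keep_all <- setdiff(dist$labels, b[degen])
    dist <- marginal_dist(dist, keep_all)
    if (length(evidence) == 0) return(dist)
    b <- names(evidence)
  }

  a <- setdiff(dist$labels, b)
  Sbb <- dist$cov[b, b, drop = FALSE]
  Sab <- dist$cov[a, b, drop = FALSE]
  K <- tryCatch(solve(Sbb, t(Sab)),
                error = function(e)
                  stop("evidence covariance block is singular; ",
                       "cannot condition", call. = FALSE))
  dev <- evidence[b] - dist$mean[b]
  mu <- dist$mean[a] + drop(crossprod(K, dev))
  S <- dist$cov[a, a, drop = FALSE] - Sab %*% K
  S <- (S + t(S)) / 2
  # round-off guard: clamp tiny negative variances produced by the Schur step
  d <- diag(S)
  d[d < 0 & d > -1e-8 * max(1, max(abs(S)))] <- 0
  diag(S) <- d
  gaussian_dist(a, mu, S)
}

#' Population least-squares regression implied by a Gaussian distribution
#'
#' Returns the population regression coefficients of `outcome` on
#' `predictors` under `dist`: slopes
#' \eqn{\Sigma_{bb}^{-1}\Sigma_{bo}} and the intercept implied by the
#' means. With a backdoor-sufficient adjustment set among the predictors,
#' the slope on a treatment equals the corresponding causal coefficient;
#' without it, it is the purely predictive (regression) coefficient.
#'
#' @param dist a [gaussian_dist()].
#' @param outcome single outcome label.
#' @param predictors character vector of predictor labels.
#' @return named numeric vector: `(Intercept)` followed by one slope per
#'   predictor.
#' @examples
#' joint <- implied_moments(insulin_glucose_model())
#' population_regression(joint, "Y3", c("X2", "Y2"))  # -0.6, 1.2
#' @export
population_regression <- function(dist, outcome, predictors) {
  stopifnot(inherits(dist, "gaussian_dist"), length(outcome) == 1)
  check_labels(dist, c(outcome, predictors))
  if (length(predictors) == 0)
    return(c("(Intercept)" = unname(dist$mean[outcome])))
  Sbb <- dist$cov[predictors, predictors, drop = FALSE]
  Sbo <- dist$cov[predictors, outcome, drop = FALSE]
  slopes <- tryCatch(drop(solve(Sbb, Sbo)),
                     error = function(e)
                       stop("predictor covariance block is singular ",
                            "(collinear predictors)", call. = FALSE))
  slopes <- stats::setNames(as.numeric(slopes), predictors)
  intercept <- unname(dist$mean[outcome] -
                        sum(slopes * dist$mean[predictors]))
  c("(Intercept)" = intercept, slopes)
}
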