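#' Maximum-likelihood estimation of the cross-lagged panel model
#'
#' Fits the bivariate cross-lagged panel model (homogeneous or with random
#' intercepts) to complete panel data by normal-theory covariance ML:
#' minimizes the discrepancy
#' \deqn{F(\theta) = \ln|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1})
#'   - \ln|S| - p}
#' over the free parameters, where S is the sample covariance of the
#' observed wide vector (X1..XT, Y1..YT) and \eqn{\Sigma(\theta)} the
#' model-implied covariance. The parameterization enforces the model's
#' equality constraints: time-stable autoregressive/cross-lagged
#' coefficients, time-stable innovation variances for waves t >= 2, and
#' unit latent loadings for t >= 2 (wave-1 loadings and wave-1 error
#' (co)variances free).
#'
#' Optimization uses [stats::nlminb()] from `n_starts` starting points:
#' data-driven moment starts (pooled and within-person OLS for the lagged
#' coefficients; for the random-intercept variant, wave-1 loadings start
#' at the long-run accumulation matrix \eqn{(I-\hat A)^{-1}} and the
#' latent covariance at the covariance of back-projected person means)
#' plus jittered replicates; the best solution is returned. Standard
#' errors come from the numerical Hessian of F at the optimum
#' (\eqn{cov(\hat\theta) \approx (2/n) H^{-1}}).
#'
#' @param data long- or wide-format panel data (see [simulate_panel()],
#'   [panel_to_wide()]).
#' @param T number of waves (inferred from the data when `NULL`).
#' @param heterogeneous fit the random-intercept variant?
#' @param n_starts number of optimizer starts.
#' @param seed optional seed for the start jitter (for reproducible fits).
#' @return an object of class `panelcause_fit`: list with `estimates`
#'   (named vector), `se`, `objective` (F at the optimum), `converged`,
#'   `n_persons`, `T`, `heterogeneous`.
#' @examples
#' \donttest{
#' pd <- simulate_panel(insulin_glucose_model(), 2000, seed = 7)
#' fit <- fit_crosslagged_ml(pd)
#' fit$estimates["c_yx"]  # close to -0.6
#' }
#' @export
fit_crosslagged_ml <- function(data, T = NULL, heterogeneous = FALSE,
                               n_starts = 5, seed = NULL) {
  wide <- if (all(c("person", "wave", "x", "y") %in% names(data)))
    panel_to_wide(data) else data
  if (is.null(T)) {
    T <- length(grep("^X[0-9]+$", names(wide)))
    if (T < 2) stop("could not infer the number of waves from the data")
  }
  obs <- as.vector(rbind(paste0("X", seq_len(T)), paste0("Y", seq_len(T))))
  missing_cols <- setdiff(obs, names(wide))
  if (length(missing_cols) > 0)
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  Yd <- as.matrix(wide[, obs])
  if (anyNA(Yd)) stop("estimation requires complete data")
  n <- nrow(Yd)
  par_names <- crosslagged_par_names(heterogeneous)
  if (n <= length(par_names))
    stop("need more persons than free parameters")
  S <- crossprod(sweep(Yd, 2, colMeans(Yd))) / n
  if (rcond(S) < 1e-14) stop("sample covariance matrix is singular")

  objective <- function(theta) {
    Sigma <- crosslagged_sigma(theta, T, heterogeneous)
    if (is.null(Sigma)) return(1e10)
    f <- fml_value(Sigma, S)
    if (!is.finite(f)) 1e10 else f
  }
  # Smooth counterpart without the admissibility penalty: the constrained
  # optimum can sit on the boundary of the PSD region (e.g. a wave-1 error
  # correlation of +-1), where finite differences of the penalized
  # objective step across the penalty cliff. Curvature (for standard
  # errors) is therefore measured on the smooth surface, which only
  # requires the implied full covariance to stay positive definite.
  objective_smooth <- function(theta) {
    Sigma <- crosslagged_sigma(theta, T, heterogeneous, check = FALSE)
    if (is.null(Sigma)) return(NA_real_)
    f <- fml_value(Sigma, S)
    if (!is.finite(f)) NA_real_ else f
  }

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(as.integer(seed))
  }

  starts <- crosslagged_starts(Yd, S, T, heterogeneous, n_starts)
  best <- NULL
  for (start in starts) {
    if (!is.finite(objective(start)) || objective(start) >= 1e10) next
    opt <- stats::nlminb(start, objective,
                         control = list(rel.tol = 1e-12, abs.tol = 1e-10,
                                        iter.max = 2000, eval.max = 4000))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("no optimizer start produced a finite objective")

  # polish once from the incumbent; "converged" means the objective is
  # stable under the restart (nlminb's own flag is pessimistic on the
  # flat ridges of this likelihood)
  polish <- stats::nlminb(best$par, objective,
                          control = list(rel.tol = 1e-12, abs.tol = 1e-10,
                                         iter.max = 2000, eval.max = 4000))
  converged <- (best$objective - polish$objective) <
    1e-8 * max(1, best$objective)
  if (polish$objective < best$objective) best <- polish

  theta <- stats::setNames(best$par, par_names)
  se <- rep(NA_real_, length(theta))
  names(se) <- par_names
  H <- tryCatch(stats::optimHess(best$par, objective_smooth),
                error = function(e) NULL)
  if (!is.null(H)) {
    # The likelihood can be very flat along ridges (the random-intercept
    # variant is only weakly identified at small T): eigenvalues of H that
    # are numerically zero or negative carry no curvature information.
    # Clamping them to a tiny positive floor yields correspondingly huge
    # standard errors along those directions instead of NAs.
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-10 * max(abs(ev$values), 1))
    covm <- (2 / n) * ev$vectors %*% (t(ev$vectors) / lam)
    d <- diag(covm)
    se[d > 0] <- sqrt(d[d > 0])
  }

  structure(list(estimates = theta, se = se, objective = best$objective,
                 converged = converged, n_persons = n,
                 T = T, heterogeneous = heterogeneous),
            class = "panelcause_fit")
}

crosslagged_par_names <- function(heterogeneous) {
  nm <- c("c_xx", "c_xy", "c_yx", "c_yy",
          "psi_x1x1", "psi_y1y1", "psi_x1y1", "psi_xx", "psi_yy")
  if (heterogeneous)
    nm <- c(nm, "c_x1_etax", "c_y1_etay", "c_x1_etay", "c_y1_etax",
            "psi_etax_etax", "psi_etay_etay", "psi_etax_etay")
  nm
}

# Model-implied covariance of the observed wide vector for a raw parameter
# vector (ordered as crosslagged_par_names); with `check = TRUE`, NULL
# outside the admissible region (negative variances, non-PSD wave-1 or
# latent blocks). Fast path used inside the optimizer; equivalent to
# implied_moments(build_crosslagged(...)) restricted to the observed part.
crosslagged_sigma <- function(theta, T, heterogeneous, check = TRUE) {
  th <- theta
  if (any(!is.finite(th))) return(NULL)
  cxx <- th[1]; cxy <- th[2]; cyx <- th[3]; cyy <- th[4]
  p11 <- th[5]; p22 <- th[6]; p12 <- th[7]; pxx <- th[8]; pyy <- th[9]
  if (check && (p11 < 0 || p22 < 0 || pxx < 0 || pyy < 0)) return(NULL)
  if (check && p12 * p12 > p11 * p22) return(NULL)
  nlat <- if (heterogeneous) 2L else 0L
  if (heterogeneous) {
    lxx <- th[10]; lyy <- th[11]; lxy <- th[12]; lyx <- th[13]
    qxx <- th[14]; qyy <- th[15]; qxy <- th[16]
    if (check && (qxx < 0 || qyy < 0 || qxy * qxy > qxx * qyy)) return(NULL)
  }
  p <- nlat + 2L * T
  C <- matrix(0, p, p)
  Psi <- matrix(0, p, p)
  ix <- function(t) nlat + 2L * (t - 1L) + 1L # X_t
  iy <- function(t) nlat + 2L * (t - 1L) + 2L # Y_t
  for (t in seq_len(T - 1)) {
    C[ix(t + 1), ix(t)] <- cxx
    C[ix(t + 1), iy(t)] <- cxy
    C[iy(t + 1), ix(t)] <- cyx
    C[iy(t + 1), iy(t)] <- cyy
  }
  Psi[ix(1), ix(1)] <- p11
  Psi[iy(1), iy(1)] <- p22
  Psi[ix(1), iy(1)] <- Psi[iy(1), ix(1)] <- p12
  for (t in 2:T) {
    Psi[ix(t), ix(t)] <- pxx
    Psi[iy(t), iy(t)] <- pyy
  }
  if (heterogeneous) {
    C[ix(1), 1] <- lxx; C[iy(1), 2] <- lyy
    C[ix(1), 2] <- lxy; C[iy(1), 1] <- lyx
    for (t in 2:T) {
      C[ix(t), 1] <- 1
      C[iy(t), 2] <- 1
    }
    Psi[1, 1] <- qxx; Psi[2, 2] <- qyy
    Psi[1, 2] <- Psi[2, 1] <- qxy
  }
  M <- solve(diag(p) - C)
  Sigma <- M %*% Psi %*% t(M)
  Sigma <- (Sigma + t(Sigma)) / 2
  Sigma[(nlat + 1):p, (nlat + 1):p]
}

# Data-driven starting values: pooled and within-person (fixed-effects)
# OLS for the lagged coefficients; long-run accumulation loadings and
# back-projected person means for the latent block; jittered replicates.
crosslagged_starts <- function(Yd, S, T, heterogeneous, n_starts) {
  n <- nrow(Yd)
  xs <- Yd[, seq(1, 2 * T, by = 2), drop = FALSE]
  ys <- Yd[, seq(2, 2 * T, by = 2), drop = FALSE]
  src_x <- as.vector(xs[, 1:(T - 1)]); src_y <- as.vector(ys[, 1:(T - 1)])
  dst_x <- as.vector(xs[, 2:T]);       dst_y <- as.vector(ys[, 2:T])

  ols <- function(sx, sy, dx, dy) {
    X <- cbind(sx, sy)
    B <- tryCatch(solve(crossprod(X), crossprod(X, cbind(dx, dy))),
                  error = function(e) matrix(0, 2, 2))
    res <- cbind(dx, dy) - X %*% B
    list(A = t(B), vx = stats::var(res[, 1]), vy = stats::var(res[, 2]))
  }
  pooled <- ols(src_x, src_y, dst_x, dst_y)

  base <- c(pooled$A[1, 1], pooled$A[1, 2], pooled$A[2, 1], pooled$A[2, 2],
            S[1, 1], S[2, 2], 0.8 * S[1, 2],
            max(pooled$vx, 1e-2), max(pooled$vy, 1e-2))

  starts <- list(base)
  if (heterogeneous) {
    # within-person demeaning removes the additive intercepts
    pid <- rep(seq_len(n), times = T - 1)
    dm <- function(v) v - stats::ave(v, pid)
    fe <- ols(dm(src_x), dm(src_y), dm(dst_x), dm(dst_y))
    A <- fe$A
    Mlr <- tryCatch(solve(diag(2) - A), error = function(e) diag(2))
    # back-project long-run person means onto the latent scale
    pm <- cbind(rowMeans(xs[, 2:T, drop = FALSE]),
                rowMeans(ys[, 2:T, drop = FALSE]))
    eta_hat <- pm %*% t(diag(2) - A)
    Q <- stats::cov(eta_hat)
    qxx <- max(Q[1, 1] * 0.8, 1e-2)
    qyy <- max(Q[2, 2] * 0.8, 1e-2)
    qxy <- sign(Q[1, 2]) * min(abs(Q[1, 2]), 0.8 * sqrt(qxx * qyy))
    # wave-1 residual block net of the latent contribution
    lat1 <- Mlr %*% matrix(c(qxx, qxy, qxy, qyy), 2) %*% t(Mlr)
    r11 <- max(S[1, 1] - lat1[1, 1], 0.1 * S[1, 1])
    r22 <- max(S[2, 2] - lat1[2, 2], 0.1 * S[2, 2])
    r12 <- sign(S[1, 2] - lat1[1, 2]) *
      min(abs(S[1, 2] - lat1[1, 2]), 0.8 * sqrt(r11 * r22))
    het_base <- c(A[1, 1], A[1, 2], A[2, 1], A[2, 2],
                  r11, r22, r12, max(fe$vx, 1e-2), max(fe$vy, 1e-2),
                  Mlr[1, 1], Mlr[2, 2], Mlr[1, 2], Mlr[2, 1],
                  qxx, qyy, qxy)
    starts <- list(het_base,
                   c(base, Mlr[1, 1], Mlr[2, 2], Mlr[1, 2], Mlr[2, 1],
                     qxx, qyy, qxy))
  }
  main <- starts[[1]]
  nvar <- length(main)
  is_var <- seq_len(nvar) %in% which(crosslagged_par_names(heterogeneous)
                                     %in% c("psi_x1x1", "psi_y1y1",
                                            "psi_xx", "psi_yy",
                                            "psi_etax_etax",
                                            "psi_etay_etay"))
  while (length(starts) < n_starts) {
    j <- main * (1 + stats::rnorm(nvar, 0, 0.15)) +
      stats::rnorm(nvar, 0, 0.05)
    j[is_var] <- pmax(j[is_var], 1e-2)
    starts[[length(starts) + 1L]] <- j
  }
  starts
}

# F_ML(Sigma, S); >= 0, zero iff Sigma == S.
fml_value <- function(Sigma, S) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet_sigma <- 2 * sum(log(diag(ch)))
  logdet_s <- determinant(S, logarithm = TRUE)$modulus
  p <- nrow(S)
  as.numeric(logdet_sigma + sum(diag(chol2inv(ch) %*% S)) - logdet_s - p)
}

#' @export
print.panelcause_fit <- function(x, ...) {
  cat("Cross-lagged panel model fit (",
      if (x$heterogeneous) "random intercepts" else "homogeneous",
      ", T = ", x$T, ", n = ", x$n_persons, ")\n", sep = "")
  cat("ML discrepancy:", format(x$objective, digits = 6),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(round(rbind(estimate = x$estimates, se = x$se), 4))
  invisible(x)
}

#' Empirical-Bayes latent intercept scores
#'
#' For a fitted random-intercept model, returns each person's
#' conditional-mean (regression / empirical-Bayes) estimate of the latent
#' intercepts given the person's observed panel vector:
#' \eqn{\hat z = \Sigma_{\eta o}\Sigma_{oo}^{-1}(y - \mu_o)}. Scores are
#' shrunken toward zero relative to the true latent values, with the
#' shrinkage determined by the model's signal-to-noise structure.
#'
#' @param fit a heterogeneous [fit_crosslagged_ml()] result.
#' @param data the panel data (long or wide).
#' @return data frame with columns `person`, `eta_x`, `eta_y`.
#' @export
predict_latents <- function(fit, data) {
  stopifnot(inherits(fit, "panelcause_fit"))
  if (!fit$heterogeneous)
    stop("latent scores require a random-intercept (heterogeneous) fit")
  wide <- if (all(c("person", "wave", "x", "y") %in% names(data)))
    panel_to_wide(data) else data
  model <- build_crosslagged(fit$T, as.list(fit$estimates),
                             heterogeneity = TRUE)
  joint <- implied_moments(model)
  obs <- as.vector(rbind(paste0("X", seq_len(fit$T)),
                         paste0("Y", seq_len(fit$T))))
  lat <- c("eta_x", "eta_y")
  Soo <- joint$cov[obs, obs]
  Slo <- joint$cov[lat, obs, drop = FALSE]
  K <- Slo %*% solve(Soo)
  Yd <- as.matrix(wide[, obs])
  dev <- sweep(Yd, 2, joint$mean[obs])
  scores <- dev %*% t(K)
  data.frame(person = if ("person" %in% names(wide)) wide$person else
    seq_len(nrow(wide)),
    eta_x = scores[, 1], eta_y = scores[, 2])
}
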