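#' Build a bivariate cross-lagged panel model
#'
#' Constructs the linear Gaussian SEM for a two-variable panel design with
#' `T` equally spaced waves: autoregressive effects X_t -> X_{t+1} and
#' Y_t -> Y_{t+1}, cross-lagged effects X_t -> Y_{t+1} and Y_t -> X_{t+1},
#' time-stable coefficients, a bidirected (unobserved-confounder) edge
#' between the wave-1 variables, and optionally additive random intercepts
#' `eta_x`, `eta_y` capturing time-invariant unobserved heterogeneity.
#'
#' In the random-intercept variant, `eta_x` loads on X_1..X_T and on Y_1,
#' and `eta_y` on Y_1..Y_T and on X_1. Loadings onto waves t >= 2 are fixed
#' at 1 (setting the latent scale and expressing time stability); the four
#' wave-1 loadings are free parameters representing the accumulated
#' long-run effect of the intercepts on the process before observation
#' starts.
#'
#' @param T number of measurement waves (>= 2).
#' @param params named list/vector of parameters:
#'   \describe{
#'     \item{c_xx, c_yy}{autoregressive coefficients of the X and Y series.}
#'     \item{c_xy}{cross-lagged effect of Y_t on X_{t+1}.}
#'     \item{c_yx}{cross-lagged effect of X_t on Y_{t+1}.}
#'     \item{psi_xx, psi_yy}{innovation variances for waves t >= 2.}
#'     \item{psi_x1x1, psi_y1y1, psi_x1y1}{wave-1 error (co)variances;
#'       may be omitted with `stationary_init = TRUE`.}
#'     \item{c_x1_etax, c_y1_etay, c_x1_etay, c_y1_etax}{wave-1 latent
#'       loadings (heterogeneous variant only).}
#'     \item{psi_etax_etax, psi_etay_etay, psi_etax_etay}{random-intercept
#'       (co)variances (heterogeneous variant only).}
#'   }
#' @param heterogeneity logical; include the random intercepts?
#' @param stationary_init logical; if `TRUE` the wave-1 error
#'   (co)variances are set to the stationary Lyapunov solution
#'   ([stationary_initial_covariance()]) of the lagged dynamics instead of
#'   being read from `params`.
#'
#' @return a [model_spec()] with variables ordered latents first, then
#'   wave-major observed (`X1`, `Y1`, `X2`, `Y2`, ...). The number of waves
#'   and the variant are recorded in attributes `waves` and
#'   `heterogeneity`.
#' @examples
#' m <- build_crosslagged(4, insulin_glucose_params())
#' implied_moments(m)$cov["Y3", "Y3"]  # 632.93
#' @export
build_crosslagged <- function(T, params, heterogeneity = FALSE,
                              stationary_init = FALSE) {
  if (!is.numeric(T) || length(T) != 1 || T < 2)
    stop("T must be a single integer >= 2")
  T <- as.integer(T)
  params <- as.list(params)

  need <- c("c_xx", "c_xy", "c_yx", "c_yy", "psi_xx", "psi_yy")
  if (!stationary_init) need <- c(need, "psi_x1x1", "psi_y1y1", "psi_x1y1")
  if (heterogeneity)
    need <- c(need, "c_x1_etax", "c_y1_etay", "c_x1_etay", "c_y1_etax",
              "psi_etax_etax", "psi_etay_etay", "psi_etax_etay")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0)
    stop("missing model parameter(s): ", paste(missing, collapse = ", "))
  pr <- lapply(params[need], as.numeric)

  if (stationary_init) {
    A <- matrix(c(pr$c_xx, pr$c_yx, pr$c_xy, pr$c_yy), 2, 2)
    Q <- diag(c(pr$psi_xx, pr$psi_yy))
    S1 <- stationary_initial_covariance(A, Q)
    pr$psi_x1x1 <- S1[1, 1]
    pr$psi_y1y1 <- S1[2, 2]
    pr$psi_x1y1 <- S1[1, 2]
  }

  xv <- paste0("X", seq_len(T))
  yv <- paste0("Y", seq_len(T))
  obs <- as.vector(rbind(xv, yv)) # X1 Y1 X2 Y2 ...
  latents <- if (heterogeneity) c("eta_x", "eta_y") else character()
  vars <- c(latents, obs)

  edges <- list()
  add <- function(from, to, coef)
    edges[[length(edges) + 1L]] <<- list(from, to, coef)
  for (t in seq_len(T - 1)) {
    add(xv[t], xv[t + 1], pr$c_xx)
    add(yv[t], xv[t + 1], pr$c_xy)
    add(xv[t], yv[t + 1], pr$c_yx)
    add(yv[t], yv[t + 1], pr$c_yy)
  }
  if (heterogeneity) {
    add("eta_x", "X1", pr$c_x1_etax)
    add("eta_y", "Y1", pr$c_y1_etay)
    add("eta_y", "X1", pr$c_x1_etay)
    add("eta_x", "Y1", pr$c_y1_etax)
    for (t in 2:T) {
      add("eta_x", xv[t], 1)
      add("eta_y", yv[t], 1)
    }
  }

  cov_entries <- list(
    list("X1", "X1", pr$psi_x1x1),
    list("Y1", "Y1", pr$psi_y1y1),
    list("X1", "Y1", pr$psi_x1y1))
  for (t in 2:T) {
    cov_entries[[length(cov_entries) + 1L]] <- list(xv[t], xv[t], pr$psi_xx)
    cov_entries[[length(cov_entries) + 1L]] <- list(yv[t], yv[t], pr$psi_yy)
  }
  if (heterogeneity) {
    cov_entries <- c(cov_entries, list(
      list("eta_x", "eta_x", pr$psi_etax_etax),
      list("eta_y", "eta_y", pr$psi_etay_etay),
      list("eta_x", "eta_y", pr$psi_etax_etay)))
  }

  model <- model_spec(vars, edges, cov_entries, latents = latents)
  attr(model, "waves") <- T
  attr(model, "heterogeneity") <- heterogeneity
  attr(model, "params") <- pr
  model
}

#' Parameter values of the worked insulin-glucose example
#'
#' Returns the data-generating parameter values of the running example: a
#' stable, covariance-stationary bivariate system for mean-centered blood
#' insulin (X, mcIU/ml) and blood glucose (Y, mg/dl) measured at four
#' waves, with wave-1 (co)variances at their long-term equilibrium values.
#' With `heterogeneous = TRUE` the random-intercept parameters (latent
#' variances/covariance and the four free wave-1 loadings) are appended.
#'
#' @param heterogeneous include the random-intercept parameters?
#' @return a named list of parameters suitable for [build_crosslagged()].
#' @export
insulin_glucose_params <- function(heterogeneous = FALSE) {
  pr <- list(
    c_xx = 0.05, c_xy = 0.40, c_yx = -0.60, c_yy = 1.20,
    psi_x1x1 = 131.76, psi_y1y1 = 632.94, psi_x1y1 = 254.12,
    psi_xx = 20.00, psi_yy = 40.00)
  if (heterogeneous) {
    pr <- c(pr, list(
      c_x1_etax = -4.00, c_y1_etay = 19.00,
      c_x1_etay = 8.00, c_y1_etax = -12.00,
      psi_etax_etax = 5.00, psi_etay_etay = 10.00, psi_etax_etay = 2.50))
  }
  pr
}

#' Worked-example model and persons
#'
#' `insulin_glucose_model()` builds the four-wave cross-lagged panel model
#' of the worked insulin-glucose example, homogeneous or with random
#' intercepts. `insulin_glucose_persons()` returns the latent-intercept
#' values (`eta_x`, `eta_y`) of the three illustrative individuals Amy,
#' Joe and Sam (one SD below the mean, at the mean, one SD above).
#'
#' @param heterogeneous include random-intercept heterogeneity?
#' @param T number of waves (default 4).
#' @return a [model_spec()], resp. a named list of named numeric vectors.
#' @examples
#' m <- insulin_glucose_model(heterogeneous = TRUE)
#' sam <- insulin_glucose_persons()$Sam
#' person_specific_interventional(m, c(X2 = 26.30), sam)
#' @export
insulin_glucose_model <- function(heterogeneous = FALSE, T = 4) {
  build_crosslagged(T, insulin_glucose_params(heterogeneous),
                    heterogeneity = heterogeneous)
}

#' @rdname insulin_glucose_model
#' @export
insulin_glucose_persons <- function() {
  list(
    Amy = c(eta_x = -2.24, eta_y = -3.16),
    Joe = c(eta_x = 0, eta_y = 0),
    Sam = c(eta_x = 2.24, eta_y = 3.16))
}
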