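#' Graph surgery for the do-operator
#'
#' Returns the mutilated model implementing `do(target = level)` for each
#' assignment in `intervention`: all directed edges into each target are
#' removed, the target's error variance and all its error covariances are
#' set to zero, and its intercept is set to the interventional level. All
#' other mechanisms are left untouched (modularity): the intervention sets
#' the variable uniformly for every unit and detaches it from its causes.
#'
#' @param model a [model_spec()].
#' @param intervention named numeric vector of interventional levels, e.g.
#'   `c(X2 = 11.48)`; an empty vector returns the model unchanged.
#'   Interventions on latent variables are rejected.
#' @return the mutilated [model_spec()].
#' @examples
#' m_do <- apply_do(insulin_glucose_model(), c(X2 = 11.48))
#' implied_moments(m_do)$mean["Y3"]  # -6.89
#' @export
apply_do <- function(model, intervention) {
  stopifnot(inherits(model, "model_spec"))
  if (length(intervention) == 0) return(model)
  if (is.null(names(intervention)) || any(names(intervention) == ""))
    stop("intervention must be a named numeric vector")
  targets <- names(intervention)
  if (anyDuplicated(targets)) stop("duplicated intervention target")
  unknown <- setdiff(targets, model$variables)
  if (length(unknown) > 0)
    stop("unknown intervention target(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(targets, model$latents)) > 0)
    stop("interventions on latent variables are not supported: ",
         paste(intersect(targets, model$latents), collapse = ", "))

  out <- model
  out$directed_edges <-
    out$directed_edges[!(out$directed_edges$to %in% targets), , drop = FALSE]
  out$error_cov[targets, ] <- 0
  out$error_cov[, targets] <- 0
  out$intercepts[targets] <- intervention
  out
}

#' Interventional distribution
#'
#' The joint distribution of all model variables after the intervention:
#' `implied_moments(apply_do(model, intervention))`. The intervened
#' coordinates are degenerate (zero variance) at their levels; all other
#' variables reflect the downstream propagation of the intervention. In a
#' random-intercept model the latent intercepts are integrated out, so the
#' marginal of an outcome is the population interventional distribution.
#'
#' @inheritParams apply_do
#' @return a [gaussian_dist()] over all model variables.
#' @examples
#' d <- interventional_distribution(insulin_glucose_model(), c(X2 = 11.48))
#' d$cov["Y3", "Y3"]  # 951.43, independent of the level
#' @export
interventional_distribution <- function(model, intervention) {
  implied_moments(apply_do(model, intervention))
}

#' Person-specific interventional distribution
#'
#' Conditions the interventional distribution of a random-intercept model
#' on an individual's latent intercept values: the forecast distribution
#' for a known person rather than a randomly drawn member of the
#' heterogeneous population. Conditioning on the intercepts shifts the
#' mean by the person's time-invariant characteristics and removes the
#' between-person variance component from the forecast error.
#'
#' @inheritParams apply_do
#' @param person named numeric vector of latent values, e.g.
#'   `c(eta_x = 2.24, eta_y = 3.16)`; must reference latent variables only.
#' @return the conditional [gaussian_dist()] (latents dropped).
#' @examples
#' m <- insulin_glucose_model(heterogeneous = TRUE)
#' sam <- insulin_glucose_persons()$Sam
#' person_specific_interventional(m, c(X2 = 26.30), sam)$mean["Y3"]  # 27.17
#' @export
person_specific_interventional <- function(model, intervention, person) {
  stopifnot(inherits(model, "model_spec"))
  if (length(person) == 0 || is.null(names(person)))
    stop("person must be a named numeric vector over latent variables")
  not_latent <- setdiff(names(person), model$latents)
  if (length(not_latent) > 0)
    stop("person values must reference latent variables only; got: ",
         paste(not_latent, collapse = ", "))
  condition_on(interventional_distribution(model, intervention), person)
}

#' Average treatment effect between two interventions
#'
#' Difference between the interventional means of `outcome` under
#' `intervention_a` and `intervention_b`. In the linear models handled
#' here the ATE does not depend on a person's time-invariant
#' characteristics, so the population ATE and every person-specific ATE
#' coincide.
#'
#' @inheritParams apply_do
#' @param intervention_a,intervention_b named numeric vectors over the
#'   same targets.
#' @param outcome outcome variable label.
#' @return numeric scalar, `E(outcome | do_a) - E(outcome | do_b)`.
#' @examples
#' ate(insulin_glucose_model(), c(X2 = 11.48), c(X2 = 0), "Y3")  # -6.89
#' @export
ate <- function(model, intervention_a, intervention_b, outcome) {
  if (!setequal(names(intervention_a), names(intervention_b)))
    stop("both interventions must assign the same target variables")
  da <- interventional_distribution(model, intervention_a)
  db <- interventional_distribution(model, intervention_b)
  check_labels(da, outcome)
  unname(da$mean[outcome] - db$mean[outcome])
}
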