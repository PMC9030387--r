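#' Simulate panel data from a cross-lagged model
#'
#' Draws `n_persons` independent realizations of the panel process defined
#' by a model built with [build_crosslagged()] (optionally after do-surgery
#' with [apply_do()]): latent random intercepts from their bivariate
#' normal (heterogeneous variant), the wave-1 pair from its (eta-shifted)
#' bivariate normal, and subsequent waves by iterating the structural
#' recursion with independent Gaussian innovations.
#'
#' Randomness is organized in substreams derived from the master seed: one
#' stream for the latent draws, one for the wave-1 errors, and one per
#' later wave. Homogeneous and heterogeneous runs with the same seed
#' therefore share their wave-level innovations, and an interventional run
#' differs from its observational counterpart only where the surgery
#' dictates (the intervened column is constant at its level).
#'
#' @param model a cross-lagged [model_spec()] from [build_crosslagged()]
#'   (possibly mutilated by [apply_do()]).
#' @param n_persons number of persons (> 0).
#' @param seed integer master seed; identical seed and parameters give a
#'   bitwise identical dataset.
#' @return a long-format data frame with columns `person`, `wave`, `x`,
#'   `y`, plus `eta_x`, `eta_y` (the person's true latent intercepts) for
#'   heterogeneous models; exactly `T` rows per person, no missing cells.
#' @examples
#' pd <- simulate_panel(insulin_glucose_model(), 500, seed = 1)
#' sd(pd$y[pd$wave == 3])  # close to 25.16
#' @export
simulate_panel <- function(model, n_persons, seed) {
  stopifnot(inherits(model, "model_spec"))
  if (!is.numeric(n_persons) || length(n_persons) != 1 || n_persons <= 0)
    stop("n_persons must be a positive integer")
  n <- as.integer(n_persons)
  T <- attr(model, "waves")
  if (is.null(T))
    stop("simulate_panel requires a model built by build_crosslagged()")
  het <- isTRUE(attr(model, "heterogeneity"))
  vars <- model$variables
  xv <- paste0("X", seq_len(T))
  yv <- paste0("Y", seq_len(T))
  psi <- model$error_cov

  # substream seeds: latents, wave 1, then one per later wave
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  substreams <- sample.int(.Machine$integer.max, T + 1L)

  eps <- matrix(0, n, length(vars), dimnames = list(NULL, vars))

  set.seed(substreams[1])
  if (het) {
    lat <- c("eta_x", "eta_y")
    eps[, lat] <- rmvn_psd(n, psi[lat, lat])
  }
  set.seed(substreams[2])
  w1 <- c(xv[1], yv[1])
  eps[, w1] <- rmvn_psd(n, psi[w1, w1])
  for (t in 2:T) {
    set.seed(substreams[t + 1L])
    eps[, xv[t]] <- sqrt(psi[xv[t], xv[t]]) * stats::rnorm(n)
    eps[, yv[t]] <- sqrt(psi[yv[t], yv[t]]) * stats::rnorm(n)
  }

  # reduced form: values = (b + eps) (I - C)^{-T}; identical to iterating
  # the structural recursion wave by wave
  M <- solve(diag(length(vars)) - coef_matrix(model))
  values <- sweep(eps, 2, model$intercepts, "+") %*% t(M)
  colnames(values) <- vars

  out <- data.frame(
    person = rep(seq_len(n), each = T),
    wave = rep(seq_len(T), times = n),
    x = as.vector(t(values[, xv, drop = FALSE])),
    y = as.vector(t(values[, yv, drop = FALSE])))
  if (het) {
    out$eta_x <- rep(values[, "eta_x"], each = T)
    out$eta_y <- rep(values[, "eta_y"], each = T)
  }
  out
}

#' Simulate panel data under an intervention
#'
#' Convenience wrapper: simulates from the mutilated model
#' `apply_do(model, intervention)`, so the intervened variable is constant
#' at its level for every person and detached from its causes.
#'
#' @inheritParams simulate_panel
#' @param intervention named numeric vector of interventional levels.
#' @export
simulate_interventional <- function(model, intervention, n_persons, seed) {
  simulate_panel(apply_do(model, intervention), n_persons, seed)
}

# n draws from N(0, S) for a PSD (possibly degenerate) covariance S,
# via its symmetric eigendecomposition.
rmvn_psd <- function(n, S) {
  S <- as.matrix(S)
  p <- nrow(S)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Z %*% (t(e$vectors) * sqrt(lam))
}

#' Reshape a long panel to wide format
#'
#' @param panel a long-format panel data frame from [simulate_panel()] or
#'   [read_panel()].
#' @return a wide data frame, one row per person, with columns `person`,
#'   `X1..XT`, `Y1..YT` and, if present, `eta_x`, `eta_y`.
#' @export
panel_to_wide <- function(panel) {
  stopifnot(all(c("person", "wave", "x", "y") %in% names(panel)))
  waves <- sort(unique(panel$wave))
  persons <- unique(panel$person)
  cnt <- table(panel$person)
  if (any(cnt != length(waves)))
    stop("panel is unbalanced: every person needs one row per wave")
  panel <- panel[order(panel$person, panel$wave), ]
  wide <- data.frame(person = persons)
  for (t in waves) {
    wide[[paste0("X", t)]] <- panel$x[panel$wave == t]
    wide[[paste0("Y", t)]] <- panel$y[panel$wave == t]
  }
  if ("eta_x" %in% names(panel)) {
    first <- !duplicated(panel$person)
    wide$eta_x <- panel$eta_x[first]
    wide$eta_y <- panel$eta_y[first]
  }
  wide
}

#' Read / write panel data as CSV
#'
#' Long format (default): columns `person`, `wave`, `x`, `y` (+ optional
#' `eta_x`, `eta_y`). Wide format: `person`, `X1..XT`, `Y1..YT`.
#'
#' @param panel a panel data frame.
#' @param path CSV file path.
#' @param wide write/read wide format?
#' @return `read_panel` returns a long-format data frame (wide input is
#'   reshaped); `write_panel` invisibly returns `path`.
#' @export
write_panel <- function(panel, path, wide = FALSE) {
  if (wide) panel <- panel_to_wide(panel)
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, wide = FALSE) {
  df <- utils::read.csv(path)
  if (!wide) {
    stopifnot(all(c("person", "wave", "x", "y") %in% names(df)))
    return(df)
  }
  xcols <- grep("^X[0-9]+$", names(df), value = TRUE)
  ycols <- grep("^Y[0-9]+$", names(df), value = TRUE)
  T <- length(xcols)
  stopifnot(T >= 2, length(ycols) == T)
  person <- if ("person" %in% names(df)) df$person else seq_len(nrow(df))
  long <- data.frame(
    person = rep(person, each = T),
    wave = rep(seq_len(T), times = nrow(df)),
    x = as.vector(t(as.matrix(df[, paste0("X", seq_len(T))]))),
    y = as.vector(t(as.matrix(df[, paste0("Y", seq_len(T))]))))
  long
}
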