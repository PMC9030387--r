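test_that("cross-lagged builder produces the expected graph structure", {
  m <- insulin_glucose_model()
  expect_equal(nrow(m$directed_edges), 12L) # 3 transitions x 4 edges
  expect_equal(m$variables,
               c("X1", "Y1", "X2", "Y2", "X3", "Y3", "X4", "Y4"))
  # one bidirected edge: the wave-1 pair
  off <- m$error_cov
  diag(off) <- 0
  expect_equal(sum(off != 0), 2L) # symmetric entry counted twice
  expect_equal(m$error_cov["X1", "Y1"], 254.12)

  mh <- insulin_glucose_model(heterogeneous = TRUE)
  e <- mh$directed_edges
  eta_x_targets <- sort(e$to[e$from == "eta_x"])
  eta_y_targets <- sort(e$to[e$from == "eta_y"])
  expect_equal(eta_x_targets, c("X1", "X2", "X3", "X4", "Y1"))
  expect_equal(eta_y_targets, c("X1", "Y1", "Y2", "Y3", "Y4"))
  # loadings for t >= 2 are fixed at 1, wave-1 loadings free
  expect_true(all(e$coef[e$from == "eta_x" &
                           e$to %in% c("X2", "X3", "X4")] == 1))
  expect_equal(e$coef[e$from == "eta_x" & e$to == "X1"], -4)
  expect_equal(e$coef[e$from == "eta_y" & e$to == "X1"], 8)
  expect_equal(mh$latents, c("eta_x", "eta_y"))
})

test_that("builder rejects bad input with informative errors", {
  pr <- insulin_glucose_params()
  expect_error(build_crosslagged(1, pr), "T must be")
  pr2 <- pr
  pr2$c_yx <- NULL
  expect_error(build_crosslagged(4, pr2), "c_yx")
  expect_error(build_crosslagged(4, insulin_glucose_params(),
                                 heterogeneity = TRUE), "psi_etax_etax")
})

test_that("zero-coefficient model has implied covariance equal to its errors", {
  pr <- insulin_glucose_params()
  pr[c("c_xx", "c_xy", "c_yx", "c_yy")] <- 0
  m <- build_crosslagged(2, pr)
  j <- implied_moments(m)
  expect_equal(j$cov, m$error_cov, tolerance = 1e-12)
  expect_equal(unname(j$mean), rep(0, 4))
})

test_that("implied moments reproduce the stationary insulin-glucose moments", {
  j <- implied_moments(insulin_glucose_model())
  expect_equal(j$cov["X2", "X2"], 131.76, tolerance = 0.01)
  for (t in 1:4) {
    expect_equal(sqrt(j$cov[paste0("X", t), paste0("X", t)]), 11.48,
                 tolerance = 0.005)
    expect_equal(sqrt(j$cov[paste0("Y", t), paste0("Y", t)]), 25.16,
                 tolerance = 0.005)
  }
  slope <- j$cov["X2", "Y3"] / j$cov["X2", "X2"]
  expect_equal(round(slope, 2), 1.71)
})

test_that("stationary initialization gives wave-constant moments", {
  m <- build_crosslagged(4, insulin_glucose_params(), stationary_init = TRUE)
  j <- implied_moments(m)
  vx <- diag(j$cov)[paste0("X", 1:4)]
  vy <- diag(j$cov)[paste0("Y", 1:4)]
  expect_lt(max(vx) - min(vx), 1e-6)
  expect_lt(max(vy) - min(vy), 1e-6)
  # printed wave-1 values agree with the Lyapunov solution to print precision
  expect_equal(unname(vx[1]), 131.76, tolerance = 0.005)
  expect_equal(unname(vy[1]), 632.94, tolerance = 0.005)
  expect_equal(j$cov["X1", "Y1"], 254.12, tolerance = 0.005)
})

test_that("Lyapunov solver matches printed equilibrium and an iteration oracle", {
  A <- table1_lag_matrix()
  expect_lt(max(Mod(eigen(A, only.values = TRUE)$values)), 1)
  S <- stationary_initial_covariance(A, diag(c(20, 40)))
  expect_equal(S[1, 1], 131.76, tolerance = 0.01)
  expect_equal(S[2, 2], 632.94, tolerance = 0.01)
  expect_equal(S[1, 2], 254.12, tolerance = 0.01)

  expect_equal(stationary_initial_covariance(matrix(0, 2, 2), diag(2)),
               diag(2))

  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(stats::runif(4, -0.5, 0.5), 2, 2)
    Q <- crossprod(matrix(stats::rnorm(4), 2, 2)) + diag(2)
    S <- stationary_initial_covariance(A, Q)
    # independent oracle: iterate the recursion to its fixed point
    S_it <- Q
    for (i in 1:500) S_it <- A %*% S_it %*% t(A) + Q
    expect_equal(S, S_it, tolerance = 1e-10)
  }

  expect_error(stationary_initial_covariance(diag(c(1.1, 0.5)), diag(2)),
               "not stationary")
})

test_that("heterogeneous model reproduces the inflated stationary moments", {
  j <- implied_moments(insulin_glucose_model(heterogeneous = TRUE))
  for (t in 2:4) {
    expect_equal(j$cov[paste0("Y", t), paste0("Y", t)], 3822.93,
                 tolerance = 0.02)
    expect_equal(sqrt(j$cov[paste0("X", t), paste0("X", t)]), 26.30,
                 tolerance = 0.01)
    expect_equal(sqrt(j$cov[paste0("Y", t), paste0("Y", t)]), 61.83,
                 tolerance = 0.01)
  }
})

test_that("implied covariance is symmetric PSD for random valid models", {
  set.seed(7)
  for (rep in 1:10) {
    m <- random_linear_model(p = 6)
    S <- implied_moments(m)$cov
    expect_lt(max(abs(S - t(S))), 1e-10)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(1, max(ev)))
  }
})

test_that("model validation rejects cycles and indefinite error matrices", {
  expect_error(
    model_spec(c("A", "B"),
               list(list("A", "B", 1), list("B", "A", 1)),
               list(list("A", "A", 1), list("B", "B", 1))),
    "cycle")
  expect_error(
    model_spec(c("A", "B"), list(),
               list(list("A", "A", 1), list("B", "B", 1),
                    list("A", "B", 5))),
    "positive semidefinite")
  expect_error(
    model_spec("A", list(list("A", "Z", 1)), list(list("A", "A", 1))),
    "unknown variable")
})

test_that("model files round-trip and the shipped fixtures match the built-ins", {
  m <- insulin_glucose_model(heterogeneous = TRUE)
  path <- tempfile(fileext = ".yaml")
  write_model_spec(m, path)
  m2 <- read_model_spec(path)
  j1 <- implied_moments(m)
  j2 <- implied_moments(m2)
  expect_equal(j2$cov[j1$labels, j1$labels], j1$cov, tolerance = 1e-12)

  for (fixture in c("insulin_glucose_homogeneous.yaml",
                    "insulin_glucose_random_intercepts.yaml")) {
    f <- system.file("extdata", fixture, package = "panelcause")
    expect_true(file.exists(f))
    mf <- read_model_spec(f)
    het <- fixture == "insulin_glucose_random_intercepts.yaml"
    jb <- implied_moments(insulin_glucose_model(heterogeneous = het))
    jf <- implied_moments(mf)
    expect_equal(jf$cov[jb$labels, jb$labels], jb$cov, tolerance = 1e-12)
  }
})
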