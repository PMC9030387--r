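g_hom <- as_causal_graph(insulin_glucose_model())
g_het <- as_causal_graph(insulin_glucose_model(heterogeneous = TRUE))

test_that("backdoor paths from X2 to Y3 include the two canonical routes", {
  paths <- backdoor_paths(g_hom, "X2", "Y3")
  keys <- vapply(paths, paste, character(1), collapse = ">")
  expect_true("X2>X1>Y2>Y3" %in% keys)
  expect_true("X2>Y1>Y2>Y3" %in% keys)
  # every reported path starts with an edge into the treatment
  for (p in paths) {
    expect_true(p[2] %in% c("X1", "Y1"))
  }
  # deterministic lexicographic ordering
  expect_identical(keys, sort(keys))
})

test_that("a treatment without causes has no backdoor paths", {
  g <- causal_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_length(backdoor_paths(g, "A", "C"), 0)
})

test_that("backdoor enumeration agrees with a brute-force oracle on random DAGs", {
  set.seed(11)
  for (rep in 1:8) {
    g <- random_dag(paste0("N", 1:8), prob = 0.3)
    pair <- sample(g$nodes, 2)
    got <- backdoor_paths(g, pair[1], pair[2])
    ex <- panelcause:::latent_expand(g)
    want <- oracle_all_paths(ex$directed, pair[1], pair[2])
    want <- Filter(function(p)
      any(ex$directed[, 1] == p[2] & ex$directed[, 2] == p[1]), want)
    got_keys <- sort(vapply(got, paste, character(1), collapse = ">"))
    want_keys <- sort(vapply(want, paste, character(1), collapse = ">"))
    expect_identical(got_keys, want_keys)
  }
})

test_that("minimal adjustment set for X2 -> Y3 is {Y2} first", {
  sets <- minimal_adjustment_sets(g_hom, "X2", "Y3")
  expect_identical(sets[[1]], "Y2")
  # every returned set is inclusion-minimal and valid
  for (Z in sets) {
    expect_true(d_separated_backdoor(g_hom, "X2", "Y3", Z))
    if (length(Z) > 0) {
      for (drop in seq_along(Z)) {
        expect_false(d_separated_backdoor(g_hom, "X2", "Y3", Z[-drop]))
      }
    }
  }
})

test_that("a pure chain needs no adjustment", {
  g <- causal_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_identical(minimal_adjustment_sets(g, "A", "C"),
                   list(character(0)))
})

test_that("with random intercepts, identification requires the latents", {
  # no observed-only backdoor set exists: the latent intercepts confound
  # every route and cannot be blocked downstream of the treatment
  obs_only <- minimal_adjustment_sets(g_het, "X2", "Y3",
                                      latents = c("eta_x", "eta_y"))
  expect_length(obs_only, 0)
  # admitting the latents restores identification, and every valid set
  # involves at least one of them
  sets <- minimal_adjustment_sets(g_het, "X2", "Y3",
                                  include_latents = TRUE,
                                  latents = c("eta_x", "eta_y"))
  expect_gt(length(sets), 0)
  for (Z in sets) {
    expect_true(any(c("eta_x", "eta_y") %in% Z))
    expect_true(d_separated_backdoor(g_het, "X2", "Y3", Z))
  }
})

test_that("d-separation handles the collider canon", {
  g <- causal_graph(c("A", "B", "C", "D"),
                    rbind(c("A", "C"), c("B", "C"), c("C", "D")))
  expect_true(d_separated(g, "A", "B"))
  expect_false(d_separated(g, "A", "B", "C"))
  expect_false(d_separated(g, "A", "B", "D")) # descendant of a collider
})

test_that("d-separation in the panel model matches vanishing partial covariance", {
  expect_true(d_separated(g_hom, "X1", "Y3", c("X2", "Y2")))
  joint <- implied_moments(insulin_glucose_model())
  cond <- condition_on(joint, c(X2 = 0, Y2 = 0))
  expect_lt(abs(cond$cov["X1", "Y3"]), 1e-8)
  # and a dependent pair for contrast
  expect_false(d_separated(g_hom, "X1", "Y3", "X2"))
})

test_that("d-separation agrees with the path-blocking oracle on random DAGs", {
  set.seed(23)
  for (rep in 1:12) {
    g <- random_dag(paste0("N", 1:7), prob = 0.35)
    picks <- sample(g$nodes, 4)
    A <- picks[1]; B <- picks[2]; Z <- picks[3:sample(3:4, 1)]
    expect_identical(d_separated(g, A, B, Z),
                     oracle_d_separated(g, A, B, Z),
                     info = paste("rep", rep))
  }
})

test_that("d-separation implies zero partial covariance in random linear models", {
  set.seed(31)
  for (rep in 1:6) {
    m <- random_linear_model(p = 5)
    g <- as_causal_graph(m)
    joint <- implied_moments(m)
    picks <- sample(m$variables, 4)
    A <- picks[1]; B <- picks[2]; Z <- picks[3:4]
    if (d_separated(g, A, B, Z)) {
      cond <- condition_on(joint, stats::setNames(c(0, 0), Z))
      expect_lt(abs(cond$cov[A, B]), 1e-8)
    }
  }
})

test_that("graph utilities validate their arguments", {
  expect_error(d_separated(g_hom, "X2", "X2", "Y2"), "disjoint")
  expect_error(d_separated(g_hom, "Q1", "Y3"), "unknown node")
  expect_error(backdoor_paths(g_hom, "X2", "X2"), "must differ")
  expect_error(causal_graph(c("A", "B"),
                            rbind(c("A", "B"), c("B", "A"))), "cycle")
})
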