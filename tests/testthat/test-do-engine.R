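m_hom <- insulin_glucose_model()
m_het <- insulin_glucose_model(heterogeneous = TRUE)

test_that("do-surgery removes incoming edges and fixes the target", {
  md <- apply_do(m_hom, c(X2 = 11.48))
  expect_false(any(md$directed_edges$to == "X2"))
  expect_equal(sum(m_hom$directed_edges$to == "X2"), 2L)
  expect_equal(md$error_cov["X2", "X2"], 0)
  expect_true(all(md$error_cov["X2", setdiff(md$variables, "X2")] == 0))
  expect_equal(unname(md$intercepts["X2"]), 11.48)
  # everything else untouched (modularity)
  others <- md$directed_edges
  expect_equal(others, m_hom$directed_edges[m_hom$directed_edges$to != "X2", ],
               ignore_attr = TRUE)

  j <- implied_moments(md)
  expect_equal(j$cov["X2", "X2"], 0)
  expect_equal(unname(j$mean["X2"]), 11.48)
})

test_that("the empty intervention is the identity", {
  expect_identical(apply_do(m_hom, numeric(0)), m_hom)
})

test_that("surgery on the random-intercept model also severs the latent edge", {
  md <- apply_do(m_het, c(X2 = 26.30))
  expect_false(any(md$directed_edges$to == "X2"))
  expect_equal(sum(m_het$directed_edges$from == "eta_x" &
                     m_het$directed_edges$to == "X2"), 1L)
})

test_that("interventions on latents are rejected", {
  expect_error(apply_do(m_het, c(eta_x = 1)), "latent")
  expect_error(apply_do(m_hom, c(Q7 = 1)), "unknown")
})

test_that("interventional moments match the closed-form forecast values", {
  d <- interventional_distribution(m_hom, c(X2 = 11.48))
  expect_equal(unname(d$mean["Y3"]), -6.89, tolerance = 0.005)
  expect_equal(d$cov["Y3", "Y3"], 951.43, tolerance = 0.01)

  # interventional variance does not depend on the level
  vs <- vapply(c(-50, 0, 50), function(x)
    interventional_distribution(m_hom, c(X2 = x))$cov["Y3", "Y3"],
    numeric(1))
  expect_lt(max(vs) - min(vs), 1e-10)
  # ... and neither does the conditional variance on the observed value
  joint <- implied_moments(m_hom)
  cvs <- vapply(c(-50, 0, 50), function(x)
    condition_on(joint, c(X2 = x))$cov["Y3", "Y3"], numeric(1))
  expect_lt(max(cvs) - min(cvs), 1e-10)

  # joint intervention leaves only the innovation variance
  d2 <- interventional_distribution(m_hom, c(X2 = 3, Y2 = -2))
  expect_equal(d2$cov["Y3", "Y3"], 40, tolerance = 1e-9)
  expect_equal(unname(d2$mean["Y3"]), -0.6 * 3 + 1.2 * (-2),
               tolerance = 1e-9)
})

test_that("person-specific interventional distribution matches the worked case", {
  persons <- insulin_glucose_persons()
  d_sam <- person_specific_interventional(m_het, c(X2 = 26.30),
                                          persons$Sam)
  expect_equal(unname(d_sam$mean["Y3"]), 27.17, tolerance = 0.02)
  expect_equal(d_sam$cov["Y3", "Y3"], 951.43, tolerance = 0.02)
  # the person-specific variance is level- and person-independent
  for (p in persons) {
    d <- person_specific_interventional(m_het, c(X2 = -10), p)
    expect_equal(d$cov["Y3", "Y3"], 951.43, tolerance = 0.02)
  }
  # the average person's forecast equals the population forecast
  d_joe <- person_specific_interventional(m_het, c(X2 = 26.30),
                                          persons$Joe)
  d_pop <- interventional_distribution(m_het, c(X2 = 26.30))
  expect_equal(unname(d_joe$mean["Y3"]), unname(d_pop$mean["Y3"]),
               tolerance = 1e-9)
  expect_error(person_specific_interventional(m_het, c(X2 = 1),
                                              c(X3 = 1)),
               "latent variables only")
})

test_that("ATE is the difference of interventional means and is person-free", {
  expect_equal(ate(m_hom, c(X2 = 11.48), c(X2 = 0), "Y3"), -6.89,
               tolerance = 0.005)
  expect_equal(ate(m_hom, c(X2 = 7), c(X2 = 7), "Y3"), 0)
  expect_error(ate(m_hom, c(X2 = 1), c(Y2 = 1), "Y3"), "same target")

  # person-specific ATE equals the population ATE for any person
  sam <- insulin_glucose_persons()$Sam
  psa <- person_specific_interventional(m_het, c(X2 = 11), sam)$mean["Y3"] -
    person_specific_interventional(m_het, c(X2 = 4), sam)$mean["Y3"]
  expect_equal(unname(psa), ate(m_het, c(X2 = 11), c(X2 = 4), "Y3"),
               tolerance = 1e-9)
})

test_that("backdoor adjustment recovers the structural coefficient", {
  joint <- implied_moments(m_hom)
  g <- as_causal_graph(m_hom)
  sets <- minimal_adjustment_sets(g, "X2", "Y3")
  expect_gt(length(sets), 0)
  for (Z in sets) {
    slope <- population_regression(joint, "Y3", c("X2", Z))[["X2"]]
    expect_equal(slope, -0.6, tolerance = 1e-10)
  }
})

test_that("heterogeneous interventional variance decomposes into latent + homogeneous parts", {
  v_het <- interventional_distribution(m_het, c(X2 = 0))$cov["Y3", "Y3"]
  v_hom <- interventional_distribution(m_hom, c(X2 = 0))$cov["Y3", "Y3"]
  expect_equal(v_het - v_hom, 5939.03 - 951.43, tolerance = 0.02)
  expect_equal(v_het, 5939.03, tolerance = 0.02)
})

test_that("simulated interventional data agree with the analytic forecast", {
  pd <- simulate_interventional(m_hom, c(X2 = 11.48), 40000, seed = 5)
  y3 <- pd$y[pd$wave == 3]
  expect_true(all(pd$x[pd$wave == 2] == 11.48))
  se_mean <- sqrt(951.43 / 40000)
  expect_lt(abs(mean(y3) - (-6.888)), 3 * se_mean)
  se_var <- 951.43 * sqrt(2 / 40000)
  expect_lt(abs(stats::var(y3) - 951.43), 3 * se_var)
})
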