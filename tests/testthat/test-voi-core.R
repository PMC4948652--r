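test_that("EVPI matches enumeration on a two-outcome bet and degenerates to 0", {
  # B2 - B1 = +1 or -1 with equal probability: EVPI = E[max(0, B2)] = 0.5
  nb <- cbind(0, rep(c(1, -1), each = 500))
  est <- evpi_nb(nb)
  expect_equal(est$estimate, 0.5)
  # no uncertainty, no value
  expect_equal(evpi_nb(cbind(0, rep(2.5, 100)))$estimate, 0)
  expect_error(evpi_nb(matrix(numeric(0), 0, 2)), "empty")
})

test_that("EVPPI equals EVPI for the full focal set and 0 for constant cond_nb", {
  d <- fluid_fixture(5000)
  ref <- evpi(d, 250)
  full <- evppi_single_step(d, fluid_params(fluid_context()),
                            function(s, w, ctx) nb_matrix(s, w, ctx),
                            250, method_label = "exact")
  expect_identical(full$estimate, ref$estimate)
  flat <- evppi_single_step(d, "qM",
                            function(s, w, ctx) {
                              matrix(rep(c(0, 5, 3, 1), each = nrow(s)),
                                     nrow(s), 4)
                            }, 250, method_label = "flat")
  expect_equal(flat$estimate, 0)
})

test_that("the registry maps the case-study focal sets to their methods", {
  expect_equal(admissible_method(c("dM", "alpha", "pB", "dS", "pL")), "m1")
  expect_equal(admissible_method(c("dM", "alpha", "pB", "dS", "qS")), "m1")
  expect_equal(admissible_method(c("dM", "alpha", "pB", "dS", "qM")), "m2")
  expect_equal(admissible_method(c("dM", "alpha", "pB", "dS")), "m2")
  expect_equal(admissible_method("pL"), "m3")
  expect_equal(admissible_method(c("qM", "qS", "pL")), "m3")
  expect_equal(admissible_method(c("dM", "dS")), "m4")
  expect_equal(admissible_method(c("alpha", "pB")), "m4")
  for (f in c("alpha", "pB", "dS", "d_albumin", "d_saline", "d_gelofusine")) {
    expect_equal(admissible_method(f), "m5")
  }
  expect_equal(admissible_method(fluid_params(fluid_context())), "evpi")
  # no single-step method: a result, not an error
  expect_equal(admissible_method(c("alpha", "qM")), "nested")
  expect_error(admissible_method("nope"), "unknown focal")
})

test_that("inadmissible plug-in raises naming the offending parameters", {
  d <- fluid_fixture(1000)
  err <- expect_error(cond_nb_plugin(d, c("dM", "dS")),
                      class = "voitools_condition_violation")
  expect_match(conditionMessage(err), "alpha")
  expect_match(conditionMessage(err), "pB")
  expect_error(cond_nb_reparam(d, c("qM", "alpha")),
               class = "voitools_condition_violation")
})

test_that("method 3 with a degenerate complement reduces to direct plug-in", {
  # zero-variance treatment-effect block: beta terms are deterministic, so
  # the reparameterized estimator equals plugging the fixed values into the
  # net benefit directly
  marg <- list(
    marginal_spec("alpha", "fixed", value = -1.07),
    marginal_spec("d_saline", "fixed", value = -0.31),
    marginal_spec("d_albumin", "fixed", value = -2.34),
    marginal_spec("d_gelofusine", "fixed", value = -0.19),
    marginal_spec("dS", "fixed", value = 1.88),
    marginal_spec("pB", "fixed", value = 0.1),
    marginal_spec("pL", "beta", shape1 = 1, shape2 = 1),
    marginal_spec("qM", "normal", mean = 19.99, sd = sqrt(24.97)),
    marginal_spec("qS", "truncnorm", mean = 5, sd = 3.16, lower = 0)
  )
  d <- sample_posterior(posterior_spec(marg), 5000, seed = 12)
  m3 <- evppi(d, c("qM", "qS", "pL"), 250, method = "m3")
  direct <- evppi_single_step(d, c("qM", "qS", "pL"),
                              function(s, w, ctx) nb_matrix(s, w, ctx),
                              250, method_label = "direct")
  expect_equal(m3$estimate, direct$estimate, tolerance = 1e-10)
})

test_that("single-step estimates agree with quadrature on toy models", {
  suite <- toy_suite()
  # linear toy: conditional mean given t1 is t1 + E[t2]; plug-in is exact
  toy <- suite$linear
  d <- sample_toy(toy, 4e4, seed = 21)
  oracle <- quadrature_evppi(toy, "t1")
  cond <- function(s, w, ctx) cbind(0, s$t1 + 0)   # E[t2] = 0
  est <- evppi_single_step(d, "t1", cond, NA, method_label = "plugin")
  expect_within_se(est$estimate, oracle, est$mc_se)
  # product toy: conditional mean given t1 is t1 * E[t2] - 0.1
  toyp <- suite$product
  dp <- sample_toy(toyp, 4e4, seed = 22)
  oraclep <- quadrature_evppi(toyp, "t1")
  condp <- function(s, w, ctx) cbind(0, s$t1 * 0.2 - 0.1)
  estp <- evppi_single_step(dp, "t1", condp, NA, method_label = "plugin")
  expect_within_se(estp$estimate, oraclep, estp$mc_se)
})

test_that("nested Monte Carlo converges to quadrature, conditionally sampled", {
  suite <- toy_suite()
  toy <- suite$expit_corr
  d <- sample_toy(toy, 3e4, seed = 31)
  oracle <- quadrature_evppi(toy, "t1")
  nest <- evppi_nested(d, "t1", spec = toy$spec, nb_fn = toy$nb_fn,
                       n_outer = 1500, n_inner = 4000, seed = 32)
  expect_within_se(nest$estimate, oracle, nest$mc_se)
  # ignoring the correlation biases the estimate down
  naive <- suppressWarnings(
    evppi_nested(d, "t1", spec = toy$spec, nb_fn = toy$nb_fn,
                 n_outer = 1500, n_inner = 4000, conditional = FALSE,
                 seed = 32))
  expect_lt(naive$estimate, oracle - 3 * naive$mc_se)
  expect_warning(
    evppi_nested(d, "t1", spec = toy$spec, nb_fn = toy$nb_fn,
                 n_outer = 50, n_inner = 50, conditional = FALSE, seed = 1),
    "downward bias")
})

test_that("nested with a deterministic complement equals single-step plug-in", {
  marg <- list(marginal_spec("t1", "normal", mean = 0.3, sd = 1),
               marginal_spec("t2", "fixed", value = 0.7))
  toy <- structure(list(name = "fixed-comp",
                        spec = posterior_spec(marg),
                        nb_fn = function(s) cbind(0, plogis(s$t1) * s$t2 - 0.3)),
                   class = "voi_toy")
  d <- sample_toy(toy, 5000, seed = 41)
  nest <- evppi_nested(d, "t1", spec = toy$spec, nb_fn = toy$nb_fn,
                       n_outer = 5000, n_inner = 3, seed = 42)
  plug <- evppi_single_step(d, "t1",
                            function(s, w, ctx) cbind(0, plogis(s$t1) * 0.7 - 0.3),
                            NA, method_label = "plugin")
  expect_equal(nest$estimate, plug$estimate, tolerance = 1e-12)
})

test_that("EVPPI never exceeds EVPI and estimates are almost surely >= 0", {
  d <- fluid_fixture(2e4)
  ref <- evpi(d, 250)
  sets <- list("qM", "qS", "pL", c("dM", "alpha", "pB", "dS", "pL"),
               c("dM", "alpha", "pB", "dS", "qM"), c("dM", "dS"),
               "alpha", "pB", "dS", "d_albumin")
  for (f in sets) {
    e <- evppi(d, f, 250)
    expect_lte(e$estimate, ref$estimate + 3 * sqrt(e$mc_se^2 + ref$mc_se^2))
    expect_gte(e$estimate, -3 * e$mc_se)
  }
})
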