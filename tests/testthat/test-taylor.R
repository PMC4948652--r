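test_that("closed-form second-order corrections match their derivations", {
  # symmetry point: curvature term vanishes
  expect_equal(taylor2_expit(0, 3), 0.5)
  expect_equal(taylor2_expit(2, 0), plogis(2))
  expect_equal(taylor2_cloglog(0.3, 0), 1 - exp(-exp(0.3)))
  # limit of the inverse-cloglog
  expect_equal(taylor2_cloglog(-40, 0.25), 0, tolerance = 1e-12)
  # both track the Gauss-Hermite oracle at moderate variance
  expect_lt(abs(taylor2_expit(2, 0.25) - gh_expectation(plogis, 2, 0.5)),
            2e-3)
  expect_lt(abs(taylor2_cloglog(0, 0.25) -
                gh_expectation(function(x) 1 - exp(-exp(x)), 0, 0.5)),
            5e-3)
  expect_error(taylor2_expit(0, -1), "var")
})

test_that("segment moments partition the sample correctly", {
  x <- withr::with_seed(8, rnorm(4e4))
  m1 <- segment_moments(x, 1)
  expect_equal(m1$mean, mean(x))
  expect_equal(m1$m2, mean((x - mean(x))^2))
  m2 <- segment_moments(x, 2)
  expect_equal(sum(m2$weight), 1)
  # symmetric sample: segment means symmetric about the overall mean
  expect_equal(m2$mean[1] + m2$mean[2], 2 * mean(x), tolerance = 0.02)
  # standard normal quartile means are +/- 1.27 and +/- 0.32 (closed form)
  m4 <- segment_moments(x, 4)
  expect_equal(m4$mean, c(-1.27, -0.32, 0.32, 1.27), tolerance = 0.03)
  expect_true(all(diff(m4$mean) > 0))
  expect_error(segment_moments(1:3, 5), "fewer samples")
  expect_warning(segment_moments(rnorm(50), 2), "noisy")
})

test_that("taylor_expect is exact for linear functions and point masses", {
  lin <- list(fn = function(x) 2 * x + 1, d2 = function(x) 0 * x)
  mom <- segment_moments(withr::with_seed(9, rnorm(2e4, 3, 2)), 4)
  expect_equal(taylor_expect(lin, mom, 2, shift = 0),
               2 * sum(mom$weight * mom$mean) + 1)
  m0 <- tibble::tibble(segment = 1, weight = 1, mean = 1.5,
                       m2 = 0, m3 = 0, m4 = 0)
  expect_equal(taylor_expect("expit", m0, 4, shift = 0.5), plogis(2))
  expect_error(taylor_expect(lin, mom, 4), "d3")
  expect_error(taylor_expect("expit", mom, 3), "order")
})

test_that("segment averaging improves on raising the expansion order", {
  x <- withr::with_seed(10, rnorm(2e5))
  grid <- seq(-4, 4, by = 0.25)
  truth <- vapply(grid, function(s) gh_expectation(plogis, s, 1), numeric(1))
  err <- function(mom, order) {
    max(abs(taylor_expect("expit", mom, order, grid) - truth))
  }
  mom1 <- segment_moments(x, 1)
  mom4 <- segment_moments(x, 4)
  mom8 <- segment_moments(x, 8)
  # error shrinks along the segment ladder 1 -> 4 -> 8
  expect_gt(err(mom1, 2), err(mom4, 2))
  expect_gt(err(mom4, 2), err(mom8, 2))
  # four-segment order 2 beats a single order-4 expansion
  expect_lt(err(mom4, 2), err(mom1, 4))
  # and meets the absolute oracle tolerance at sd <= 1
  expect_lt(err(mom4, 2), 5e-3)
})

test_that("approximation error shrinks with segments across sd values", {
  grid <- seq(-3, 3, by = 0.5)
  for (sdv in c(0.5, 1, 1.5)) {
    x <- withr::with_seed(11, rnorm(1e5, 0, sdv))
    truth <- vapply(grid, function(s) gh_expectation(plogis, s, sdv),
                    numeric(1))
    errs <- vapply(c(1, 4, 8), function(k) {
      max(abs(taylor_expect("expit", segment_moments(x, k), 2, grid) - truth))
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
  }
})

test_that("taylor EVPPI with zero-variance nonfocals is plain plug-in", {
  marg <- list(
    marginal_spec("alpha", "fixed", value = -1.07),
    marginal_spec("d_saline", "normal", mean = -0.31, sd = sqrt(0.51)),
    marginal_spec("d_albumin", "normal", mean = -2.34, sd = sqrt(0.64)),
    marginal_spec("d_gelofusine", "normal", mean = -0.19, sd = sqrt(1.81)),
    marginal_spec("dS", "normal", mean = 1.88, sd = sqrt(4.52)),
    marginal_spec("pB", "fixed", value = 0.1),
    marginal_spec("pL", "beta", shape1 = 1, shape2 = 1),
    marginal_spec("qM", "normal", mean = 19.99, sd = 5),
    marginal_spec("qS", "truncnorm", mean = 5, sd = 3.16, lower = 0)
  )
  d <- sample_posterior(posterior_spec(marg), 5000, seed = 14)
  est <- evppi(d, c("dM", "dS"), 250, method = "m4")
  # alpha and pB are known: the Taylor terms collapse to the exact expits
  plug <- evppi_single_step(d, c("dM", "dS"), function(s, w, ctx) {
    st <- voitools:::nb_streams(s, ctx)
    eb1 <- w * mean(s$qM) - ctx$c_hosp
    eb2 <- mean(s$pL) * (w * mean(s$qS) + ctx$c_ns)
    cm <- st$u * eb1 - st$v * eb2
    cm <- sweep(cm, 2, ctx$c_fluid[colnames(cm)], `-`)
    cbind(none = 0, cm)
  }, 250, method_label = "plug")
  expect_equal(est$estimate, plug$estimate, tolerance = 1e-10)
  expect_equal(est$settings[[1]]$clipped, 0L)
})

test_that("taylor EVPPI tracks the quadrature oracle on an independent toy", {
  # two-arm model: B2 = 10 expit(t1 + t2) - 6, t1 focal, t2 nonfocal normal
  toy <- toy_suite()$expit_indep
  d <- sample_toy(toy, 5e4, seed = 15)
  oracle <- quadrature_evppi(toy, "t1")
  mom <- segment_moments(d$t2, 4)
  cond <- function(s, w, ctx) {
    cbind(0, 10 * taylor_expect("expit", mom, 2, shift = s$t1) - 6)
  }
  est <- evppi_single_step(d, "t1", cond, NA, method_label = "m4-toy")
  expect_within_se(est$estimate, oracle, est$mc_se)
  expect_error(evppi_taylor(fluid_fixture(1000), "qM", 250),
               class = "voitools_condition_violation")
})
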