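test_that("the restricted basis is linear in the tails and C2 at the knots", {
  knots <- c(-1.2, -0.3, 0.4, 1.1, 2.0)
  # left of the first knot every cubic term is zero
  xl <- seq(-3, -1.2, length.out = 20)
  b <- rcs_basis(xl, knots)
  expect_true(all(b[, -1] == 0))
  # numeric second derivative vanishes beyond both boundary knots
  d2 <- function(x, h = 1e-4) {
    (rcs_basis(x + h, knots) - 2 * rcs_basis(x, knots) +
       rcs_basis(x - h, knots)) / h^2
  }
  expect_lt(max(abs(d2(-1.5))), 1e-6)
  expect_lt(max(abs(d2(2.4))), 1e-6)
  # value and first derivative continuous across each knot
  h <- 1e-6
  for (tau in knots) {
    lhs <- (rcs_basis(tau, knots) - rcs_basis(tau - h, knots)) / h
    rhs <- (rcs_basis(tau + h, knots) - rcs_basis(tau, knots)) / h
    expect_lt(max(abs(rhs - lhs)), 1e-4)
    expect_lt(max(abs(rcs_basis(tau + h, knots) - rcs_basis(tau - h, knots))),
              1e-5)
  }
  expect_error(rcs_basis(0, c(1, 2)), "3 knots")
  expect_error(rcs_basis(0, c(2, 1, 3)), "increasing")
  expect_error(rcs_basis(NA_real_, knots),
               class = "voitools_invalid_parameter")
})

test_that("equal-count bins summarise the sample faithfully", {
  x <- withr::with_seed(20, rnorm(2e4))
  h <- cbind(ident = x, indep = withr::with_seed(21, rnorm(2e4)))
  bins <- make_bins(x, h, 50)
  expect_equal(sum(bins$n), 2e4)
  expect_true(all(abs(bins$n - 400) <= 1))
  # identity term: bin means coincide exactly with focal bin means
  expect_equal(unname(bins$h_bar[, "ident"]), bins$phi_bar)
  # independent term: bin means stay near the overall mean
  z <- (bins$h_bar[, "indep"] - mean(h[, "indep"])) / bins$h_se[, "indep"]
  expect_lt(max(abs(z)), 5)
  # single bin = overall means
  b1 <- make_bins(x, h, 1)
  expect_equal(unname(b1$h_bar[1, ]), unname(colMeans(h)))
  # discrete focal values trigger merge-and-warn
  expect_warning(make_bins(rep(c(1, 2), 500), cbind(rep(1, 1000)), 10),
                 "merging")
  tb <- as_tibble(bins)
  expect_equal(nrow(tb), 100)
})

test_that("knots are equally spaced strictly inside the focal range", {
  x <- withr::with_seed(22, runif(1e4))
  bins <- make_bins(x, cbind(x), 100)
  k <- choose_knots(bins, 10)
  expect_equal(length(k), 10)
  expect_true(all(diff(k) > 0))
  expect_equal(sd(diff(k)), 0, tolerance = 1e-12)
  expect_gt(min(k), min(x))
  expect_lt(max(k), max(x))
  expect_error(choose_knots(bins, 2), "3 knots")
})

test_that("the fit reproduces lines and recovers a known spline exactly", {
  x <- seq(0, 1, length.out = 60)
  knots <- choose_knots(quantile(x, seq(0, 1, 0.1)), 5)
  lin <- fit_rcs(x, 3 - 2 * x, knots)
  expect_lt(lin$max_resid, 1e-10)
  expect_equal(unname(lin$coef[1:2]), c(3, -2), tolerance = 1e-8)
  # data generated from a spline in the same basis is recovered
  gamma <- c(0.5, 1.2, -4, 7, -5)
  y <- drop(cbind(1, rcs_basis(x, knots)) %*% gamma)
  fit <- fit_rcs(x, y, knots)
  expect_equal(unname(fit$coef), gamma, tolerance = 1e-8)
  expect_lt(fit$max_resid, 1e-10)
  expect_equal(predict(fit, x), y, tolerance = 1e-10)
  expect_gt(glance(fit)$r.squared, 1 - 1e-12)
  expect_equal(nrow(tidy(fit)), 5)
  # a constant regressor collapses the basis onto the intercept
  expect_error(fit_rcs(rep(0.5, 10), rnorm(10), c(0.2, 0.4, 0.6)),
               "collinear|rank")
})

test_that("spline conditional means converge to quadrature conditionals", {
  # correlated bivariate normal: E[10 expit(t1 + t2) | t1] known by quadrature
  toy <- toy_suite()$expit_corr
  d <- sample_toy(toy, 2e5, seed = 23)
  h <- 10 * plogis(d$t1 + d$t2) - 6
  oracle_cond <- function(t1) {
    mu <- 0.5 + 0.5 * 0.8 / 1 * (t1 - 1)   # rho sigma2/sigma1 conditional mean
    sdv <- 0.8 * sqrt(1 - 0.25)
    vapply(t1, function(ti) {
      gh_expectation(function(z) 10 * plogis(ti + z) - 6,
                     0.5 + 0.4 * (ti - 1), sdv)
    }, numeric(1))
  }
  # interior evaluation grid: at the extreme percentiles the fit relies on
  # its linear tails, which is an extrapolation property, not convergence
  grid <- quantile(d$t1, seq(0.025, 0.975, length.out = 101))
  oracle_vals <- oracle_cond(grid)
  err_at <- function(m_bins) {
    bins <- make_bins(d$t1, cbind(h = h), m_bins)
    fit <- fit_rcs(bins, "h", choose_knots(bins, 10))
    max(abs(predict(fit, grid) - oracle_vals))
  }
  e100 <- err_at(100)
  # the fitted conditional is accurate to ~1% of the net-benefit range
  expect_lt(e100, 0.1)
  # refining the bins does not hurt on the common evaluation grid
  expect_lt(e100, err_at(25) + 0.02)
})

test_that("spline EVPPI agrees with an exact conditional when one exists", {
  # break the dS / treatment-effect correlation by permuting dS: then
  # E[B_j | dS] factorises exactly as E[u_j] * (quadrature over pB of the
  # saved-patient NS probability at each dS), an independent oracle
  d <- fluid_fixture(5e4)
  d$dS <- withr::with_seed(30, sample(d$dS))
  est_m5 <- evppi(d, "dS", 250, method = "m5")
  ctx <- fluid_context()
  st <- voitools:::nb_streams(d, ctx)
  pb_nodes <- quantile(d$pB, (seq_len(256) - 0.5) / 256)
  e_s_given_ds <- rowMeans(vapply(pb_nodes, function(pb) {
    r <- pb * exp(d$dS); r / (1 + r)
  }, numeric(nrow(d))))
  eb1 <- 250 * mean(d$qM) - ctx$c_hosp
  eb2 <- mean(d$pL) * (250 * mean(d$qS) + ctx$c_ns)
  cm <- vapply(colnames(st$u), function(j) {
    mean(st$u[, j]) * (eb1 - e_s_given_ds * eb2) - ctx$c_fluid[[j]]
  }, numeric(nrow(d)))
  exact <- evppi_single_step(d, "dS", function(s, w, cc) cbind(none = 0, cm),
                             250, method_label = "exact-cond")
  expect_within_se(est_m5$estimate, exact$estimate,
                   sqrt(est_m5$mc_se^2 + exact$mc_se^2))
})

test_that("spline EVPPI is stable in the number of knots", {
  d <- fluid_fixture(2e5)
  # dS and the albumin effect have smooth, well-spread conditional means;
  # pB's conditional curvature near zero is examined in the acceptance suite
  for (f in c("dS", "d_albumin")) {
    e6 <- evppi(d, f, 250, method = "m5", n_knots = 6)
    e10 <- evppi(d, f, 250, method = "m5", n_knots = 10)
    expect_lt(abs(e6$estimate - e10$estimate) / e10$estimate, 0.015)
  }
  expect_error(evppi_spline(d, c("dM"), 250),
               class = "voitools_not_supported")
  expect_error(evppi_spline(d, "qM", 250),
               class = "voitools_condition_violation")
})
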