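#' Decision context for the fluid-resuscitation model
#'
#' Bundles the economic constants and treatment arms of the cost-effectiveness
#' model for fluid resuscitation of children hospitalised with severe malaria.
#' Four strategies are compared: no fluid (the reference), albumin, saline,
#' and gelofusine.  Each fluid changes the log-odds of death by a
#' treatment-specific amount (`d_albumin`, `d_saline`, `d_gelofusine`), and
#' survivors "saved" by treatment have their log-odds of neurological
#' sequelae (NS) shifted by `dS`.
#'
#' @param treatments Named numeric vector of per-patient fluid costs (USD),
#'   first element the zero-cost reference arm.
#' @param effects Named character vector mapping each non-reference treatment
#'   to the column of the sample matrix holding its log-odds-ratio of death.
#' @param c_hosp Incremental hospital cost of surviving (USD); default $60
#'   (five extra inpatient days at $12/day).
#' @param c_ns Discounted lifetime cost of managing long-term NS (USD).
#'
#' @return An object of class `voi_context`.
#' @examples
#' fluid_context()
#' @export
fluid_context <- function(treatments = c(none = 0, albumin = 35, saline = 1,
                                         gelofusine = 12.5),
                          effects = c(albumin = "d_albumin",
                                      saline = "d_saline",
                                      gelofusine = "d_gelofusine"),
                          c_hosp = 60, c_ns = 20000) {
  if (treatments[[1]] != 0) {
    abort("the first (reference) treatment must have zero fluid cost")
  }
  if (any(treatments < 0) || c_hosp < 0 || c_ns < 0) {
    abort("costs must be non-negative")
  }
  if (!setequal(names(effects), names(treatments)[-1])) {
    abort("`effects` must name every non-reference treatment")
  }
  structure(
    list(treatments = names(treatments),
         c_fluid = treatments,
         effects = effects[names(treatments)[-1]],
         c_hosp = c_hosp,
         c_ns = c_ns),
    class = "voi_context"
  )
}

#' @export
print.voi_context <- function(x, ...) {
  cat("<voi_context> fluid-resuscitation decision model\n")
  cat("  treatments:",
      paste0(x$treatments, " ($", x$c_fluid, ")", collapse = ", "), "\n")
  cat("  hospital cost of survival: $", x$c_hosp,
      "; lifetime NS cost: $", x$c_ns, "\n", sep = "")
  invisible(x)
}

#' Probability of death under a fluid arm
#'
#' Inverse logit of the baseline log-odds of death plus the arm's
#' log-odds-ratio (`0` for the reference arm).
#'
#' @param alpha Baseline log-odds of death without fluids.
#' @param d Log-odds-ratio of death for the fluid arm.
#' @return Probability in (0, 1).
#' @examples
#' prob_death(0, 0)           # 0.5
#' prob_death(-log(3), 0)     # 0.25
#' @export
prob_death <- function(alpha, d = 0) {
  stopifnot_finite(alpha, "alpha")
  stopifnot_finite(d, "d")
  plogis(alpha + d)
}

#' Probability of neurological sequelae among "saved" patients
#'
#' Patients who survive only because of fluid therapy have their NS risk
#' shifted by `dS` relative to baseline, composed on the log scale of `pB`:
#' `pB * exp(dS) / (1 + pB * exp(dS))`.  Note the composition is with
#' `log(pB)`, not `logit(pB)`, so at `pB = 1` the value is
#' `exp(dS) / (1 + exp(dS))`, not 1; boundary values are permitted (they are
#' measure-zero under the Beta(1, 9) prior) and flagged with a warning.
#'
#' @param pB Baseline probability of NS without fluids.
#' @param dS Log-scale shift in NS odds among saved patients.
#' @return Probability in \[0, 1).
#' @examples
#' prob_ns_saved(0.5, 0)   # 1/3
#' @export
prob_ns_saved <- function(pB, dS) {
  stopifnot_finite(pB, "pB")
  stopifnot_finite(dS, "dS")
  if (any(pB < 0 | pB > 1)) abort("pB must lie in [0, 1]")
  if (any(pB == 0 | pB == 1)) {
    warn("pB on the boundary of [0, 1]; using the limiting formula value")
  }
  r <- pB * exp(dS)
  r / (1 + r)
}

# Validate a sample matrix/tibble against the parameters the context needs.
check_samples <- function(samples, context) {
  need <- c("alpha", unname(context$effects), "dS", "pB", "pL", "qM", "qS")
  miss <- setdiff(need, colnames(samples))
  if (length(miss)) {
    abort(paste0("samples are missing columns: ", paste(miss, collapse = ", ")))
  }
  invisible(samples)
}

# N x J matrix of incremental net benefit, reference arm first (all zero).
# Split as nb = a + wtp * b so curves over many thresholds are cheap.
nb_components <- function(samples, context) {
  check_samples(samples, context)
  p0 <- plogis(samples$alpha)
  s  <- prob_ns_saved(samples$pB, samples$dS)
  ns_q <- samples$pL * s * samples$qS          # expected QALY loss via NS
  ns_c <- samples$pL * s * context$c_ns        # expected NS cost
  J <- length(context$treatments)
  n <- nrow(samples)
  a <- b <- matrix(0, n, J, dimnames = list(NULL, context$treatments))
  for (j in seq_len(J - 1L)) {
    trt <- context$treatments[j + 1L]
    u <- p0 - plogis(samples$alpha + samples[[context$effects[[trt]]]])
    a[, j + 1L] <- u * (-context$c_hosp - ns_c) - context$c_fluid[[trt]]
    b[, j + 1L] <- u * (samples$qM - ns_q)
  }
  list(a = a, b = b)
}

nb_matrix <- function(samples, wtp, context) {
  cmp <- nb_components(samples, context)
  cmp$a + wtp * cmp$b
}

#' Incremental net benefit of each treatment
#'
#' Per-draw incremental net monetary benefit of every arm relative to no
#' fluid: the mortality reduction times the monetary value of the health a
#' survivor gains (`wtp * qM` minus hospital costs and expected NS
#' consequences among saved patients), minus the fluid cost.
#'
#' @param samples Data frame of joint parameter draws (see
#'   [sample_posterior()]).
#' @param wtp Willingness to pay per QALY (USD), a single value.
#' @param context A [fluid_context()].
#' @return A tibble with one column per treatment, one row per draw; the
#'   reference column is identically zero.
#' @examples
#' draws <- sample_posterior(posterior_spec(), 100, seed = 1)
#' net_benefit(draws, wtp = 250)
#' @export
net_benefit <- function(samples, wtp, context = fluid_context()) {
  stopifnot(length(wtp) == 1L, wtp >= 0)
  tibble::as_tibble(nb_matrix(samples, wtp, context))
}

#' Net benefit by enumerating patient outcomes
#'
#' Independent accounting of the same quantity as [net_benefit()]: each arm's
#' expected `wtp * utility - cost` is built by enumerating the four patient
#' outcomes (death; NS-free survival; short-term NS; long-term NS).  Under a
#' fluid arm the survivors split into those who would have survived anyway
#' (NS risk `pB`) and those saved by treatment (NS risk
#' [prob_ns_saved()]).  Serves as an algebraic cross-check on the closed-form
#' net-benefit expression.
#'
#' @inheritParams net_benefit
#' @return A tibble like [net_benefit()]'s.
#' @export
outcome_net_benefit <- function(samples, wtp, context = fluid_context()) {
  check_samples(samples, context)
  p0 <- plogis(samples$alpha)
  s  <- prob_ns_saved(samples$pB, samples$dS)

  arm_value <- function(p_die, p_ns28, c_fluid) {
    # p_ns28: probability of NS at 28 d among this arm's survivors (already
    # weighted over the anyway-survivor / saved split)
    p_surv <- 1 - p_die
    p_no_ns <- p_surv - p_ns28
    p_short <- p_ns28 * (1 - samples$pL)
    p_long  <- p_ns28 * samples$pL
    tot <- p_die + p_no_ns + p_short + p_long
    if (any(abs(tot - 1) > 1e-12)) {
      abort("internal consistency error: outcome probabilities do not sum to 1")
    }
    utility <- samples$qM * (p_no_ns + p_short) + (samples$qM - samples$qS) * p_long
    cost <- c_fluid + context$c_hosp * p_surv + context$c_ns * p_long
    wtp * utility - cost
  }

  ref <- arm_value(p0, (1 - p0) * samples$pB, 0)
  out <- matrix(0, nrow(samples), length(context$treatments),
                dimnames = list(NULL, context$treatments))
  for (trt in context$treatments[-1]) {
    pj <- plogis(samples$alpha + samples[[context$effects[[trt]]]])
    p_ns28 <- (1 - p0) * samples$pB + (p0 - pj) * s
    out[, trt] <- arm_value(pj, p_ns28, context$c_fluid[[trt]]) - ref
  }
  tibble::as_tibble(out)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of posterior draws on which each treatment attains the maximal
#' incremental net benefit, at one or more willingness-to-pay thresholds.
#' Ties (measure-zero for continuous draws) go to the earliest arm.
#'
#' @inheritParams net_benefit
#' @param wtp Vector of willingness-to-pay thresholds (USD/QALY).
#' @return A tibble with columns `wtp`, `treatment`, `probability`;
#'   probabilities sum to 1 within each threshold.
#' @examples
#' draws <- sample_posterior(posterior_spec(), 5000, seed = 1)
#' ceac(draws, wtp = c(100, 250, 1000))
#' @export
ceac <- function(samples, wtp, context = fluid_context()) {
  if (nrow(samples) == 0L) abort("empty sample")
  cmp <- nb_components(samples, context)
  J <- length(context$treatments)
  out <- purrr::map_dfr(wtp, function(w) {
    best <- max.col(cmp$a + w * cmp$b, ties.method = "first")
    tibble::tibble(
      wtp = w,
      treatment = factor(context$treatments, levels = context$treatments),
      probability = tabulate(best, nbins = J) / nrow(samples)
    )
  })
  class(out) <- c("voi_ceac", class(out))
  out
}

#' Threshold at which the optimal treatment switches
#'
#' Scans a willingness-to-pay grid for changes in the treatment with maximal
#' *mean* incremental net benefit, then refines each change point by
#' bisection (mean net benefit is affine in `wtp`, so bisection converges to
#' the exact crossing) to better than $1 resolution.
#'
#' @inheritParams net_benefit
#' @param wtp Strictly increasing grid of thresholds with at least 2 points.
#' @return A tibble with columns `wtp` (the switching threshold), `from`,
#'   `to`; zero rows when the optimum never changes on the grid.
#' @export
switching_threshold <- function(samples, context = fluid_context(),
                                wtp = seq(0, 4000, by = 10)) {
  if (length(wtp) < 2L || any(diff(wtp) <= 0)) {
    abort("`wtp` must be a strictly increasing grid with >= 2 points")
  }
  cmp <- nb_components(samples, context)
  a <- colMeans(cmp$a)
  b <- colMeans(cmp$b)
  best_at <- function(w) which.max(a + w * b)
  best <- vapply(wtp, best_at, integer(1))
  ix <- which(diff(best) != 0L)
  purrr::map_dfr(ix, function(i) {
    lo <- wtp[i]; hi <- wtp[i + 1L]
    from <- best[i]; to <- best[i + 1L]
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (best_at(mid) == from) lo <- mid else hi <- mid
    }
    tibble::tibble(wtp = (lo + hi) / 2,
                   from = context$treatments[from],
                   to = context$treatments[best_at(hi)])
  })
}

#' EVPI across a willingness-to-pay grid
#'
#' @inheritParams switching_threshold
#' @param wtp Vector of thresholds.
#' @return A tibble of [evpi()] rows, one per threshold, of class
#'   `voi_curve` for plotting.
#' @export
evpi_curve <- function(samples, context = fluid_context(),
                       wtp = seq(50, 4000, by = 50)) {
  cmp <- nb_components(samples, context)
  out <- purrr::map_dfr(wtp, function(w) evpi_from_nb(cmp$a + w * cmp$b, w))
  class(out) <- c("voi_curve", class(out))
  out
}
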