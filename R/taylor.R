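# Analytic derivatives to order 4, parameterised by H = h(x).
# expit: h' = H(1-H); higher orders stay polynomial in H.
# inverse-cloglog F(x) = 1 - exp(-exp(x)): with u = exp(x), H = exp(-u),
# F'' = H u (1 - u), F''' = H (u - 3u^2 + u^3), F'''' = H (u - 7u^2 + 6u^3 - u^4).
taylor_family <- function(h) {
  if (is.list(h)) return(h)
  switch(h,
    expit = list(
      fn = plogis,
      d2 = function(x) { H <- plogis(x); H * (1 - H) * (1 - 2 * H) },
      d3 = function(x) { H <- plogis(x); H * (1 - H) * (1 - 6 * H + 6 * H^2) },
      d4 = function(x) { H <- plogis(x)
                         H * (1 - H) * (1 - 2 * H) * (1 - 12 * H + 12 * H^2) }
    ),
    cloglog = list(
      fn = function(x) 1 - exp(-exp(x)),
      d2 = function(x) { u <- exp(x); exp(-u) * u * (1 - u) },
      d3 = function(x) { u <- exp(x); exp(-u) * (u - 3 * u^2 + u^3) },
      d4 = function(x) { u <- exp(x); exp(-u) * (u - 7 * u^2 + 6 * u^3 - u^4) }
    ),
    abort(paste0("unknown function family: ", h))
  )
}

#' Per-segment moments of an empirical distribution
#'
#' Splits a sample into `n_segments` equal-probability segments by quantiles
#' and returns each segment's mass, mean, and central moments up to order 4
#' — the ingredients of the quantile-averaged Taylor approximation.
#'
#' @param x Numeric sample of the nonfocal parameter.
#' @param n_segments Number of segments (1 = a single expansion about the
#'   overall mean; 4 = expansions about the interquartile means).
#' @return A tibble with columns `segment`, `weight`, `mean`, `m2`, `m3`,
#'   `m4`; weights sum to 1 and segment means are nondecreasing.
#' @examples
#' segment_moments(rnorm(1e4), 4)
#' @export
segment_moments <- function(x, n_segments = 4L) {
  if (n_segments < 1L) abort("n_segments must be >= 1")
  if (length(x) < n_segments) abort("fewer samples than segments")
  if (length(x) < 100L * n_segments) {
    warn("fewer than 100 samples per segment; moments will be noisy")
  }
  if (n_segments == 1L) {
    g <- rep(1L, length(x))
  } else {
    br <- quantile(x, probs = seq(0, 1, length.out = n_segments + 1L))
    g <- findInterval(x, br[-c(1L, n_segments + 1L)]) + 1L
  }
  out <- purrr::map_dfr(seq_len(n_segments), function(q) {
    xs <- x[g == q]
    if (!length(xs)) return(NULL)     # ties can leave a segment empty
    mu <- mean(xs)
    tibble::tibble(segment = q, weight = length(xs) / length(x), mean = mu,
                   m2 = mean((xs - mu)^2), m3 = mean((xs - mu)^3),
                   m4 = mean((xs - mu)^4))
  })
  out
}

#' Taylor-series expectation of a smooth function
#'
#' Approximates `E[h(shift + X)]` where `X` is the nonfocal parameter
#' summarised by [segment_moments()]: within each quantile segment, `h` is
#' expanded to `order` around the segment mean (the first-order term
#' vanishes by centering) and the segment approximations are averaged with
#' their probability masses.  More segments shrink the range over which each
#' local expansion must hold, which is more effective than raising the order.
#'
#' @param h `"expit"`, `"cloglog"`, or a list with functions `fn`, `d2` and
#'   (for order 4) `d3`, `d4`.
#' @param moments A [segment_moments()] tibble.
#' @param order 2 or 4.
#' @param shift Known offset(s) added to the argument, e.g. the focal
#'   parameter values; vectorised.
#' @return Approximate expectations, one per element of `shift`.
#' @examples
#' mom <- segment_moments(rnorm(1e4, 0, 1), 4)
#' taylor_expect("expit", mom, order = 2, shift = 2)
#' @export
taylor_expect <- function(h, moments, order = 2L, shift = 0) {
  if (!order %in% c(2L, 4L)) abort("order must be 2 or 4")
  fam <- taylor_family(h)
  if (order == 4L && (is.null(fam$d3) || is.null(fam$d4))) {
    abort("order-4 expansion needs d3 and d4 derivatives")
  }
  out <- numeric(length(shift))
  for (q in seq_len(nrow(moments))) {
    x <- shift + moments$mean[q]
    v <- fam$fn(x) + fam$d2(x) / 2 * moments$m2[q]
    if (order == 4L) {
      v <- v + fam$d3(x) / 6 * moments$m3[q] + fam$d4(x) / 24 * moments$m4[q]
    }
    out <- out + moments$weight[q] * v
  }
  out
}

#' Second-order Taylor approximation to an expit expectation
#'
#' Closed form for `E[expit(mean_shift + X)]` with `Var[X] = var`, expanded
#' about the mean: `H + H(1-H)(1-2H) var / 2` with `H = expit(mean_shift)`.
#'
#' @param mean_shift Expansion point (focal value plus nonfocal mean).
#' @param var Variance of the nonfocal parameter.
#' @return Approximate expectation.
#' @examples
#' taylor2_expit(0, 0.5)  # exactly 0.5: the curvature term vanishes
#' @export
taylor2_expit <- function(mean_shift, var) {
  if (any(var < 0)) abort("var must be >= 0")
  H <- plogis(mean_shift)
  H + H * (1 - H) * (1 - 2 * H) * var / 2
}

#' Second-order Taylor approximation to an inverse-cloglog expectation
#'
#' Closed form for `E[1 - exp(-exp(mean_shift + X))]` with `Var[X] = var`.
#' With `H = exp(-exp(mean_shift))` and `u = exp(mean_shift) = -log(H)`, the
#' second derivative of the inverse-cloglog is `H u (1 - u)`, so the
#' approximation is `1 - H - H log(H) (1 + log(H)) var / 2`.
#'
#' @inheritParams taylor2_expit
#' @return Approximate expectation.
#' @export
taylor2_cloglog <- function(mean_shift, var) {
  if (any(var < 0)) abort("var must be >= 0")
  u <- exp(mean_shift)
  H <- exp(-u)
  1 - H + H * u * (1 - u) * var / 2
}

#' EVPPI by quantile-averaged Taylor approximation (method 4)
#'
#' Single-step EVPPI for the two focal sets whose conditional expectations
#' involve smooth nonlinear functions of one independent nonfocal parameter
#' each: the treatment-effect set `{dM, dS}` (expectations over `alpha` and
#' over `log(pB)`) and `{alpha, pB}` (expectations over each treatment
#' effect and over `dS`).  Each required conditional expectation of an expit
#' term is approximated by [taylor_expect()] with the given order and
#' segment count; the remaining nonfocal parameters enter linearly and are
#' replaced by sample means.  Approximated probabilities are clipped to
#' \[0, 1\] and the clip count reported in `settings`.
#'
#' For `{alpha, pB}` the two expit terms carry the correlated pair
#' `(d_j, dS)` in a product whose expectation is factorised; the modest
#' effect-block correlations are thereby neglected in that cross term.
#'
#' @inheritParams evppi_single_step
#' @param order Expansion order, 2 (default) or 4.
#' @param n_segments Quantile segments for the averaging adaptation;
#'   default 4 (interquartile means).
#' @return A one-row estimate tibble.
#' @export
evppi_taylor <- function(samples, focal, wtp, context = fluid_context(),
                         order = 2L, n_segments = 4L) {
  focal <- expand_focal(focal, context)
  dm <- unname(context$effects)
  key <- paste(sort(focal), collapse = "|")
  sets <- c(paste(sort(c(dm, "dS")), collapse = "|"),
            paste(sort(c("alpha", "pB")), collapse = "|"))
  if (!key %in% sets) {
    abort("method 4 applies to focal sets {dM, dS} and {alpha, pB} only",
          class = "voitools_condition_violation")
  }
  trt <- context$treatments[-1]
  n <- nrow(samples)
  clipped <- 0L
  clip01 <- function(x) {
    k <- sum(x < 0 | x > 1)
    if (k > 0) clipped <<- clipped + k
    pmin(1, pmax(0, x))
  }

  if (key == sets[1]) {                      # focal = {dM, dS}
    mom_a <- segment_moments(samples$alpha, n_segments)
    mom_lp <- segment_moments(log(samples$pB), n_segments)
    e_h11 <- clip01(taylor_expect("expit", mom_a, order, shift = 0))
    e_h1 <- vapply(trt, function(t) {
      clip01(taylor_expect("expit", mom_a, order,
                           shift = samples[[context$effects[[t]]]]))
    }, numeric(n))
    e_h2 <- clip01(taylor_expect("expit", mom_lp, order, shift = samples$dS))
  } else {                                   # focal = {alpha, pB}
    e_h11 <- plogis(samples$alpha)
    e_h1 <- vapply(trt, function(t) {
      mom_d <- segment_moments(samples[[context$effects[[t]]]], n_segments)
      clip01(taylor_expect("expit", mom_d, order, shift = samples$alpha))
    }, numeric(n))
    mom_ds <- segment_moments(samples$dS, n_segments)
    e_h2 <- clip01(taylor_expect("expit", mom_ds, order,
                                 shift = log(samples$pB)))
  }

  e_b1 <- wtp * mean(samples$qM) - context$c_hosp
  e_b2 <- mean(samples$pL) * (wtp * mean(samples$qS) + context$c_ns)
  cm <- (e_h11 - e_h1) * (e_b1 - e_h2 * e_b2)
  cm <- sweep(cm, 2, context$c_fluid[trt], `-`)
  cm <- cbind(matrix(0, n, 1, dimnames = list(NULL, context$treatments[1])), cm)

  evppi_single_step(samples, focal, function(s, w, ctx) cm, wtp, context,
                    method_label = "m4",
                    settings = list(order = order, n_segments = n_segments,
                                    clipped = clipped))
}
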