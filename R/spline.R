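#' Restricted cubic spline basis
#'
#' Basis functions of a natural (restricted) cubic spline with knots `tau`:
#' a linear term plus, for each interior knot, a combination of truncated
#' cubes constructed so that every function in the span is continuously
#' twice differentiable and exactly linear outside `[tau_1, tau_K]`.  Any
#' coefficient vector therefore automatically satisfies the linear-tail
#' restriction.  Truncated-cube columns are scaled by `1 / (tau_K - tau_1)^2`
#' for numerical stability.
#'
#' @param x Evaluation points.
#' @param knots Strictly increasing vector of at least 3 knots.
#' @return A matrix with `length(knots) - 1` columns (linear term first).
#' @examples
#' b <- rcs_basis(seq(0, 1, 0.1), knots = c(0.2, 0.5, 0.8))
#' @export
rcs_basis <- function(x, knots) {
  stopifnot_finite(x, "x")
  k <- length(knots)
  if (k < 3L) abort("need at least 3 knots")
  if (any(diff(knots) <= 0)) abort("knots must be strictly increasing")
  scl <- (knots[k] - knots[1])^2
  cube <- function(t) pmax(x - t, 0)^3
  last <- cube(knots[k])
  penu <- cube(knots[k - 1L])
  cubes <- vapply(seq_len(k - 2L), function(n) {
    (cube(knots[n]) -
       penu * (knots[k] - knots[n]) / (knots[k] - knots[k - 1L]) +
       last * (knots[k - 1L] - knots[n]) / (knots[k] - knots[k - 1L])) / scl
  }, numeric(length(x)))
  out <- cbind(x, matrix(cubes, nrow = length(x)))
  colnames(out) <- c("x", paste0("c", seq_len(k - 2L)))
  out
}

#' Equal-count bin summaries of conditioning terms
#'
#' Step one of the spline conditional-expectation estimator: the focal
#' parameter's range is split into `m_bins` bins holding equal numbers of
#' draws (by empirical quantiles), and within each bin the mean of the focal
#' parameter and of every supplied term is recorded, with standard errors
#' for diagnostics.  Duplicate quantile boundaries (discrete focal values)
#' are merged with a warning.
#'
#' @param x Focal parameter draws.
#' @param terms Matrix (or data frame) of per-draw term values, one column
#'   per term stream.
#' @param m_bins Number of equal-count bins.
#' @return A `voi_bins` object: list with `boundaries`, `n`, `phi_bar`, and
#'   matrices `h_bar`, `h_se` (bins by terms).
#' @export
make_bins <- function(x, terms, m_bins = 100L) {
  terms <- as.matrix(terms)
  if (length(x) < m_bins) abort("fewer samples than bins")
  if (m_bins < 1L) abort("m_bins must be >= 1")
  br <- quantile(x, probs = seq(0, 1, length.out = m_bins + 1L))
  if (anyDuplicated(br)) {
    warn("duplicate bin boundaries; merging bins")
    br <- unique(br)
  }
  g <- findInterval(x, br[-c(1L, length(br))]) + 1L
  m <- length(br) - 1L
  n_g <- tabulate(g, m)
  if (any(n_g == 0L)) abort("internal error: empty bin after merging")
  gf <- factor(g, levels = seq_len(m))
  phi_bar <- drop(rowsum(x, gf)) / n_g
  h_bar <- rowsum(terms, gf) / n_g
  h_var <- (rowsum(terms^2, gf) - n_g * h_bar^2) / pmax(n_g - 1L, 1L)
  h_se <- sqrt(pmax(h_var, 0) / n_g)
  dimnames(h_bar) <- dimnames(h_se) <- list(NULL, colnames(terms))
  structure(list(boundaries = unname(br), n = n_g, phi_bar = unname(phi_bar),
                 h_bar = h_bar, h_se = h_se),
            class = "voi_bins")
}

#' @export
print.voi_bins <- function(x, ...) {
  cat("<voi_bins>", length(x$n), "equal-count bins,",
      ncol(x$h_bar), "term stream(s)\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.voi_bins <- function(x, ...) {
  nm <- colnames(x$h_bar) %||% paste0("term", seq_len(ncol(x$h_bar)))
  purrr::map_dfr(seq_along(nm), function(i) {
    tibble::tibble(bin = seq_along(x$n), n = x$n, phi_bar = x$phi_bar,
                   term = nm[i], h_bar = x$h_bar[, i], h_se = x$h_se[, i])
  })
}

#' Equally spaced knots inside the binned range
#'
#' Knot placement used by the spline estimator: `n_knots` equally spaced
#' points spanning the interior bin boundaries, so every knot lies strictly
#' inside the observed focal range.
#'
#' @param bins A [make_bins()] object (or a numeric vector of boundaries).
#' @param n_knots Number of knots (>= 3).
#' @return Numeric vector of knots.
#' @export
choose_knots <- function(bins, n_knots = 10L) {
  if (n_knots < 3L) abort("need at least 3 knots")
  br <- if (inherits(bins, "voi_bins")) bins$boundaries else bins
  if (length(br) < 3L) abort("need at least 2 bins to place interior knots")
  seq(br[2L], br[length(br) - 1L], length.out = n_knots)
}

#' Fit a restricted cubic spline to bin means
#'
#' Ordinary least squares of bin-mean term values on the restricted cubic
#' spline basis of the bin-mean focal values.  Equal-count binning makes the
#' bin means roughly homoscedastic, so the fit is unweighted.
#'
#' @param x Bin means of the focal parameter (or a `voi_bins` object, in
#'   which case `y` names one of its term columns).
#' @param y Bin means of the conditioning term.
#' @param knots Knot vector, e.g. from [choose_knots()].
#' @return An `rcs_fit` object with `knots`, `coef`, `r2`, `sigma`,
#'   `max_resid`, and the training data; supports `predict()`, [tidy()],
#'   [glance()], and [autoplot()].
#' @export
fit_rcs <- function(x, y, knots) {
  if (inherits(x, "voi_bins")) {
    bins <- x
    y <- bins$h_bar[, y]
    x <- bins$phi_bar
  }
  if (length(x) <= length(knots)) {
    abort("need more bins than basis dimensions")
  }
  X <- cbind(1, rcs_basis(x, knots))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])
    abort(paste0("rank-deficient spline basis; collinear columns: ",
                 paste(colnames(X)[bad], collapse = ", ")))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  structure(list(knots = knots,
                 coef = setNames(beta, c("(Intercept)", colnames(X)[-1])),
                 r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
                 sigma = sqrt(sum(res^2) / max(1, length(y) - ncol(X))),
                 max_resid = max(abs(res)),
                 x = x, y = y, fitted = fitted,
                 range = range(x)),
            class = "rcs_fit")
}

#' @export
predict.rcs_fit <- function(object, newdata, ...) {
  X <- cbind(1, rcs_basis(newdata, object$knots))
  drop(X %*% object$coef)
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat("<rcs_fit>", length(x$knots), "knots on [",
      signif(x$range[1], 4), ",", signif(x$range[2], 4),
      "], R^2 =", signif(x$r2, 4), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rcs_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @exportS3Method generics::glance
glance.rcs_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, sigma = x$sigma,
                 max_resid = x$max_resid, n_knots = length(x$knots),
                 nobs = length(x$x))
}

#' EVPPI by spline-estimated conditional expectations (method 5)
#'
#' Single-step EVPPI for a single focal parameter that enters the net
#' benefit nonlinearly and may be correlated with nonfocal parameters (any
#' of `alpha`, `pB`, `dS`, or a treatment effect).  The incremental net
#' benefit decomposes, per arm, into the two streams `u_j` (mortality
#' reduction) and `v_j = u_j * prob_ns_saved(pB, dS)` multiplied by
#' economically linear factors.  Each stream's conditional expectation given
#' the focal parameter is estimated by equal-count binning plus restricted
#' cubic spline regression on the bin means — which correctly absorbs any
#' correlation, because bin means of a term against the focal parameter
#' estimate its conditional expectation whatever the dependence — while
#' streams statistically independent of the focal parameter use their
#' overall means.
#'
#' @inheritParams evppi_single_step
#' @param m_bins Equal-count bins (default 100).
#' @param n_knots Equally spaced knots (default 10).
#' @param keep_fits Attach the per-stream `rcs_fit` objects and bin
#'   summaries to the result's `settings` for diagnostics?
#' @return A one-row estimate tibble.
#' @export
evppi_spline <- function(samples, focal, wtp, context = fluid_context(),
                         m_bins = 100L, n_knots = 10L, keep_fits = FALSE) {
  focal <- expand_focal(focal, context)
  if (length(focal) != 1L) {
    abort(paste0("method 5 supports a single focal parameter; multivariate ",
                 "focal sets would need multivariate splines"),
          class = "voitools_not_supported")
  }
  if (!focal %in% c("alpha", "pB", "dS", unname(context$effects))) {
    abort("method 5 applies to alpha, pB, dS, or a treatment effect",
          class = "voitools_condition_violation")
  }
  spec <- attr(samples, "spec") %||% posterior_spec()
  closure <- correlated_closure(spec, focal)
  st <- nb_streams(samples, context)
  trt <- context$treatments[-1]
  deps_u <- lapply(context$effects[trt], function(eff) c("alpha", eff))
  deps_v <- lapply(deps_u, function(d) c(d, "pB", "dS"))

  x <- samples[[focal]]
  streams <- cbind(st$u, st$v)
  colnames(streams) <- c(paste0("u_", trt), paste0("v_", trt))
  dep_list <- c(setNames(deps_u, paste0("u_", trt)),
                setNames(deps_v, paste0("v_", trt)))
  needs_fit <- vapply(dep_list, function(d) any(d %in% closure), logical(1))

  bins <- make_bins(x, streams[, needs_fit, drop = FALSE], m_bins)
  knots <- choose_knots(bins, n_knots)
  fits <- lapply(colnames(bins$h_bar), function(tm) {
    fit_rcs(bins, tm, knots)
  })
  names(fits) <- colnames(bins$h_bar)

  cond <- matrix(rep(colMeans(streams), each = nrow(samples)),
                 nrow(samples), ncol(streams),
                 dimnames = list(NULL, colnames(streams)))
  for (tm in names(fits)) cond[, tm] <- predict(fits[[tm]], x)

  e_b1 <- wtp * mean(samples$qM) - context$c_hosp
  e_b2 <- mean(samples$pL) * (wtp * mean(samples$qS) + context$c_ns)
  cm <- e_b1 * cond[, paste0("u_", trt), drop = FALSE] -
        e_b2 * cond[, paste0("v_", trt), drop = FALSE]
  cm <- sweep(cm, 2, context$c_fluid[trt], `-`)
  colnames(cm) <- trt
  cm <- cbind(matrix(0, nrow(samples), 1,
                     dimnames = list(NULL, context$treatments[1])), cm)

  settings <- list(m_bins = m_bins, n_knots = n_knots)
  if (keep_fits) settings <- c(settings, list(fits = fits, bins = bins))
  evppi_single_step(samples, focal, function(s, w, ctx) cm, wtp, context,
                    method_label = "m5", settings = settings)
}
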