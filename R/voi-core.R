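# Canonical parameter sets for the case-study model.
fluid_params <- function(context = fluid_context()) {
  c("alpha", unname(context$effects), "dS", "pB", "pL", "qM", "qS")
}

# Expand the "dM" shorthand (all treatment effects) and validate names.
expand_focal <- function(focal, context = fluid_context()) {
  focal <- unique(unlist(lapply(focal, function(f) {
    if (identical(f, "dM")) unname(context$effects) else f
  })))
  unknown <- setdiff(focal, fluid_params(context))
  if (length(unknown)) {
    abort(paste0("unknown focal parameter(s): ", paste(unknown, collapse = ", ")))
  }
  focal
}

row_max <- function(m) do.call(pmax, as.data.frame(m))

evpi_from_nb <- function(nb, wtp = NA_real_, method = "evpi",
                         focal = "all", settings = list()) {
  nb <- as.matrix(nb)
  if (nrow(nb) == 0L) abort("empty sample")
  jstar <- which.max(colMeans(nb))
  regret <- row_max(nb) - nb[, jstar]
  voi_estimate(method, focal, wtp,
               estimate = mean(regret),
               mc_se = sd(regret) / sqrt(nrow(nb)),
               n = nrow(nb), settings = settings)
}

#' Expected value of perfect information
#'
#' The expected gain from resolving all parameter uncertainty before
#' deciding: the mean over draws of the best achievable net benefit minus
#' the mean net benefit of the treatment that is optimal on average
#' (`j*`, the arm maximising the sample-mean net benefit).  Non-negative by
#' construction; the Monte Carlo standard error is that of the per-draw
#' regret.
#'
#' @inheritParams net_benefit
#' @return A one-row tibble: `method`, `focal`, `wtp`, `estimate`, `mc_se`,
#'   `n`, `settings`.
#' @examples
#' draws <- sample_posterior(posterior_spec(), 1e4, seed = 1)
#' evpi(draws, wtp = 250)
#' @export
evpi <- function(samples, wtp, context = fluid_context()) {
  evpi_from_nb(nb_matrix(samples, wtp, context), wtp)
}

#' EVPI of an arbitrary net-benefit table
#'
#' Same computation as [evpi()] but applied directly to a draws-by-treatments
#' net-benefit table (first column the reference arm), e.g. from a toy model.
#'
#' @param nb Matrix or data frame of per-draw net benefit, one column per
#'   treatment.
#' @param wtp Optional threshold recorded in the result.
#' @return A one-row estimate tibble.
#' @export
evpi_nb <- function(nb, wtp = NA_real_) {
  evpi_from_nb(nb, wtp)
}

#' Single-step EVPPI from a conditional net-benefit approximation
#'
#' The generic one-simulation estimator: for every draw of the focal
#' parameters, `cond_nb` supplies (an approximation to) the conditional
#' expectation of each arm's net benefit given those focal values; EVPPI is
#' the mean of the per-draw maximum minus the mean for `j*`, the arm with
#' maximal full-sample mean net benefit.
#'
#' @inheritParams net_benefit
#' @param focal Character vector of focal parameter names (`"dM"` expands to
#'   all three treatment effects).
#' @param cond_nb Function `(samples, wtp, context) -> matrix` returning the
#'   draws-by-treatments conditional expectation table; the reference column
#'   must be identically zero.
#' @param method_label,settings Bookkeeping stored in the result.
#' @param nb_fn Optional net-benefit evaluator used to fix `j*`; defaults to
#'   the fluid model when `samples` carries its parameters, otherwise `j*`
#'   comes from the column means of `cond_nb`'s table (the same quantity by
#'   the law of total expectation).
#' @return A one-row estimate tibble.
#' @export
evppi_single_step <- function(samples, focal, cond_nb, wtp,
                              context = fluid_context(),
                              method_label = "custom", settings = list(),
                              nb_fn = NULL) {
  focal <- unique(unlist(lapply(focal, function(f) {
    if (identical(f, "dM")) unname(context$effects) else f
  })))
  if (!all(focal %in% colnames(samples))) {
    abort(paste0("unknown focal parameter(s): ",
                 paste(setdiff(focal, colnames(samples)), collapse = ", ")))
  }
  cm <- cond_nb(samples, wtp, context)
  if (!is.matrix(cm) || nrow(cm) != nrow(samples)) {
    abort("cond_nb must return one row of conditional net benefit per draw")
  }
  if (is.null(nb_fn) && all(fluid_params(context) %in% colnames(samples))) {
    nb_fn <- function(s) nb_matrix(s, wtp, context)
  }
  jstar <- which.max(colMeans(if (is.null(nb_fn)) cm else nb_fn(samples)))
  regret <- row_max(cm) - cm[, jstar]
  voi_estimate(method_label, focal, wtp,
               estimate = mean(regret),
               mc_se = sd(regret) / sqrt(nrow(cm)),
               n = nrow(cm), settings = settings)
}

#' Which single-step method applies to a focal set?
#'
#' Looks the focal set up in the registry of net-benefit structures
#' established for the case-study model: mean plug-in for sets leaving a
#' (multi)linear complement (`m1`, `m2`), reparameterized plug-in for
#' subsets of the economically linear parameters (`m3`), quantile-averaged
#' Taylor approximation for the independent nonlinear pairs (`m4`), and
#' spline-estimated conditional expectations for single parameters entering
#' nonlinearly, possibly correlated with the complement (`m5`).  Sets not in
#' the registry return `"nested"` (no single-step method established).
#'
#' @inheritParams evppi_single_step
#' @return One of `"m1"`, `"m2"`, `"m3"`, `"m4"`, `"m5"`, `"evpi"`,
#'   `"nested"`.
#' @examples
#' admissible_method("pL")
#' admissible_method(c("alpha", "pB"))
#' @export
admissible_method <- function(focal, context = fluid_context()) {
  focal <- expand_focal(focal, context)
  all9 <- fluid_params(context)
  dm <- unname(context$effects)
  econ <- c("qM", "qS", "pL")
  key <- function(x) paste(sort(x), collapse = "|")
  f <- key(focal)
  m1_sets <- lapply(list(c("qM", "qS"), c("qM", "pL"), "qM", "qS", "pL"),
                    function(cc) setdiff(all9, cc))
  m2_sets <- lapply(list(c("pL", "qS"), c("qM", "qS", "pL")),
                    function(cc) setdiff(all9, cc))
  if (f == key(all9)) return("evpi")
  if (all(focal %in% econ)) return("m3")
  if (f %in% vapply(m1_sets, key, character(1))) return("m1")
  if (f %in% vapply(m2_sets, key, character(1))) return("m2")
  if (f %in% c(key(c(dm, "dS")), key(c("alpha", "pB")))) return("m4")
  if (length(focal) == 1L && focal %in% c("alpha", "pB", "dS", dm)) {
    return("m5")
  }
  "nested"
}

#' Mean plug-in conditional net benefit (methods 1 and 2)
#'
#' For focal sets whose complement enters the net benefit (multi)linearly
#' and independently of its coefficients, the conditional expectation is
#' exactly the net benefit with each nonfocal parameter replaced by its
#' sample mean.  Admissibility is enforced against the registry; an
#' inadmissible set raises an error naming the offending parameters rather
#' than silently returning a biased estimate.
#'
#' @inheritParams evppi_single_step
#' @return A `cond_nb` function for [evppi_single_step()].
#' @export
cond_nb_plugin <- function(samples, focal, context = fluid_context()) {
  focal <- expand_focal(focal, context)
  meth <- admissible_method(focal, context)
  if (!meth %in% c("m1", "m2")) {
    bad <- setdiff(setdiff(fluid_params(context), focal),
                   c("qM", "qS", "pL"))
    abort(paste0(
      "mean plug-in is invalid for this focal set: nonfocal parameter(s) ",
      paste(bad, collapse = ", "),
      " enter the net benefit nonlinearly or correlated with the focal set"),
      class = "voitools_condition_violation")
  }
  nonfocal <- setdiff(fluid_params(context), focal)
  mu <- colMeans(samples[nonfocal])
  function(s, wtp, ctx) {
    s[nonfocal] <- as.list(mu)
    nb_matrix(s, wtp, ctx)
  }
}

#' Reparameterized plug-in conditional net benefit (method 3)
#'
#' For focal subsets of the economic parameters `{qM, qS, pL}` the net
#' benefit is linear in two derived quantities per arm: the mortality
#' reduction `beta1_j = expit(alpha) - expit(alpha + d_j)` and its product
#' with the saved-patient NS probability, `beta2_j`.  Their unconditional
#' sample means are precomputed over the full sample and plugged in, leaving
#' only focal parameters in the coefficients.
#'
#' @inheritParams evppi_single_step
#' @return A `cond_nb` function for [evppi_single_step()].
#' @export
cond_nb_reparam <- function(samples, focal, context = fluid_context()) {
  focal <- expand_focal(focal, context)
  if (!all(focal %in% c("qM", "qS", "pL")) || length(focal) == 0L) {
    abort("method 3 requires a non-empty focal subset of {qM, qS, pL}",
          class = "voitools_condition_violation")
  }
  st <- nb_streams(samples, context)
  e_b1 <- colMeans(st$u)
  e_b2 <- colMeans(st$v)
  mu <- colMeans(samples[setdiff(c("qM", "qS", "pL"), focal)])
  function(s, wtp, ctx) {
    qM <- if ("qM" %in% focal) s$qM else mu[["qM"]]
    qS <- if ("qS" %in% focal) s$qS else mu[["qS"]]
    pL <- if ("pL" %in% focal) s$pL else mu[["pL"]]
    f1 <- rep_len(wtp * qM - ctx$c_hosp, nrow(s))
    f2 <- rep_len(pL * (wtp * qS + ctx$c_ns), nrow(s))
    cm <- outer(f1, e_b1) - outer(f2, e_b2)
    cm <- sweep(cm, 2, ctx$c_fluid[colnames(st$u)], `-`)
    cbind(matrix(0, nrow(s), 1, dimnames = list(NULL, ctx$treatments[1])), cm)
  }
}

# Per-draw mortality-reduction streams, non-reference arms only:
#   u_j = expit(alpha) - expit(alpha + d_j)       ("beta1" stream)
#   v_j = u_j * prob_ns_saved(pB, dS)             ("beta2" stream)
nb_streams <- function(samples, context) {
  check_samples(samples, context)
  p0 <- plogis(samples$alpha)
  s <- prob_ns_saved(samples$pB, samples$dS)
  trt <- context$treatments[-1]
  u <- vapply(trt, function(t) {
    p0 - plogis(samples$alpha + samples[[context$effects[[t]]]])
  }, numeric(nrow(samples)))
  if (!is.matrix(u)) u <- matrix(u, 1, dimnames = list(NULL, trt))
  list(u = u, v = u * s, h2 = s)
}

#' Estimate EVPPI for a focal parameter set
#'
#' Front end dispatching to the single-step estimator registered for the
#' focal set ([admissible_method()]): mean plug-in (`m1`/`m2`),
#' reparameterized plug-in (`m3`), quantile-averaged Taylor approximation
#' (`m4`, see [evppi_taylor()]), or restricted-cubic-spline conditional
#' expectations (`m5`, see [evppi_spline()]).  `method = "nested"` runs the
#' two-level Monte Carlo baseline instead.
#'
#' @inheritParams evppi_single_step
#' @param method `"auto"` (default) picks from the registry; or one of
#'   `"m1"`, `"m2"`, `"m3"`, `"m4"`, `"m5"`, `"nested"`.
#' @param ... Tuning passed to the method: `order`, `n_segments` for `m4`;
#'   `m_bins`, `n_knots` for `m5`; `spec`, `n_outer`, `n_inner`,
#'   `conditional`, `seed` for `"nested"`.
#' @return A one-row estimate tibble.
#' @examples
#' draws <- sample_posterior(posterior_spec(), 2e4, seed = 7)
#' evppi(draws, "pL", wtp = 250)
#' @export
evppi <- function(samples, focal, wtp, context = fluid_context(),
                  method = "auto", ...) {
  focal <- expand_focal(focal, context)
  if (identical(method, "auto")) {
    method <- admissible_method(focal, context)
    if (method == "nested") {
      abort(paste0("no single-step method is registered for focal set {",
                   focal_label(focal),
                   "}; call evppi(..., method = \"nested\")"))
    }
  }
  switch(method,
    evpi = evpi(samples, wtp, context),
    m1 = ,
    m2 = evppi_single_step(samples, focal,
                           cond_nb_plugin(samples, focal, context),
                           wtp, context, method_label = method),
    m3 = evppi_single_step(samples, focal,
                           cond_nb_reparam(samples, focal, context),
                           wtp, context, method_label = "m3"),
    m4 = evppi_taylor(samples, focal, wtp, context, ...),
    m5 = evppi_spline(samples, focal, wtp, context, ...),
    nested = evppi_nested(samples, focal, wtp, context, ...),
    abort(paste0("unknown method: ", method))
  )
}

#' Nested (two-level) Monte Carlo EVPPI
#'
#' The baseline estimator: for each outer draw of the focal parameters, the
#' conditional mean net benefit is estimated from `n_inner` fresh draws of
#' the complement, sampled from its conditional law given the focal values
#' (via [conditional_sampler()]) or, when `conditional = FALSE`, from its
#' marginal.  Ignoring correlations biases the estimate downward (a warning
#' is issued); a finite inner sample biases it upward, on the order of the
#' inner-mean variance.
#'
#' @inheritParams evppi_single_step
#' @param spec The [posterior_spec()] behind `samples` (defaults to the
#'   `spec` attribute of `samples`).
#' @param n_outer Number of outer draws (taken from the head of `samples`).
#' @param n_inner Inner draws per outer draw.
#' @param conditional Sample the complement conditionally on the focal
#'   values?  Default `TRUE` when any focal/nonfocal correlation exists.
#' @param nb_fn Net-benefit evaluator `(samples) -> matrix`; defaults to the
#'   fluid model at `wtp`.  Supply for toy models.
#' @param seed Optional seed for the inner sampling.
#' @return A one-row estimate tibble (`mc_se` from the outer loop).
#' @export
evppi_nested <- function(samples, focal, wtp = NA_real_,
                         context = fluid_context(), spec = NULL,
                         n_outer = 1000L, n_inner = 1000L,
                         conditional = NULL, nb_fn = NULL, seed = NULL) {
  spec <- spec %||% attr(samples, "spec")
  if (is.null(spec)) abort("supply `spec` (or samples carrying one)")
  nm <- names(spec$marginals)
  focal <- unique(unlist(lapply(focal, function(f) {
    if (identical(f, "dM")) unname(context$effects) else f
  })))
  if (!all(focal %in% nm)) {
    abort(paste0("unknown focal parameter(s): ",
                 paste(setdiff(focal, nm), collapse = ", ")))
  }
  comp <- setdiff(nm, focal)
  if (!length(comp)) abort("focal set must leave a non-empty complement")
  nb_fn <- nb_fn %||% (function(s) nb_matrix(s, wtp, context))
  cross <- spec$correlation[focal, comp, drop = FALSE]
  if (is.null(conditional)) conditional <- any(cross != 0)
  if (!conditional && any(cross != 0)) {
    warn(paste0("focal and nonfocal parameters are correlated but ",
                "conditional = FALSE: expect downward bias"))
  }
  n_outer <- min(n_outer, nrow(samples))
  outer_df <- samples[seq_len(n_outer), focal, drop = FALSE]
  csamp <- if (conditional) conditional_sampler(spec, focal) else NULL

  run <- function() {
    jstar <- which.max(colMeans(nb_fn(samples)))
    inner_means <- NULL
    for (i in seq_len(n_outer)) {
      inner <- if (conditional) {
        csamp(as.list(outer_df[i, ]), n_inner)
      } else {
        idx <- sample.int(nrow(samples), n_inner, replace = TRUE)
        samples[idx, comp, drop = FALSE]
      }
      inner[focal] <- as.list(outer_df[i, ])
      m <- colMeans(nb_fn(tibble::as_tibble(inner)))
      if (is.null(inner_means)) {
        inner_means <- matrix(NA_real_, n_outer, length(m))
      }
      inner_means[i, ] <- m
    }
    regret <- row_max(inner_means) - inner_means[, jstar]
    voi_estimate("nested", focal, wtp,
                 estimate = mean(regret),
                 mc_se = sd(regret) / sqrt(n_outer),
                 n = n_outer,
                 settings = list(n_inner = n_inner,
                                 conditional = conditional))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
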