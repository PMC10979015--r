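#' Reduced chi-square of a model prediction against paired count curves
#'
#' Sum over both compartments of the squared weighted residuals
#' `((obs - pred) / sigma)^2`, divided by the number of degrees of freedom
#' `N - p` where `N` counts the data points of both curves together and `p`
#' the free parameters. A value near 1 indicates residuals consistent with
#' the stated measurement dispersion.
#'
#' @param obs_ct,obs_pb Observed counts per curve.
#' @param pred Either a `trajectory` from [solve_trajectory()] or a list with
#'   numeric elements `rna_ct` and `rna_pb`.
#' @param sigma_ct,sigma_pb Per-point dispersions (must be > 0).
#' @param n_free_params Number of fitted parameters `p`.
#' @return The reduced chi-square (dimensionless scalar).
#' @export
reduced_chi_square <- function(obs_ct, obs_pb, pred, sigma_ct, sigma_pb,
                               n_free_params) {
  pred_ct <- pred$rna_ct
  pred_pb <- pred$rna_pb
  n <- length(obs_ct)
  if (length(obs_pb) != n || length(pred_ct) != n || length(pred_pb) != n ||
      length(sigma_ct) != n || length(sigma_pb) != n) {
    stop("observed, predicted and sigma vectors must all have equal length",
         call. = FALSE)
  }
  N <- 2L * n
  if (N <= n_free_params) {
    stop("need more data points than free parameters (N = ", N,
         ", p = ", n_free_params, ")", call. = FALSE)
  }
  if (any(c(sigma_ct, sigma_pb) <= 0)) {
    stop("all sigma entries must be strictly positive", call. = FALSE)
  }
  r <- c((obs_ct - pred_ct) / sigma_ct, (obs_pb - pred_pb) / sigma_pb)
  sum(r^2) / (N - n_free_params)
}

#' Fitting options for [fit_variant()]
#'
#' @param n_starts Number of multi-start initializations for the bounded
#'   Levenberg-Marquardt optimizer. The first start is a data-driven guess;
#'   the remainder draw rates log-uniformly from `start_range`.
#' @param seed Integer seed making the multi-start draw (and hence the whole
#'   fit) deterministic.
#' @param fit_n0 `"free"` (default) fits the initial cytoplasmic count as an
#'   extra amplitude parameter with the P-body count fixed at 0; `"fixed"`
#'   pins it to the t = 0 cytoplasmic measurement.
#' @param sigma_floor_frac Per-curve dispersion floor as a fraction of that
#'   curve's maximum mean; prevents near-zero late-timepoint error bars from
#'   dominating the weighted fit.
#' @param sigma_floor_abs Absolute dispersion floor (counts), applied after
#'   the fractional floor.
#' @param start_range Two-element range (per hour) for the log-uniform
#'   multi-start rate draws.
#' @param max_iter Maximum optimizer iterations per start.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 16L, seed = 1L,
                        fit_n0 = c("free", "fixed"),
                        sigma_floor_frac = 0.05, sigma_floor_abs = 0,
                        start_range = c(1e-3, 10), max_iter = 200L) {
  fit_n0 <- match.arg(fit_n0)
  stopifnot(n_starts >= 1L, sigma_floor_frac >= 0, sigma_floor_abs >= 0,
            length(start_range) == 2L, all(start_range > 0))
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 fit_n0 = fit_n0, sigma_floor_frac = sigma_floor_frac,
                 sigma_floor_abs = sigma_floor_abs,
                 start_range = as.numeric(start_range),
                 max_iter = as.integer(max_iter)),
            class = "fit_options")
}

# Free rate-parameter names per variant; constrained rates are reinstated by
# apply_variant() on the assembled rate_params.
variant_free_rates <- function(variant) {
  switch(variant,
    full        = c("k_ct", "k_pb", "k_r", "k_l"),
    no_pb_decay = c("k_ct", "k_r", "k_l"),
    equal_decay = c("k_ct", "k_r", "k_l"),
    no_leave    = c("k_ct", "k_pb", "k_r")
  )
}

# Assemble a rate_params from the optimizer's free-parameter vector.
params_from_theta <- function(theta, variant, n0_fixed) {
  free <- variant_free_rates(variant)
  rates <- c(k_ct = 0, k_pb = 0, k_r = 0, k_l = 0)
  rates[free] <- theta[seq_along(free)]
  n0 <- if (is.null(n0_fixed)) theta[length(free) + 1L] else n0_fixed
  apply_variant(rate_params(rates[["k_ct"]], rates[["k_pb"]], rates[["k_r"]],
                            rates[["k_l"]], n0_ct = n0, n0_pb = 0),
                variant)
}

# Per-curve effective sigma after flooring.
effective_sigma <- function(tc, options) {
  floor_ct <- max(options$sigma_floor_frac * max(tc$mean_ct),
                  options$sigma_floor_abs)
  floor_pb <- max(options$sigma_floor_frac * max(tc$mean_pb),
                  options$sigma_floor_abs)
  list(ct = pmax(tc$sd_ct, floor_ct), pb = pmax(tc$sd_pb, floor_pb))
}

#' Fit one model variant to a time course
#'
#' Minimizes the weighted sum of squared residuals of the cytoplasmic and
#' P-body curves jointly, with all rates bounded below by zero, using
#' bounded Levenberg-Marquardt least squares with seeded multi-start
#' initialization. The dispersion used for weighting is the stated `sd` of
#' replicate means, floored per [fit_options()].
#'
#' @param data A [time_course()].
#' @param variant One of [model_variants()].
#' @param options A [fit_options()] list.
#' @return An object of class `fit_result` with elements `variant`, `params`
#'   (fitted [rate_params()]), `reduced_chi2`, `chi2` (unreduced),
#'   `residuals_ct`/`residuals_pb` (weighted), `n_free_params`, `converged`,
#'   `n_starts`, `seed`, and the floored `sigma` used.
#' @export
fit_variant <- function(data, variant, options = fit_options()) {
  stopifnot(inherits(data, "time_course"), inherits(options, "fit_options"))
  variant <- match_variant(variant)
  if (all(data$mean_ct == 0) && all(data$mean_pb == 0)) {
    stop("all-zero time course: nothing to fit", call. = FALSE)
  }
  sig <- effective_sigma(data, options)
  if (any(c(sig$ct, sig$pb) <= 0)) {
    stop("nonpositive sigma after flooring; set sigma_floor_abs > 0",
         call. = FALSE)
  }

  free <- variant_free_rates(variant)
  n0_fixed <- if (options$fit_n0 == "fixed") data$mean_ct[1L] else NULL
  k_free <- length(free) + if (is.null(n0_fixed)) 1L else 0L
  n_pts <- 2L * nrow(data)
  if (n_pts <= k_free) {
    stop("not enough data points (", n_pts, ") for ", k_free,
         " free parameters", call. = FALSE)
  }

  resid_fn <- function(theta) {
    p <- params_from_theta(theta, variant, n0_fixed)
    tr <- solve_trajectory(p, data$time_h)
    c((data$mean_ct - tr$rna_ct) / sig$ct,
      (data$mean_pb - tr$rna_pb) / sig$pb)
  }

  n0_guess <- max(data$mean_ct[1L], max(data$mean_pb), 1)
  starts <- with_seed(options$seed, {
    s <- vector("list", options$n_starts)
    s[[1L]] <- c(rep(0.5, length(free)),
                 if (is.null(n0_fixed)) n0_guess)
    lr <- log(options$start_range)
    for (i in seq_len(options$n_starts)[-1L]) {
      s[[i]] <- c(exp(stats::runif(length(free), lr[1L], lr[2L])),
                  if (is.null(n0_fixed)) n0_guess * exp(stats::rnorm(1, 0, 0.3)))
    }
    s
  })

  lower <- rep(0, k_free)
  best <- NULL
  any_converged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = st, lower = lower, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = options$max_iter))),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    any_converged <- any_converged || ok
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("all optimizer starts failed for variant ", variant, call. = FALSE)
  }

  params <- params_from_theta(best$par, variant, n0_fixed)
  tr <- solve_trajectory(params, data$time_h)
  r_ct <- (data$mean_ct - tr$rna_ct) / sig$ct
  r_pb <- (data$mean_pb - tr$rna_pb) / sig$pb
  chi2 <- sum(r_ct^2) + sum(r_pb^2)
  structure(list(
    variant = variant,
    params = params,
    reduced_chi2 = chi2 / (n_pts - k_free),
    chi2 = chi2,
    residuals_ct = r_ct,
    residuals_pb = r_pb,
    n_free_params = k_free,
    n_data = n_pts,
    converged = any_converged,
    n_starts = options$n_starts,
    seed = options$seed,
    sigma = sig,
    data = data
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit of variant '%s' (%d free parameters, %d data points)\n",
              x$variant, x$n_free_params, x$n_data))
  cat(sprintf("  reduced chi-square: %.4g  converged: %s\n",
              x$reduced_chi2, x$converged))
  print(x$params)
  invisible(x)
}

#' Fit and rank all requested model variants
#'
#' Fits every variant to the same data and ranks by reduced chi-square
#' (ascending); exact ties are broken in favour of fewer free parameters.
#' A variant is flagged `sufficient` when its reduced chi-square is within
#' `sufficiency_factor` of the best variant with more free parameters — the
#' parsimony criterion used to prefer a simpler nested model that fits the
#' data essentially as well.
#'
#' @param data A [time_course()].
#' @param variants Character vector of variants (>= 2).
#' @param options A [fit_options()].
#' @param sufficiency_factor Multiplicative slack for calling a simpler
#'   model sufficient (default 1.2).
#' @return A data frame (one row per variant, ranked) with the fitted rates,
#'   `reduced_chi2`, `n_free_params`, `converged` and `sufficient`; the full
#'   `fit_result` objects are attached as attribute `"fits"`.
#' @export
compare_models <- function(data, variants = model_variants(),
                           options = fit_options(),
                           sufficiency_factor = 1.2) {
  if (length(variants) < 2L) {
    stop("need at least 2 variants to compare", call. = FALSE)
  }
  fits <- lapply(variants, function(v) fit_variant(data, v, options))
  names(fits) <- variants
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(variant = f$variant,
               k_ct = f$params$k_ct, k_pb = f$params$k_pb,
               k_r = f$params$k_r, k_l = f$params$k_l,
               n0_ct = f$params$n0_ct,
               reduced_chi2 = f$reduced_chi2,
               n_free_params = f$n_free_params,
               converged = f$converged)
  }))
  tab$sufficient <- vapply(seq_len(nrow(tab)), function(i) {
    bigger <- tab$n_free_params > tab$n_free_params[i]
    if (!any(bigger)) return(NA)
    tab$reduced_chi2[i] <= sufficiency_factor * min(tab$reduced_chi2[bigger])
  }, logical(1))
  ord <- order(tab$reduced_chi2, tab$n_free_params)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Parameter uncertainty from replicate-level data
#'
#' Two reporting modes. `"bootstrap"` resamples the biological replicates
#' with replacement `n_boot` times, re-aggregates and refits, and returns
#' percentile intervals of the fitted parameters. `"replicate_fits"` fits
#' each replicate separately and reports the mean and standard deviation of
#' the fitted parameters across replicates (the conventional per-replicate
#' reporting for 3-4 biological replicates).
#'
#' @param replicates List of >= 2 per-replicate [time_course()]s on a common
#'   time grid.
#' @param variant One of [model_variants()].
#' @param n_boot Number of bootstrap resamples (>= 1; ignored for
#'   `"replicate_fits"`).
#' @param seed Integer seed for the resampling.
#' @param options A [fit_options()].
#' @param mode `"bootstrap"` or `"replicate_fits"`.
#' @param probs Lower/upper percentile for the bootstrap intervals.
#' @return A data frame with one row per parameter: `estimate` (fit to the
#'   aggregated data, or replicate mean), `lower`, `upper` (percentiles, or
#'   mean -/+ sd); the per-resample estimates are attached as attribute
#'   `"samples"`.
#' @export
bootstrap_uncertainty <- function(replicates, variant, n_boot = 200L,
                                  seed = 1L, options = fit_options(),
                                  mode = c("bootstrap", "replicate_fits"),
                                  probs = c(0.025, 0.975)) {
  mode <- match.arg(mode)
  if (length(replicates) < 2L) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  par_names <- c("k_ct", "k_pb", "k_r", "k_l", "n0_ct")
  extract <- function(fit) unlist(fit$params[par_names])

  if (mode == "replicate_fits") {
    est <- vapply(replicates, function(r) {
      extract(fit_variant(r, variant, options))
    }, numeric(length(par_names)))
    m <- rowMeans(est)
    s <- apply(est, 1L, stats::sd)
    out <- data.frame(param = par_names, estimate = m,
                      lower = m - s, upper = m + s, sd = s)
    attr(out, "samples") <- t(est)
    rownames(out) <- NULL
    return(out)
  }

  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  k <- length(replicates)
  pooled_fit <- fit_variant(aggregate_replicates(replicates), variant, options)
  idx <- with_seed(seed, {
    matrix(sample.int(k, k * n_boot, replace = TRUE), nrow = n_boot)
  })
  est <- t(vapply(seq_len(n_boot), function(b) {
    agg <- aggregate_replicates(replicates[idx[b, ]])
    extract(fit_variant(agg, variant, options))
  }, numeric(length(par_names))))
  colnames(est) <- par_names
  out <- data.frame(param = par_names,
                    estimate = extract(pooled_fit),
                    lower = apply(est, 2L, stats::quantile, probs[1L], names = FALSE),
                    upper = apply(est, 2L, stats::quantile, probs[2L], names = FALSE))
  attr(out, "samples") <- est
  rownames(out) <- NULL
  out
}
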