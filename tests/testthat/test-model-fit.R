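test_that("reduced chi-square matches hand computation", {
  tr <- list(rna_ct = c(98, 82, 59, 41), rna_pb = c(12, 24, 20, 8))
  obs_ct <- c(100, 80, 60, 40)
  obs_pb <- c(10, 25, 18, 9)
  sig_ct <- c(5, 4, 3, 2)
  sig_pb <- c(2, 3, 3, 2)

  # zero residuals
  expect_equal(reduced_chi_square(tr$rna_ct, tr$rna_pb, tr, sig_ct, sig_pb, 3),
               0)
  # unit weighted residuals: chi2 = N, reduced = N / (N - p)
  shift <- list(rna_ct = tr$rna_ct - sig_ct, rna_pb = tr$rna_pb - sig_pb)
  expect_equal(reduced_chi_square(tr$rna_ct, tr$rna_pb, shift,
                                  sig_ct, sig_pb, 3), 8 / 5)
  # 4-timepoint toy, spreadsheet-style manual sum:
  # CT: (2/5)^2+(2/4)^2+(1/3)^2+(1/2)^2 = 0.7711...
  # PB: 1^2+(1/3)^2+(2/3)^2+(1/2)^2    = 1.80555...
  # (0.771111 + 1.805556) / (8 - 3)     = 0.5153333
  expect_equal(reduced_chi_square(obs_ct, obs_pb, tr, sig_ct, sig_pb, 3),
               0.51533333333, tolerance = 1e-9)

  expect_error(reduced_chi_square(obs_ct, obs_pb, tr, sig_ct, sig_pb, 8),
               "more data points")
  expect_error(reduced_chi_square(obs_ct, obs_pb, tr, c(0, 4, 3, 2), sig_pb, 3),
               "positive")
})

noiseless_tc <- function(params, variant,
                         times = c(0, 0.25, 0.5, 1, 2, 4, 6, 9)) {
  tr <- solve_trajectory(apply_variant(params, variant), times)
  time_course(times, tr$rna_ct, tr$rna_pb,
              rep(1, length(times)), rep(1, length(times)),
              n_replicates = 3L)
}

test_that("every variant recovers its generating parameters from noiseless data", {
  gens <- list(
    full = rate_params(0.3, 2.5, 0.8, 0.4, 1200),
    no_pb_decay = rate_params(0.5, 0, 1.2, 0.6, 900),
    equal_decay = rate_params(0.6, 0.6, 0.9, 0.3, 1100),
    no_leave = rate_params(0.2, 3.0, 1.0, 0, 1000)
  )
  opts <- fit_options(n_starts = 8L, seed = 3L)
  for (v in names(gens)) {
    fit <- fit_variant(noiseless_tc(gens[[v]], v), v, opts)
    truth <- unlist(apply_variant(gens[[v]], v))
    est <- unlist(fit$params)
    nz <- truth > 0
    expect_lt(max(abs(est[nz] - truth[nz]) / truth[nz]), 1e-4)
    expect_lt(fit$reduced_chi2, 1e-8)
    expect_true(fit$converged)
  }
})

test_that("stationary data drives all decay and flux rates to zero", {
  tt <- c(0, 1, 2, 4, 6, 9)
  tc <- time_course(tt, rep(500, 6), rep(0, 6), rep(5, 6), rep(5, 6), 3L)
  for (v in c("full", "no_leave")) {
    fit <- fit_variant(tc, v, fit_options(n_starts = 8L, seed = 2L))
    expect_lt(fit$params$k_ct, 1e-4)
    expect_lt(fit$params$k_r, 1e-4)
  }
})

test_that("fits are deterministic given seed and reject degenerate input", {
  sim <- simulate_counts(default_params(), "no_leave",
                         experiment_design(seed = 11L))
  opts <- fit_options(n_starts = 6L, seed = 9L)
  f1 <- fit_variant(sim$pooled, "no_leave", opts)
  f2 <- fit_variant(sim$pooled, "no_leave", opts)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$reduced_chi2, f2$reduced_chi2)

  tt <- c(0, 1, 2, 4)
  zero <- time_course(tt, rep(0, 4), rep(0, 4), rep(1, 4), rep(1, 4), 3L)
  expect_error(fit_variant(zero, "full"), "all-zero")
})

test_that("model comparison ranks the generating variant and honours nesting", {
  opts <- fit_options(n_starts = 8L, seed = 4L)

  # data generated under no_pb_decay: that variant (or the full model)
  # must rank at least as well as equal_decay
  tc <- noiseless_tc(rate_params(0.5, 0, 1.2, 0.6, 900), "no_pb_decay")
  cmp <- compare_models(tc, c("no_pb_decay", "equal_decay", "full"), opts)
  expect_lt(which(cmp$variant == "no_pb_decay"),
            which(cmp$variant == "equal_decay"))

  # full data with k_l = 0: no_leave and full agree within 5%
  tc <- noiseless_tc(rate_params(0.25, 2.8, 1.1, 0, 1300), "full")
  cmp <- compare_models(tc, c("no_leave", "full"), opts)
  rc <- cmp$reduced_chi2 + 1e-12
  expect_lt(abs(diff(rc)) / max(rc), 0.05)

  # the full model's minimized unreduced chi2 never exceeds a nested
  # variant's on the same (noisy) data
  sim <- simulate_counts(default_params(), "no_leave",
                         experiment_design(seed = 21L))
  fits <- attr(compare_models(sim$pooled, model_variants(), opts), "fits")
  for (v in c("no_pb_decay", "equal_decay", "no_leave")) {
    expect_lte(fits$full$chi2, fits[[v]]$chi2 * (1 + 1e-6))
  }
  expect_error(compare_models(sim$pooled, "full"), "at least 2")
})

test_that("replicate uncertainty modes behave at their degenerate limits", {
  sim <- simulate_counts(default_params(), "no_leave",
                         experiment_design(seed = 31L, n_replicates = 4L))
  opts <- fit_options(n_starts = 4L, seed = 5L)

  # identical replicates: zero-width bootstrap intervals
  reps_same <- rep(sim$replicates[1], 4)
  ci <- bootstrap_uncertainty(reps_same, "no_leave", n_boot = 5L,
                              seed = 7L, options = opts)
  expect_equal(ci$lower, ci$upper, tolerance = 1e-10)

  # n_boot = 1: interval collapses onto the single refit value
  ci1 <- bootstrap_uncertainty(sim$replicates, "no_leave", n_boot = 1L,
                               seed = 7L, options = opts)
  expect_equal(ci1$lower, ci1$upper)

  # replicate-fits mode: mean +/- sd brackets the generating rates loosely
  rf <- bootstrap_uncertainty(sim$replicates, "no_leave", seed = 7L,
                              options = opts, mode = "replicate_fits")
  expect_named(rf, c("param", "estimate", "lower", "upper", "sd"))
  est <- rf$estimate[rf$param == "k_pb"]
  expect_gt(est, 0)
  expect_error(bootstrap_uncertainty(sim$replicates[1], "no_leave"),
               "at least 2")
  expect_error(bootstrap_uncertainty(sim$replicates, "no_leave", n_boot = 0L,
                                     seed = 1L, options = opts), "n_boot")
})
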