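test_that("variant constraints are applied and counted correctly", {
  p <- rate_params(k_ct = 0.5, k_pb = 2, k_r = 1, k_l = 0.3, n0_ct = 100)

  expect_identical(apply_variant(p, "full"), p)
  expect_equal(apply_variant(p, "no_leave")$k_l, 0)
  expect_equal(apply_variant(p, "no_pb_decay")$k_pb, 0)
  expect_equal(apply_variant(p, "equal_decay")$k_pb, 0.5)
  # untouched fields survive
  expect_equal(apply_variant(p, "no_leave")$k_pb, 2)

  expect_equal(n_free_rates("full"), 4L)
  for (v in c("no_pb_decay", "equal_decay", "no_leave")) {
    expect_equal(n_free_rates(v), 3L)
  }
  expect_error(apply_variant(p, "bogus"), "unknown model variant")
  expect_error(rate_params(-0.1, 1, 1, 1, 10), "nonnegative")
})

test_that("trajectory reduces to known closed forms", {
  # no flux, no decay: counts constant
  p0 <- rate_params(0, 0, 0, 0, n0_ct = 100, n0_pb = 5)
  tr <- solve_trajectory(p0, c(0, 1, 4.5, 9))
  expect_equal(tr$rna_ct, rep(100, 4))
  expect_equal(tr$rna_pb, rep(5, 4))

  # pure cytoplasmic decay at ln(2)/h: halves every hour, P-bodies empty
  p1 <- rate_params(log(2), 0, 0, 0, n0_ct = 100)
  tr <- solve_trajectory(p1, c(0, 1, 2, 3))
  expect_equal(tr$rna_ct, 100 * 2^-(0:3), tolerance = 1e-12)
  expect_equal(tr$rna_pb, rep(0, 4))

  # initial condition is honoured at t = 0
  p2 <- rate_params(0.3, 2, 1.5, 0.2, n0_ct = 800, n0_pb = 40)
  tr <- solve_trajectory(p2, 0)
  expect_equal(c(tr$rna_ct, tr$rna_pb), c(800, 40))

  expect_error(solve_trajectory(p1, c(-1, 0)), "nonnegative")
  expect_error(solve_trajectory(p1, c(2, 1)), "ascending")
})

test_that("closed-form solution matches the fixed-step RK4 oracle", {
  p <- rate_params(0.2, 3.0, 1.0, 0, n0_ct = 1000)
  times <- c(0, 0.5, 1, 2)
  oracle <- rk4_desolve(0.2, 3.0, 1.0, 0, c(1000, 0), times, h = 1e-4)
  tr <- solve_trajectory(p, times)
  expect_equal(tr$rna_ct, oracle$rna_ct, tolerance = 1e-8)
  expect_equal(tr$rna_pb, oracle$rna_pb, tolerance = 1e-8)

  # random nonnegative parameter sets against the fast step-matrix RK4
  set.seed(101)
  for (i in 1:40) {
    k <- stats::runif(4, 0, 4)
    n0 <- stats::runif(2, 0, 2000)
    times <- seq(0, 9, by = 0.5)
    tr <- solve_trajectory(rate_params(k[1], k[2], k[3], k[4],
                                       n0[1], n0[2]), times)
    orc <- rk4_linear(k[1], k[2], k[3], k[4], n0, times, h = 5e-4)
    scale <- max(n0, 1)
    expect_lt(max(abs(tr$rna_ct - orc$rna_ct) / scale), 1e-8)
    expect_lt(max(abs(tr$rna_pb - orc$rna_pb) / scale), 1e-8)
  }
})

test_that("degenerate (repeated-eigenvalue) parameter sets are handled", {
  # k_r = k_l = 0 with equal decay rates makes M a scalar multiple of I
  p <- rate_params(0.7, 0.7, 0, 0, n0_ct = 500, n0_pb = 100)
  tr <- solve_trajectory(p, c(0, 1, 2))
  expect_equal(tr$rna_ct, 500 * exp(-0.7 * (0:2)), tolerance = 1e-12)
  expect_equal(tr$rna_pb, 100 * exp(-0.7 * (0:2)), tolerance = 1e-12)

  # near-degenerate continuity: perturbing a rate by 1e-9 barely moves the
  # solution
  pa <- rate_params(1, 1, 0, 0, n0_ct = 100, n0_pb = 50)
  pb <- rate_params(1 + 1e-9, 1, 0, 0, n0_ct = 100, n0_pb = 50)
  ta <- solve_trajectory(pa, c(0.5, 3))
  tb <- solve_trajectory(pb, c(0.5, 3))
  expect_equal(ta$rna_ct, tb$rna_ct, tolerance = 1e-6)
})

test_that("model invariants hold across random parameter draws", {
  set.seed(77)
  for (i in 1:25) {
    k <- stats::runif(4, 0, 3)
    n0 <- stats::runif(2, 10, 1000)
    times <- seq(0, 9, length.out = 30)

    # conservation without decay
    cons <- solve_trajectory(rate_params(0, 0, k[3], k[4], n0[1], n0[2]),
                             times)
    expect_equal(cons$rna_ct + cons$rna_pb, rep(sum(n0), 30),
                 tolerance = 1e-10)

    # total RNA is non-increasing when decay is present
    tr <- solve_trajectory(rate_params(k[1] + 0.05, k[2], k[3], k[4],
                                       n0[1], n0[2]), times)
    expect_true(all(diff(tr$rna_ct + tr$rna_pb) <= 1e-9))
    expect_true(all(tr$rna_ct >= 0 & tr$rna_pb >= 0))

    # nesting: applying a variant equals manual constraint
    p <- rate_params(k[1], k[2], k[3], k[4], n0[1])
    for (v in model_variants()) {
      manual <- p
      if (v == "no_pb_decay") manual$k_pb <- 0
      if (v == "equal_decay") manual$k_pb <- manual$k_ct
      if (v == "no_leave") manual$k_l <- 0
      expect_equal(solve_trajectory(apply_variant(p, v), times),
                   solve_trajectory(manual, times))
    }
  }

  # limit agreement: k_r -> 0 with empty P-bodies approaches the pure
  # exponential
  times <- seq(0, 6, by = 0.5)
  for (k_r in c(1e-4, 1e-6, 1e-8)) {
    tr <- solve_trajectory(rate_params(0.4, 2, k_r, 0.3, 100, 0), times)
    expect_equal(tr$rna_ct, 100 * exp(-0.4 * times), tolerance = 50 * k_r)
  }
})

test_that("half-life follows the first-order definition", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(2 * log(2)), 0.5)
  expect_equal(half_life(1.386), log(2) / 1.386)
  expect_error(half_life(0), "positive")
  expect_error(half_life(-1), "positive")
})

test_that("trajectories export to CSV and read back", {
  p <- rate_params(0.2, 3, 1, 0, 1500)
  tr <- solve_trajectory(p, c(0, 1, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_named(back, c("time_h", "rna_ct", "rna_pb"))
  expect_equal(back$rna_ct, tr$rna_ct)
})
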