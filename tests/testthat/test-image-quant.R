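# 2D blob image helper: Gaussian blobs of peak `amp` and width `sigma`.
blob_image <- function(dim_yx, centers, amp = 200, sigma = 2.5, bg = 10) {
  img <- matrix(bg, dim_yx[1], dim_yx[2])
  for (i in seq_len(nrow(centers))) {
    img <- img + amp * outer(
      exp(-(seq_len(dim_yx[1]) - centers[i, 1])^2 / (2 * sigma^2)),
      exp(-(seq_len(dim_yx[2]) - centers[i, 2])^2 / (2 * sigma^2)))
  }
  img
}

test_that("P-body segmentation finds planted blobs and nothing in blanks", {
  expect_equal(max(segment_pbodies(matrix(7, 64, 64))), 0L)

  centers <- rbind(c(20, 20), c(44, 40))
  img <- blob_image(c(64, 64), centers)
  lab <- segment_pbodies(img)
  expect_equal(max(lab), 2L)
  for (i in 1:2) {
    idx <- which(lab > 0, arr.ind = TRUE)
    reg <- idx[lab[idx] == lab[centers[i, 1], centers[i, 2]], , drop = FALSE]
    expect_lt(max(abs(colMeans(reg) - centers[i, ])), 1)
  }

  # blobs closer than a blob width merge into one region
  merged <- segment_pbodies(blob_image(c(64, 64), rbind(c(30, 30), c(30, 33))))
  expect_equal(max(merged), 1L)

  # otsu policy is an accepted alternative
  lab2 <- segment_pbodies(img, threshold_policy = list(method = "otsu"))
  expect_gte(max(lab2), 2L)
})

test_that("spot detection is precise on planted fields and safe at borders", {
  blank <- array(10, dim = c(8L, 48L, 48L))
  expect_equal(nrow(detect_spots(blank)), 0L)

  st <- render_stack(test_scene(seed = 12L, n_granules = 0L))
  cand <- detect_spots(st$rna)
  m <- match_spots(st$truth$spots, cand)
  expect_gte(m$recall, 0.98)
  expect_gte(m$precision, 0.98)

  # a spot at the extreme corner must not crash detection or fitting
  corner <- array(0, dim = c(8L, 32L, 32L))
  corner <- add_gaussian3(corner, 1.2, 1.5, 1.5, 100, 1.3, 2.5)
  cand <- detect_spots(corner, intensity_threshold = 1)
  expect_true(nrow(cand) >= 0)
  if (nrow(cand) > 0) {
    fit <- fit_spot_3d(corner, cand[1, ])
    expect_false(is.na(fit$accepted))
    expect_identical(fit$reason, "border")
  }
})

test_that("3D Gaussian fitting recovers spot parameters", {
  mk_spot <- function(noise = FALSE, seed = 1) {
    arr <- array(10, dim = c(11L, 15L, 15L))
    arr <- add_gaussian3(arr, 6.3, 8.2, 7.6, 100, 1.3, 2.5)
    if (noise) {
      set.seed(seed)
      arr <- array(stats::rpois(length(arr), arr), dim = dim(arr))
    }
    arr
  }
  # noiseless: all parameters to <= 1% relative
  fit <- fit_spot_3d(mk_spot(), list(z = 6L, y = 8L, x = 8L))
  expect_true(fit$accepted)
  expect_lt(abs(fit$amplitude - 100) / 100, 0.01)
  expect_lt(abs(fit$background - 10) / 10, 0.01)
  expect_lt(abs(fit$sigma_xy - 1.3) / 1.3, 0.01)
  expect_lt(abs(fit$sigma_z - 2.5) / 2.5, 0.01)
  expect_lt(max(abs(c(fit$z, fit$y, fit$x) - c(6.3, 8.2, 7.6))), 0.02)

  # Poisson noise: median lateral center error stays below 0.2 px
  errs <- vapply(1:100, function(s) {
    f <- fit_spot_3d(mk_spot(noise = TRUE, seed = s),
                     list(z = 6L, y = 8L, x = 8L))
    if (!f$accepted) return(NA_real_)
    sqrt((f$y - 8.2)^2 + (f$x - 7.6)^2)
  }, numeric(1))
  expect_lt(stats::median(errs, na.rm = TRUE), 0.2)
  expect_gt(mean(!is.na(errs)), 0.95)

  # flat background: no spot to accept
  flat <- array(10, dim = c(11L, 15L, 15L))
  fit <- fit_spot_3d(flat, list(z = 6L, y = 8L, x = 8L))
  expect_false(fit$accepted)
})

test_that("unit intensity is the median of eligible single spots", {
  spots <- data.frame(y = c(10, 20, 30), x = c(10, 20, 30),
                      max_proj_intensity = c(90, 100, 160),
                      accepted = TRUE, in_pbody = FALSE)
  expect_equal(unit_intensity(spots), 100)
  spots$in_pbody <- TRUE
  expect_error(unit_intensity(spots), "outside P-bodies")

  # on rendered data the measured unit tracks the analytic per-molecule
  # max-projection mass within 5%
  st <- render_stack(test_scene(seed = 23L, n_spots = 60L, n_granules = 0L))
  sp <- fit_spots(st$rna)
  expect_equal(unit_intensity(sp), st$truth$unit_intensity, tolerance = 0.05)
})

test_that("granule quantification is calibrated and linear", {
  # granule assembled from exactly 20 unit PSFs inside a P-body
  sc <- scene_config(dim = c(12L, 72L, 72L), n_spots = 20L, n_granules = 1L,
                     granule_molecules = c(20L, 20L), margin_xy = 8L,
                     seed = 31L)
  st <- render_stack(sc)
  mask <- segment_pbodies(st$pbody)
  expect_equal(max(mask), 1L)
  g <- quantify_granules(max_project(st$rna), mask, st$truth$unit_intensity)
  expect_equal(g$rna_equiv, 20, tolerance = 0.10)

  # doubling the unit halves every estimate exactly
  g2 <- quantify_granules(max_project(st$rna), mask,
                          2 * st$truth$unit_intensity)
  expect_equal(g2$rna_equiv, g$rna_equiv / 2)

  # a P-body over pure background holds ~zero RNA equivalents
  sc0 <- scene_config(dim = c(12L, 72L, 72L), n_spots = 0L, n_granules = 0L,
                      margin_xy = 8L, seed = 32L)
  st0 <- render_stack(sc0)
  fake_mask <- matrix(0L, 72, 72)
  fake_mask[30:34, 30:34] <- 1L
  g0 <- quantify_granules(max_project(st0$rna), fake_mask,
                          st0$truth$unit_intensity)
  expect_lt(abs(g0$rna_equiv), 0.5)

  # doubling molecule content doubles the summed RNA equivalents (5%)
  sc_a <- scene_config(dim = c(12L, 96L, 96L), n_spots = 0L, n_granules = 3L,
                       granule_molecules = c(10L, 10L), margin_xy = 10L,
                       seed = 33L)
  sc_b <- scene_config(dim = c(12L, 96L, 96L), n_spots = 0L, n_granules = 3L,
                       granule_molecules = c(20L, 20L), margin_xy = 10L,
                       seed = 33L)
  qa <- render_stack(sc_a)
  qb <- render_stack(sc_b)
  ga <- quantify_granules(max_project(qa$rna), segment_pbodies(qa$pbody),
                          qa$truth$unit_intensity)
  gb <- quantify_granules(max_project(qb$rna), segment_pbodies(qb$pbody),
                          qb$truth$unit_intensity)
  expect_equal(sum(gb$rna_equiv) / sum(ga$rna_equiv), 2, tolerance = 0.05)
})

test_that("cell partitioning separates cytoplasmic and P-body RNA", {
  spots <- data.frame(y = runif(30, 5, 60), x = runif(30, 5, 60),
                      accepted = TRUE, in_pbody = FALSE)
  none <- data.frame(label = integer(), area = integer(), y = numeric(),
                     x = numeric(), integrated_intensity = numeric(),
                     rna_equiv = numeric(), border = logical())
  q <- partition_cell(spots, none)
  expect_equal(q$n_ct, 30L)
  expect_equal(q$n_pb, 0)

  # an empty cell mask yields an all-zero record
  q0 <- partition_cell(spots, none, cell_mask = matrix(0L, 64, 64))
  expect_equal(q0$n_ct, 0L)
  expect_equal(q0$n_pbodies, 0L)

  # end-to-end on a rendered single-cell stack: both compartments within 10%
  st <- render_stack(test_scene(seed = 41L))
  q <- quantify_stack(st$rna, st$pbody)
  expect_equal(q$cell$n_ct, nrow(st$truth$spots), tolerance = 0.10)
  expect_equal(q$cell$n_pb, sum(st$truth$granules$molecules),
               tolerance = 0.10)
  expect_equal(q$cell$n_pbodies, nrow(st$truth$granules))

  # determinism of the whole quantification
  q2 <- quantify_stack(st$rna, st$pbody)
  expect_identical(q$cell, q2$cell)
})

test_that("trace aggregation normalizes per cell before averaging", {
  tr <- solve_trajectory(default_params(), seq(0, 2, by = 1 / 12))$rna_pb

  one <- aggregate_traces(matrix(tr, nrow = 1), seq(0, 2, by = 1 / 12))
  expect_equal(one$mean, tr / max(tr))
  expect_equal(one$se, rep(0, length(tr)))

  two <- aggregate_traces(rbind(2 * tr, 5 * tr))
  expect_equal(two$mean, tr / max(tr))
  expect_equal(two$se, rep(0, length(tr)))

  expect_message(agg <- aggregate_traces(rbind(tr, 0 * tr)), "all-zero")
  expect_equal(agg$n_cells[1], 1)

  # simulated cells agree with the normalized analytical curve within 2 SE
  lc <- simulate_livecell(default_params(), "no_leave", n_cells = 10L,
                          seed = 17L)
  agg <- aggregate_traces(lc$traces, lc$times)
  ref <- lc$truth$rna_pb / max(lc$truth$rna_pb)
  expect_true(all(abs(agg$mean - ref) <= 2 * agg$se + 1e-9))
})
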