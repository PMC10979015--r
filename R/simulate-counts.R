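#' Design of a simulated decay time-course experiment
#'
#' Describes the sampling structure the count simulator emulates: timepoints
#' over a 0-9 h course, biological replicates, cells per timepoint, and the
#' noise model. Per-cell counts are negative-binomial around the per-replicate
#' mean; each replicate additionally carries one shared lognormal
#' multiplicative factor (replicate-to-replicate expression-level variation)
#' applied to both compartments.
#'
#' @param times Timepoints (hours), default `c(0, 0.25, 0.5, 1, 2, 4, 6, 9)`.
#' @param n_replicates Biological replicates, default 4.
#' @param cells_per_timepoint Cells quantified per timepoint per replicate,
#'   default 200.
#' @param nb_size Negative-binomial size (dispersion) of per-cell counts;
#'   `Inf` gives Poisson, `NA` disables per-cell dispersion entirely (every
#'   cell takes the mean). Default 10 (CV about 35% at mean 100).
#' @param replicate_cv Coefficient of variation of the shared lognormal
#'   replicate factor, default 0.1.
#' @param seed Integer seed.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(times = c(0, 0.25, 0.5, 1, 2, 4, 6, 9),
                              n_replicates = 4L, cells_per_timepoint = 200L,
                              nb_size = 10, replicate_cv = 0.1, seed = 1L) {
  stopifnot(n_replicates >= 1L, cells_per_timepoint >= 1L,
            !is.unsorted(times, strictly = TRUE), all(times >= 0))
  if (!is.na(nb_size) && !is.infinite(nb_size) && nb_size <= 0) {
    stop("nb_size must be positive, Inf (Poisson) or NA (no dispersion)",
         call. = FALSE)
  }
  if (replicate_cv < 0) stop("replicate_cv must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times),
                 n_replicates = as.integer(n_replicates),
                 cells_per_timepoint = as.integer(cells_per_timepoint),
                 nb_size = nb_size, replicate_cv = replicate_cv,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

# Draw per-cell counts with mean mu: NB(size), Poisson (size = Inf), or
# deterministic (size = NA).
draw_cell_counts <- function(n, mu, size) {
  if (mu <= 0) return(rep(0, n))
  if (is.na(size)) return(rep(mu, n))
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, size = size, mu = mu)
}

#' Simulate replicate count time courses from the kinetic model
#'
#' Computes the analytical mean trajectory with [solve_trajectory()] under
#' the given variant, then draws per-cell cytoplasmic and P-body counts for
#' every replicate and timepoint per the noise model in
#' [experiment_design()], and aggregates them into the pooled
#' [time_course()] used for fitting (sd = standard deviation of the
#' replicate means). Deterministic per seed.
#'
#' @param params A [rate_params()] object (generating truth).
#' @param variant One of [model_variants()]; applied to `params` first.
#' @param design An [experiment_design()].
#' @return A list with `pooled` (a `time_course`), `replicates` (list of
#'   per-replicate `time_course`s; their `sd` is the standard error of the
#'   per-cell mean) and `truth` (generating parameters, per-replicate mean
#'   matrices, design and seed).
#' @export
simulate_counts <- function(params, variant, design = experiment_design()) {
  stopifnot(inherits(params, "rate_params"),
            inherits(design, "experiment_design"))
  variant <- match_variant(variant)
  params <- apply_variant(params, variant)
  traj <- solve_trajectory(params, design$times)
  nt <- length(design$times)

  sim <- with_seed(design$seed, {
    sdlog <- sqrt(log(1 + design$replicate_cv^2))
    rep_factor <- if (design$replicate_cv > 0) {
      stats::rlnorm(design$n_replicates, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, design$n_replicates)
    reps <- vector("list", design$n_replicates)
    for (r in seq_len(design$n_replicates)) {
      m_ct <- m_pb <- se_ct <- se_pb <- numeric(nt)
      for (i in seq_len(nt)) {
        ct <- draw_cell_counts(design$cells_per_timepoint,
                               rep_factor[r] * traj$rna_ct[i], design$nb_size)
        pb <- draw_cell_counts(design$cells_per_timepoint,
                               rep_factor[r] * traj$rna_pb[i], design$nb_size)
        m_ct[i] <- mean(ct); m_pb[i] <- mean(pb)
        se_ct[i] <- stats::sd(ct) / sqrt(length(ct))
        se_pb[i] <- stats::sd(pb) / sqrt(length(pb))
      }
      reps[[r]] <- time_course(design$times, m_ct, m_pb, se_ct, se_pb,
                               n_replicates = 1L,
                               n_cells = design$cells_per_timepoint)
    }
    list(reps = reps, rep_factor = rep_factor)
  })

  pooled <- if (design$n_replicates > 1L) {
    aggregate_replicates(sim$reps)
  } else sim$reps[[1L]]
  names(sim$reps) <- paste0("rep", seq_along(sim$reps))
  list(pooled = pooled,
       replicates = sim$reps,
       truth = list(params = params, variant = variant, design = design,
                    trajectory = traj, replicate_factors = sim$rep_factor,
                    seed = design$seed))
}

#' Simulate live-cell P-body intensity traces
#'
#' Emulates time-lapse imaging of the summed RNA-granule intensity in
#' P-bodies of single cells: each cell's trace is the analytical P-body
#' occupancy `rna_pb(t)` on the frame grid, times per-cell multiplicative
#' lognormal factors (expression-level scale and detection efficiency — the
#' dominant sources of trace-to-trace variability, and exactly what per-cell
#' normalization removes). Optional extras add iid per-frame measurement
#' jitter and per-cell kinetic heterogeneity (each cell's rates scattered
#' around the population rates). A "photostress" mode multiplies the P-body
#' decay rate by `photostress_factor` (< 1) to emulate the slowed granule
#' dissolution seen under high-excitation light stress (factor 0 = no decay
#' in P-bodies at all).
#'
#' @param params A [rate_params()] object.
#' @param variant One of [model_variants()].
#' @param n_cells Number of cells (traces).
#' @param frame_interval_min Minutes between frames, default 5.
#' @param duration_h Total imaging duration in hours, default 2.
#' @param scale_cv CV of the per-cell lognormal amplitude factor, default 0.3.
#' @param detection_cv CV of a second per-cell multiplicative factor
#'   (labeling/detection efficiency), default 0.1.
#' @param frame_noise_cv Optional iid per-frame multiplicative jitter CV,
#'   default 0.
#' @param kinetic_cv Optional CV of per-cell lognormal multipliers applied
#'   to each cell's rates, default 0.
#' @param photostress_factor Multiplier on `k_pb` in `[0, 1]`, default 1.
#' @param seed Integer seed.
#' @return A list: `times` (hours), `traces` (matrix, cells x frames),
#'   `truth` (analytical trace, per-cell factors, parameters, seed).
#' @export
simulate_livecell <- function(params, variant, n_cells = 10L,
                              frame_interval_min = 5, duration_h = 2,
                              scale_cv = 0.3, detection_cv = 0.1,
                              frame_noise_cv = 0, kinetic_cv = 0,
                              photostress_factor = 1, seed = 1L) {
  stopifnot(inherits(params, "rate_params"), n_cells >= 1L,
            frame_interval_min > 0, duration_h > 0,
            scale_cv >= 0, detection_cv >= 0, frame_noise_cv >= 0,
            kinetic_cv >= 0,
            photostress_factor >= 0, photostress_factor <= 1)
  variant <- match_variant(variant)
  p <- apply_variant(params, variant)
  p$k_pb <- p$k_pb * photostress_factor
  times <- seq(0, duration_h, by = frame_interval_min / 60)
  traj <- solve_trajectory(p, times)

  lnorm_factors <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  out <- with_seed(seed, {
    scales <- lnorm_factors(n_cells, scale_cv) *
      lnorm_factors(n_cells, detection_cv)
    tr <- matrix(0, nrow = n_cells, ncol = length(times))
    for (c_i in seq_len(n_cells)) {
      pb_t <- if (kinetic_cv > 0) {
        f <- lnorm_factors(3L, kinetic_cv)
        pc <- p
        pc$k_ct <- pc$k_ct * f[1L]
        pc$k_pb <- pc$k_pb * f[2L]
        pc$k_r <- pc$k_r * f[3L]
        solve_trajectory(pc, times)$rna_pb
      } else traj$rna_pb
      tr[c_i, ] <- pb_t * scales[c_i] *
        lnorm_factors(length(times), frame_noise_cv)
    }
    list(tr = tr, scales = scales)
  })
  list(times = times, traces = out$tr,
       truth = list(params = p, variant = variant, rna_pb = traj$rna_pb,
                    scales = out$scales, seed = seed))
}
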