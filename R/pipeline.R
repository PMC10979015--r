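#' Geometric mean of gated fluorescence intensities
#'
#' `exp(mean(log(x)))` over strictly positive intensities.
#'
#' @param x Positive intensity values.
#' @return The geometric mean.
#' @examples
#' geometric_mean(c(1, 100))  # 10
#' @export
geometric_mean <- function(x) {
  if (!length(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("intensities must be positive and finite", call. = FALSE)
  }
  geomean_impl(x)
}

#' Knockdown efficiency from flow-cytometry geometric means
#'
#' `100 * (1 - treated / control)` percent, where `treated` and `control`
#' are geometric-mean fluorescence intensities of the induced and uninduced
#' conditions of the same construct. Raw gated intensity vectors are also
#' accepted and reduced with [geometric_mean()] first.
#'
#' @param treated Geometric mean (scalar) or gated intensity vector of the
#'   treated condition.
#' @param control Geometric mean (scalar) or gated intensity vector of the
#'   matched untreated control; must be > 0.
#' @return Knockdown efficiency in percent.
#' @examples
#' knockdown_efficiency(26, 100)  # 74
#' @export
knockdown_efficiency <- function(treated, control) {
  treated_gm <- if (length(treated) > 1L) geometric_mean(treated) else treated
  control_gm <- if (length(control) > 1L) geometric_mean(control) else control
  if (!is.finite(control_gm) || control_gm <= 0) {
    stop("control geometric mean must be > 0", call. = FALSE)
  }
  if (!is.finite(treated_gm) || treated_gm < 0) {
    stop("treated geometric mean must be >= 0", call. = FALSE)
  }
  100 * (1 - treated_gm / control_gm)
}

#' Validate a pipeline run configuration
#'
#' Checks a configuration list (or JSON file) before any computation:
#' exactly one input source (`counts_csv` or `stacks`), recognised variants,
#' sane fit options. Returns the resolved config with defaults filled in.
#'
#' @param config A named list, or path to a JSON file.
#' @return The validated config list (class `run_config`).
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or JSON path", call. = FALSE)
  has_counts <- !is.null(config$counts_csv)
  has_stacks <- !is.null(config$stacks)
  if (!has_counts && !has_stacks) {
    stop("config needs 'counts_csv' or 'stacks'", call. = FALSE)
  }
  if (has_counts && !file.exists(config$counts_csv)) {
    stop("counts_csv not found: ", config$counts_csv, call. = FALSE)
  }
  if (has_stacks) {
    st <- config$stacks
    need <- c("rna_tiff", "pbody_tiff", "time_h", "replicate_id")
    if (!is.data.frame(st)) st <- as.data.frame(st)
    if (!all(need %in% names(st))) {
      stop("stacks table needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    missing <- !file.exists(st$rna_tiff) | !file.exists(st$pbody_tiff)
    if (any(missing)) {
      stop("stack TIFFs not found: ",
           paste(st$rna_tiff[missing], collapse = ", "), call. = FALSE)
    }
    config$stacks <- st
  }
  defaults <- list(variants = model_variants(), fit_n0 = "free",
                   n_starts = 16L, seed = 1L, sufficiency_factor = 1.2,
                   log_sigma = 2.5, output_dir = "pipeline_out",
                   make_plots = TRUE)
  config <- utils::modifyList(defaults, config)
  bad <- setdiff(config$variants, model_variants())
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!config$fit_n0 %in% c("free", "fixed")) {
    stop("fit_n0 must be 'free' or 'fixed'", call. = FALSE)
  }
  structure(config, class = c("run_config", "list"))
}

plot_fits <- function(data, fits, path) {
  obs <- rbind(
    data.frame(time_h = data$time_h, count = data$mean_ct, sd = data$sd_ct,
               compartment = "cytoplasm"),
    data.frame(time_h = data$time_h, count = data$mean_pb, sd = data$sd_pb,
               compartment = "P-body"))
  grid <- seq(min(data$time_h), max(data$time_h), length.out = 200)
  curves <- do.call(rbind, lapply(fits, function(f) {
    tr <- solve_trajectory(f$params, grid)
    rbind(data.frame(time_h = grid, count = tr$rna_ct,
                     compartment = "cytoplasm", variant = f$variant),
          data.frame(time_h = grid, count = tr$rna_pb,
                     compartment = "P-body", variant = f$variant))
  }))
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_h, y = .data$count)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$count - .data$sd,
                                          ymax = .data$count + .data$sd,
                                          colour = .data$compartment)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$compartment)) +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "time after induction (h)", y = "RNA per cell",
                  colour = NULL) +
    ggplot2::theme_bw()
  ggplot2::ggsave(path, p, width = 8, height = 6)
  invisible(path)
}

#' Run the full quantification-and-fitting pipeline
#'
#' Orchestrates quantification (when image stacks are configured),
#' aggregation into a time course, fitting of all requested model variants,
#' and model comparison. Writes into `output_dir`: the resolved config
#' (`run_config.json`, with seed and package version, for provenance), the
#' pooled time course (`time_course.csv`), per-cell quantification
#' (`cells.csv`, stacks input only), the ranked comparison table
#' (`model_comparison.csv`), per-variant fit parameters + diagnostics
#' (`fit_results.json`), and a data-vs-fit figure (`fits.pdf`).
#'
#' @param config A config list or JSON path; see [validate_run_config()].
#'   With `counts_csv` the CSV must follow the [write_time_course()] schema;
#'   with `stacks` a table of per-stack TIFF paths, `time_h` and
#'   `replicate_id` is expected.
#' @return Invisibly, a list with `data` (pooled `time_course`),
#'   `comparison` (ranked table), `fits`, and `cells` (if quantified).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  cells <- NULL

  if (!is.null(config$counts_csv)) {
    message("stage: read counts (", config$counts_csv, ")")
    tcs <- read_time_course(config$counts_csv)
    data <- tcs$pooled
  } else {
    message("stage: quantify ", nrow(config$stacks), " stacks")
    st <- config$stacks
    quant <- lapply(seq_len(nrow(st)), function(i) {
      q <- quantify_stack(read_stack_tiff(st$rna_tiff[i]),
                          read_stack_tiff(st$pbody_tiff[i]),
                          log_sigma = config$log_sigma, cell_id = i)
      cbind(q$cell, time_h = st$time_h[i], replicate_id = st$replicate_id[i])
    })
    cells <- do.call(rbind, quant)
    utils::write.csv(cells, file.path(config$output_dir, "cells.csv"),
                     row.names = FALSE)
    reps <- lapply(split(cells, cells$replicate_id), function(d) {
      d <- d[order(d$time_h), ]
      agg_ct <- tapply(d$n_ct, d$time_h, mean)
      agg_pb <- tapply(d$n_pb, d$time_h, mean)
      tt <- as.numeric(names(agg_ct))
      time_course(tt, as.numeric(agg_ct), as.numeric(agg_pb),
                  rep(0, length(tt)), rep(0, length(tt)), n_replicates = 1L)
    })
    data <- if (length(reps) > 1L) aggregate_replicates(reps) else reps[[1L]]
  }

  message("stage: fit variants (", paste(config$variants, collapse = ", "), ")")
  opts <- fit_options(n_starts = config$n_starts, seed = config$seed,
                      fit_n0 = config$fit_n0)
  comparison <- compare_models(data, config$variants, opts,
                               config$sufficiency_factor)
  fits <- attr(comparison, "fits")

  message("stage: write outputs -> ", config$output_dir)
  write_time_course(data, file.path(config$output_dir, "time_course.csv"))
  utils::write.csv(comparison, file.path(config$output_dir,
                                         "model_comparison.csv"),
                   row.names = FALSE)
  diag <- lapply(fits, function(f) {
    list(variant = f$variant, params = unclass(f$params),
         reduced_chi2 = f$reduced_chi2, chi2 = f$chi2,
         n_free_params = f$n_free_params, converged = f$converged,
         residuals_ct = f$residuals_ct, residuals_pb = f$residuals_pb)
  })
  jsonlite::write_json(diag, file.path(config$output_dir, "fit_results.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- unclass(config)
  prov$stacks <- if (!is.null(cells)) nrow(config$stacks) else NULL
  prov$package_version <- as.character(utils::packageVersion("pbodykinetics"))
  jsonlite::write_json(prov, file.path(config$output_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(config$make_plots)) {
    plot_fits(data, fits, file.path(config$output_dir, "fits.pdf"))
  }
  message(sprintf("pipeline finished in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(data = data, comparison = comparison, fits = fits,
                 cells = cells))
}
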