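#' Replicate-mean RNA count time course
#'
#' Container for the measured inputs to model fitting: per-timepoint
#' replicate-mean RNA counts per cell in the cytoplasm and in P-bodies, the
#' standard deviation of the replicate means (the plotted error bars), and
#' bookkeeping metadata.
#'
#' @param times Strictly ascending timepoints in hours.
#' @param mean_ct,mean_pb Replicate-mean counts per cell at each timepoint.
#' @param sd_ct,sd_pb Standard deviation of the replicate means (>= 0).
#' @param n_replicates Number of biological replicates behind the means.
#' @param n_cells Optional cells-per-timepoint metadata (scalar or vector).
#' @return A `time_course` object (a data frame with attributes).
#' @export
time_course <- function(times, mean_ct, mean_pb, sd_ct, sd_pb,
                        n_replicates = NA_integer_, n_cells = NA_real_) {
  n <- length(times)
  if (!all(lengths(list(mean_ct, mean_pb, sd_ct, sd_pb)) == n)) {
    stop("all time-course vectors must have the same length", call. = FALSE)
  }
  if (n < 2L) stop("a time course needs at least 2 timepoints", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly ascending", call. = FALSE)
  }
  if (any(c(sd_ct, sd_pb) < 0)) stop("sd must be >= 0", call. = FALSE)
  out <- data.frame(time_h = as.numeric(times),
                    mean_ct = as.numeric(mean_ct),
                    mean_pb = as.numeric(mean_pb),
                    sd_ct = as.numeric(sd_ct),
                    sd_pb = as.numeric(sd_pb))
  attr(out, "n_replicates") <- n_replicates
  attr(out, "n_cells") <- n_cells
  class(out) <- c("time_course", "data.frame")
  out
}

#' Aggregate per-replicate time courses into one pooled time course
#'
#' Pointwise mean across replicates, with `sd` the standard deviation of the
#' replicate means — the quantity drawn as error bars and used as chi-square
#' weights.
#'
#' @param replicates List of `time_course` objects on a common time grid.
#' @return A pooled `time_course`.
#' @export
aggregate_replicates <- function(replicates) {
  stopifnot(length(replicates) >= 1L,
            all(vapply(replicates, inherits, logical(1), "time_course")))
  times <- replicates[[1L]]$time_h
  for (r in replicates) {
    if (!isTRUE(all.equal(r$time_h, times))) {
      stop("replicates must share a common time grid", call. = FALSE)
    }
  }
  ct <- vapply(replicates, function(r) r$mean_ct, numeric(length(times)))
  pb <- vapply(replicates, function(r) r$mean_pb, numeric(length(times)))
  ct <- matrix(ct, nrow = length(times))
  pb <- matrix(pb, nrow = length(times))
  k <- length(replicates)
  sd_or_zero <- function(m) if (k > 1L) apply(m, 1L, stats::sd) else rep(0, nrow(m))
  cells <- vapply(replicates, function(r) {
    nc <- attr(r, "n_cells")
    if (all(is.na(nc))) NA_real_ else sum(nc, na.rm = TRUE)
  }, numeric(1))
  time_course(times,
              mean_ct = rowMeans(ct), mean_pb = rowMeans(pb),
              sd_ct = sd_or_zero(ct), sd_pb = sd_or_zero(pb),
              n_replicates = k,
              n_cells = if (all(is.na(cells))) NA_real_ else sum(cells, na.rm = TRUE))
}

#' Read a time course from CSV
#'
#' Accepts the long format written by [write_time_course()]: columns
#' `time_h`, `compartment` (`CT`/`PB`), `replicate_id`, `mean_count`, `sd`.
#' Rows with distinct `replicate_id` are treated as per-replicate means and
#' aggregated with [aggregate_replicates()]; a file with a single replicate id
#' is returned as-is with the stated `sd`.
#'
#' @param path CSV path.
#' @return A list with elements `pooled` (a `time_course`) and `replicates`
#'   (list of per-replicate `time_course`s, one per replicate id).
#' @export
read_time_course <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "compartment", "replicate_id", "mean_count", "sd")
  if (!all(need %in% names(df))) {
    stop("time-course CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$compartment %in% c("CT", "PB"))) {
    stop("compartment must be 'CT' or 'PB'", call. = FALSE)
  }
  reps <- lapply(split(df, df$replicate_id), function(d) {
    ct <- d[d$compartment == "CT", ]
    pb <- d[d$compartment == "PB", ]
    ct <- ct[order(ct$time_h), ]
    pb <- pb[order(pb$time_h), ]
    if (!isTRUE(all.equal(ct$time_h, pb$time_h))) {
      stop("CT and PB rows must cover the same timepoints", call. = FALSE)
    }
    time_course(ct$time_h, ct$mean_count, pb$mean_count, ct$sd, pb$sd,
                n_replicates = 1L)
  })
  pooled <- if (length(reps) > 1L) aggregate_replicates(reps) else reps[[1L]]
  list(pooled = pooled, replicates = reps)
}

#' Write a time course (or per-replicate list) to long-format CSV
#'
#' @param x A `time_course`, or a list of per-replicate `time_course`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(x, path) {
  if (inherits(x, "time_course")) x <- list(pooled = x)
  rows <- lapply(seq_along(x), function(i) {
    tc <- x[[i]]
    id <- names(x)[i]
    if (is.null(id) || id == "") id <- as.character(i)
    rbind(
      data.frame(time_h = tc$time_h, compartment = "CT", replicate_id = id,
                 mean_count = tc$mean_ct, sd = tc$sd_ct),
      data.frame(time_h = tc$time_h, compartment = "PB", replicate_id = id,
                 mean_count = tc$mean_pb, sd = tc$sd_pb)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
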