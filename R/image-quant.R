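# Quantification of RNA in P-bodies and cytoplasm from smFISH-IF stacks.
# Arrays are (z, y, x) with 1-based voxel indices; 2D images are (y, x).

# Row-normalized banded Gaussian convolution matrix (replicate-edge
# behaviour via renormalization of the truncated kernel).
gauss_band_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  h <- ceiling(4 * sigma)
  i <- matrix(seq_len(n), n, n)
  K <- exp(-(i - t(i))^2 / (2 * sigma^2))
  K[abs(i - t(i)) > h] <- 0
  K / rowSums(K)
}

# Separable 3D Gaussian smoothing of a (z, y, x) array.
gauss_smooth_3d <- function(arr, sigma_xy, sigma_z) {
  d <- dim(arr)
  Kz <- gauss_band_matrix(d[1L], sigma_z)
  Ky <- gauss_band_matrix(d[2L], sigma_xy)
  Kx <- gauss_band_matrix(d[3L], sigma_xy)
  m <- Kz %*% matrix(arr, d[1L], d[2L] * d[3L])
  arr <- array(m, d)
  arr <- aperm(arr, c(2L, 1L, 3L))
  m <- Ky %*% matrix(arr, d[2L], d[1L] * d[3L])
  arr <- aperm(array(m, d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  arr <- aperm(arr, c(3L, 2L, 1L))
  m <- Kx %*% matrix(arr, d[3L], d[2L] * d[1L])
  aperm(array(m, d[c(3L, 2L, 1L)]), c(3L, 2L, 1L))
}

# Laplacian-of-Gaussian kernel (sign-flipped so bright blobs respond
# positively), zero-sum normalized.
log_kernel <- function(sigma) {
  h <- ceiling(4 * sigma)
  ax <- -h:h
  g <- outer(ax, ax, function(y, x) {
    r2 <- x^2 + y^2
    (r2 / sigma^2 - 2) / sigma^2 * exp(-r2 / (2 * sigma^2))
  })
  g <- -g            # bright blob -> positive response
  g - mean(g)        # flat regions -> exactly zero response
}

#' Segment P-bodies in an immunofluorescence channel
#'
#' Filters the (max-projected) P-body channel with a Laplacian-of-Gaussian
#' blob filter, thresholds the response, and labels connected components,
#' discarding regions below a minimum-area floor. An empty or featureless
#' image yields an empty mask, not an error.
#'
#' @param img 2D matrix `(y, x)`, or a 3D `(z, y, x)` stack (max-projected
#'   along z first).
#' @param log_sigma LoG scale in pixels, matched to the P-body radius
#'   (default 2.5).
#' @param threshold_policy List: `method` `"quantile"` (threshold at
#'   quantile `q` of the LoG response, default 0.995) or `"otsu"`;
#'   `k_mad` robust guard — the threshold is never below
#'   `median + k_mad * mad` of the response (default 5), so a blob-free
#'   noise image segments (almost) nothing; `min_area` region floor in
#'   pixels (default 4).
#' @return Integer label matrix `(y, x)`; 0 = background.
#' @export
segment_pbodies <- function(img, log_sigma = 2.5,
                            threshold_policy = list()) {
  pol <- utils::modifyList(
    list(method = "quantile", q = 0.995, k_mad = 5, min_area = 4L),
    threshold_policy)
  if (log_sigma <= 0) stop("log_sigma must be > 0", call. = FALSE)
  if (length(dim(img)) == 3L) img <- max_project(img)
  stopifnot(length(dim(img)) == 2L)

  resp <- EBImage::filter2(img, log_kernel(log_sigma))
  resp <- as.matrix(resp)
  thr <- switch(pol$method,
    quantile = stats::quantile(resp, pol$q, names = FALSE),
    otsu = {
      rng <- range(resp)
      if (diff(rng) == 0) Inf else {
        norm <- (resp - rng[1L]) / diff(rng)
        EBImage::otsu(EBImage::Image(norm)) * diff(rng) + rng[1L]
      }
    },
    stop("unknown threshold method: ", pol$method, call. = FALSE))
  guard <- stats::median(resp) + pol$k_mad * stats::mad(resp)
  thr <- max(thr, guard, 1e-6 * max(abs(img), 1))
  mask <- resp > thr
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))

  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  if (pol$min_area > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < pol$min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
    # relabel compactly
    keep <- sort(unique(lab[lab > 0L]))
    if (length(keep)) {
      remap <- integer(max(keep)); remap[keep] <- seq_along(keep)
      lab[lab > 0L] <- remap[lab[lab > 0L]]
    }
  }
  lab
}

# Shift a 3D array by (dz, dy, dx), padding with -Inf.
shift3 <- function(arr, dz, dy, dx) {
  d <- dim(arr)
  out <- array(-Inf, dim = d)
  zs <- intersect(seq_len(d[1L]), seq_len(d[1L]) - dz)
  ys <- intersect(seq_len(d[2L]), seq_len(d[2L]) - dy)
  xs <- intersect(seq_len(d[3L]), seq_len(d[3L]) - dx)
  out[zs + dz, ys + dy, xs + dx] <- arr[zs, ys, xs]
  out
}

#' Detect candidate single-RNA spots in a 3D stack
#'
#' Band-pass filters the stack (difference of Gaussians at the PSF scale),
#' finds 26-neighbourhood local maxima above an intensity threshold, and
#' deduplicates maxima closer than a minimum separation (brightest wins).
#'
#' @param stack 3D `(z, y, x)` RNA channel.
#' @param detection_sigma PSF-scale `c(xy, z)` of the band-pass, default
#'   `c(1.3, 2.5)`.
#' @param intensity_threshold Threshold on the filtered response; `NULL`
#'   (default) uses the robust automatic `median + k_mad * mad`.
#' @param k_mad Multiplier for the automatic threshold (default 8).
#' @param min_separation `c(xy, z)` deduplication radii in voxels.
#' @return Data frame of candidates: `z`, `y`, `x` (integer voxel), `value`
#'   (filtered response), sorted brightest first. May be empty.
#' @export
detect_spots <- function(stack, detection_sigma = c(1.3, 2.5),
                         intensity_threshold = NULL, k_mad = 8,
                         min_separation = c(2, 1)) {
  stopifnot(length(dim(stack)) == 3L, all(detection_sigma > 0))
  if (!is.null(intensity_threshold) && intensity_threshold < 0) {
    stop("intensity_threshold must be >= 0", call. = FALSE)
  }
  s1 <- gauss_smooth_3d(stack, detection_sigma[1L] / 1.6,
                        detection_sigma[2L] / 1.6)
  s2 <- gauss_smooth_3d(stack, detection_sigma[1L] * 1.6,
                        detection_sigma[2L] * 1.6)
  bp <- s1 - s2
  thr <- if (is.null(intensity_threshold)) {
    stats::median(bp) + k_mad * stats::mad(bp)
  } else intensity_threshold

  is_max <- bp > thr
  if (any(is_max)) {
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      is_max <- is_max & (bp >= shift3(bp, dz, dy, dx))
      if (!any(is_max)) break
    }
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(z = integer(), y = integer(), x = integer(),
                      value = numeric()))
  }
  cand <- data.frame(z = idx[, 1L], y = idx[, 2L], x = idx[, 3L],
                     value = bp[idx])
  cand <- cand[order(-cand$value), , drop = FALSE]

  # greedy non-maximum suppression within min_separation
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    prior <- which(keep)
    if (!length(prior)) { keep[i] <- TRUE; next }
    close_xy <- (cand$y[prior] - cand$y[i])^2 +
      (cand$x[prior] - cand$x[i])^2 <= min_separation[1L]^2
    close_z <- abs(cand$z[prior] - cand$z[i]) <= min_separation[2L]
    keep[i] <- !any(close_xy & close_z)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a 3D Gaussian to one candidate spot
#'
#' Least-squares fit of `amplitude * Gaussian(center; sigma_xy, sigma_z) +
#' background` within a rectangular ROI around the candidate, giving a
#' sub-voxel center. A spot is accepted when the fit converged, the
#' amplitude exceeds `accept_k` times the local noise SD (residual SD in the
#' ROI), the fitted widths stay strictly inside `[0.5, 3] x` the nominal PSF
#' and the center stays inside the ROI. Candidates within `roi_halfwidth` of
#' any stack border are rejected by default.
#'
#' @param stack 3D `(z, y, x)` RNA channel.
#' @param candidate List/row with integer `z`, `y`, `x`.
#' @param roi_halfwidth `c(xy, z)` ROI half-widths in voxels.
#' @param psf_sigma Nominal `c(xy, z)` PSF widths (start values and bounds).
#' @param accept_k Amplitude acceptance threshold in local-noise SDs.
#' @param reject_border Reject border candidates instead of shrinking.
#' @return One-row data frame: `z`, `y`, `x` (sub-voxel), `amplitude`,
#'   `background`, `sigma_xy`, `sigma_z`, `max_proj_intensity` (the
#'   integrated intensity of the fitted spot in the max projection,
#'   `2 * pi * amplitude * sigma_xy^2` — computed from the local fit rather
#'   than by windowed pixel summation, which nearby spots would
#'   contaminate), `accepted`, `reason`.
#' @export
fit_spot_3d <- function(stack, candidate, roi_halfwidth = c(4L, 3L),
                        psf_sigma = c(1.3, 2.5), accept_k = 3,
                        reject_border = TRUE) {
  d <- dim(stack)
  cz <- candidate$z; cy <- candidate$y; cx <- candidate$x
  hz <- roi_halfwidth[2L]; hxy <- roi_halfwidth[1L]
  rejected <- function(reason) {
    data.frame(z = cz, y = cy, x = cx, amplitude = NA_real_,
               background = NA_real_, sigma_xy = NA_real_, sigma_z = NA_real_,
               max_proj_intensity = NA_real_, accepted = FALSE,
               reason = reason)
  }
  border <- cz - hz < 1L || cz + hz > d[1L] ||
    cy - hxy < 1L || cy + hxy > d[2L] ||
    cx - hxy < 1L || cx + hxy > d[3L]
  if (border && reject_border) return(rejected("border"))
  zi <- max(1L, cz - hz):min(d[1L], cz + hz)
  yi <- max(1L, cy - hxy):min(d[2L], cy + hxy)
  xi <- max(1L, cx - hxy):min(d[3L], cx + hxy)
  roi <- stack[zi, yi, xi, drop = FALSE]
  grid <- expand.grid(z = zi, y = yi, x = xi)
  vals <- as.numeric(roi)

  bg0 <- stats::quantile(vals, 0.25, names = FALSE)
  a0 <- max(vals) - bg0
  if (a0 <= 0) return(rejected("flat"))
  start <- c(A = a0, bg = bg0, z0 = cz, y0 = cy, x0 = cx,
             sxy = psf_sigma[1L], sz = psf_sigma[2L])
  lower <- c(0, 0, min(zi), min(yi), min(xi),
             0.5 * psf_sigma[1L], 0.5 * psf_sigma[2L])
  upper <- c(Inf, Inf, max(zi), max(yi), max(xi),
             3 * psf_sigma[1L], 3 * psf_sigma[2L])
  fn <- function(p) {
    p[1L] * exp(-((grid$y - p[4L])^2 + (grid$x - p[5L])^2) / (2 * p[6L]^2) -
                  (grid$z - p[3L])^2 / (2 * p[7L]^2)) + p[2L] - vals
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(rejected("diverged"))
  p <- fit$par
  noise_sd <- stats::sd(fit$fvec)
  tol <- 1e-6
  if (p[1L] < accept_k * noise_sd) return(rejected("dim"))
  if (p[6L] <= lower[6L] + tol || p[6L] >= upper[6L] - tol ||
      p[7L] <= lower[7L] + tol || p[7L] >= upper[7L] - tol) {
    return(rejected("sigma_bound"))
  }
  data.frame(z = p[3L], y = p[4L], x = p[5L], amplitude = p[1L],
             background = p[2L], sigma_xy = p[6L], sigma_z = p[7L],
             max_proj_intensity = 2 * pi * p[1L] * p[6L]^2,
             accepted = TRUE, reason = "ok")
}

#' Detect and fit all spots in a stack
#'
#' Convenience wrapper: [detect_spots()] then [fit_spot_3d()] per candidate,
#' annotating each accepted spot with whether it falls inside the P-body
#' mask (`in_pbody`).
#'
#' @param stack 3D `(z, y, x)` RNA channel.
#' @param pbody_mask Optional label matrix from [segment_pbodies()].
#' @param ... Passed to [detect_spots()] and [fit_spot_3d()] (matched by
#'   name: `detection_sigma`, `intensity_threshold`, `roi_halfwidth`,
#'   `psf_sigma`, `accept_k`).
#' @return Data frame of spot fits (see [fit_spot_3d()]) plus `in_pbody`.
#' @export
fit_spots <- function(stack, pbody_mask = NULL, detection_sigma = c(1.3, 2.5),
                      intensity_threshold = NULL, roi_halfwidth = c(4L, 3L),
                      psf_sigma = c(1.3, 2.5), accept_k = 3) {
  cand <- detect_spots(stack, detection_sigma, intensity_threshold)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    fit_spot_3d(stack, cand[i, ], roi_halfwidth, psf_sigma, accept_k)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(z = numeric(), y = numeric(), x = numeric(),
               amplitude = numeric(), background = numeric(),
               sigma_xy = numeric(), sigma_z = numeric(),
               max_proj_intensity = numeric(), accepted = logical(),
               reason = character())
  out$in_pbody <- in_mask(out$y, out$x, pbody_mask)
  out
}

# TRUE where the rounded (y, x) position falls on a positive mask pixel.
in_mask <- function(y, x, mask) {
  if (is.null(mask) || !length(y)) return(rep(FALSE, length(y)))
  d <- dim(mask)
  yi <- pmin(pmax(round(y), 1L), d[1L])
  xi <- pmin(pmax(round(x), 1L), d[2L])
  mask[cbind(yi, xi)] > 0
}

#' Single-molecule unit intensity
#'
#' Median background-corrected integrated max-projection intensity of
#' accepted single spots lying outside the P-body mask. This is the divisor
#' that converts granule intensity into RNA-equivalent molecule counts.
#'
#' @param spots Spot data frame from [fit_spots()] (needs `accepted`,
#'   `max_proj_intensity`, and `in_pbody` or `y`/`x` + `pbody_mask`).
#' @param pbody_mask Optional label matrix; used if `spots$in_pbody` absent.
#' @return Intensity units per molecule (scalar).
#' @export
unit_intensity <- function(spots, pbody_mask = NULL) {
  inb <- if (!is.null(spots$in_pbody)) spots$in_pbody else
    in_mask(spots$y, spots$x, pbody_mask)
  ok <- spots$accepted & !inb & is.finite(spots$max_proj_intensity)
  if (!any(ok)) {
    stop("no accepted spots outside P-bodies; supply a unit intensity ",
         "measured elsewhere", call. = FALSE)
  }
  stats::median(spots$max_proj_intensity[ok])
}

#' Quantify granule RNA content in P-body regions
#'
#' Integrates the max-projected RNA channel over each segmented P-body
#' region, subtracts a local background (median intensity in a ring of width
#' `annulus_width` pixels around the region, scaled by the integration
#' area), and divides by the single-molecule unit intensity to obtain
#' RNA-equivalent molecule counts. Before integration each region is grown
#' by `grow` pixels so the diffraction-limited tails of the granule signal —
#' which extend slightly beyond the immunofluorescence-segmented P-body area
#' — are included; the background annulus sits outside every grown region.
#'
#' @param rna_maxproj 2D `(y, x)` max projection of the RNA channel.
#' @param pbody_mask Label matrix from [segment_pbodies()].
#' @param unit Intensity units per molecule (> 0), from [unit_intensity()].
#' @param background_policy `"annulus"` (default) or `"none"`.
#' @param annulus_width Ring width in pixels (default 2).
#' @param grow Region dilation in pixels before integration (default 2).
#' @return Data frame: `label`, `area` (original segmented area, px),
#'   `y`, `x` (centroid), `integrated_intensity`, `rna_equiv`, `border`
#'   (grown region touches the image edge).
#' @export
quantify_granules <- function(rna_maxproj, pbody_mask, unit,
                              background_policy = c("annulus", "none"),
                              annulus_width = 2L, grow = 2L) {
  background_policy <- match.arg(background_policy)
  if (!is.numeric(unit) || unit <= 0) stop("unit must be > 0", call. = FALSE)
  stopifnot(all(dim(rna_maxproj) == dim(pbody_mask)))
  labels <- sort(unique(pbody_mask[pbody_mask > 0L]))
  if (!length(labels)) {
    return(data.frame(label = integer(), area = integer(), y = numeric(),
                      x = numeric(), integrated_intensity = numeric(),
                      rna_equiv = numeric(), border = logical()))
  }
  d <- dim(pbody_mask)
  dilate_px <- function(region, px) {
    if (px <= 0L) return(region)
    brush <- EBImage::makeBrush(2L * px + 1L, shape = "disc")
    as.matrix(EBImage::dilate(EBImage::Image(region), brush)) > 0
  }
  all_grown <- dilate_px(pbody_mask > 0L, grow)
  do.call(rbind, lapply(labels, function(l) {
    region <- pbody_mask == l
    idx <- which(region, arr.ind = TRUE)
    reg_grown <- dilate_px(region, grow)
    gidx <- which(reg_grown, arr.ind = TRUE)
    border <- any(gidx[, 1L] %in% c(1L, d[1L])) ||
      any(gidx[, 2L] %in% c(1L, d[2L]))
    raw <- sum(rna_maxproj[reg_grown])
    bg <- 0
    if (background_policy == "annulus") {
      ring <- dilate_px(reg_grown, annulus_width) & !all_grown
      if (any(ring)) bg <- stats::median(rna_maxproj[ring])
    }
    integrated <- raw - bg * sum(reg_grown)
    data.frame(label = l, area = nrow(idx),
               y = mean(idx[, 1L]), x = mean(idx[, 2L]),
               integrated_intensity = integrated,
               rna_equiv = integrated / unit, border = border)
  }))
}

#' Partition per-cell RNA counts into cytoplasm and P-bodies
#'
#' Cytoplasmic RNA is every accepted single-spot detection inside the cell
#' mask and outside the P-body regions; P-body RNA is the summed
#' RNA-equivalent content of the cell's granules.
#'
#' @param spots Spot data frame from [fit_spots()].
#' @param granules Granule data frame from [quantify_granules()].
#' @param cell_mask Optional 2D cell mask (`> 0` inside the cell); `NULL`
#'   treats the whole field as one cell.
#' @param pbody_mask Optional P-body label matrix; used if `spots$in_pbody`
#'   is absent.
#' @param cell_id Identifier carried through to the output row.
#' @return One-row data frame: `cell_id`, `n_ct` (integer), `n_pb`,
#'   `n_pbodies`, `mean_pbody_intensity`.
#' @export
partition_cell <- function(spots, granules, cell_mask = NULL,
                           pbody_mask = NULL, cell_id = 1L) {
  in_pb <- if (!is.null(spots$in_pbody)) spots$in_pbody else
    in_mask(spots$y, spots$x, pbody_mask)
  in_cell <- if (is.null(cell_mask)) rep(TRUE, nrow(spots)) else
    in_mask(spots$y, spots$x, cell_mask)
  n_ct <- sum(spots$accepted & in_cell & !in_pb, na.rm = TRUE)
  g_in <- if (is.null(cell_mask) || nrow(granules) == 0L) {
    rep(TRUE, nrow(granules))
  } else in_mask(granules$y, granules$x, cell_mask)
  g <- granules[g_in, , drop = FALSE]
  data.frame(cell_id = cell_id, n_ct = as.integer(n_ct),
             n_pb = if (nrow(g)) sum(g$rna_equiv) else 0,
             n_pbodies = nrow(g),
             mean_pbody_intensity = if (nrow(g)) mean(g$integrated_intensity) else 0)
}

#' Quantify one two-channel stack end to end
#'
#' Runs segment -> detect -> fit -> unit -> granule quantification ->
#' partition on an RNA / P-body channel pair.
#'
#' @param rna 3D `(z, y, x)` RNA channel.
#' @param pbody 3D (or 2D) P-body channel.
#' @param cell_mask Optional 2D cell mask.
#' @param log_sigma,threshold_policy Passed to [segment_pbodies()].
#' @param unit Optional externally supplied unit intensity; `NULL` measures
#'   it from this stack's own single spots.
#' @param ... Passed to [fit_spots()].
#' @param cell_id Identifier for the output row.
#' @return List: `cell` (one-row data frame), `spots`, `granules`,
#'   `pbody_mask`, `unit`.
#' @export
quantify_stack <- function(rna, pbody, cell_mask = NULL, log_sigma = 2.5,
                           threshold_policy = list(), unit = NULL,
                           cell_id = 1L, ...) {
  mask <- segment_pbodies(pbody, log_sigma, threshold_policy)
  spots <- fit_spots(rna, pbody_mask = mask, ...)
  if (is.null(unit)) unit <- unit_intensity(spots)
  granules <- quantify_granules(max_project(rna), mask, unit)
  cell <- partition_cell(spots, granules, cell_mask, mask, cell_id)
  list(cell = cell, spots = spots, granules = granules,
       pbody_mask = mask, unit = unit)
}

#' Average normalized granule-intensity traces across cells
#'
#' Each cell's summed-granule-intensity time series is normalized by its own
#' maximum, then the traces are averaged pointwise with the standard error
#' across cells. All-zero traces (no granules ever detected) are excluded.
#'
#' @param traces Matrix (cells x frames) or list of equal-length numeric
#'   traces with >= 2 timepoints.
#' @param times Optional frame times (hours) carried into the output.
#' @return Data frame: `time_h` (or frame index), `mean`, `se`, `n_cells`;
#'   the normalized per-cell traces are attached as attribute
#'   `"normalized"`.
#' @export
aggregate_traces <- function(traces, times = NULL) {
  if (is.list(traces)) {
    if (length(unique(lengths(traces))) != 1L) {
      stop("all traces must have the same number of frames", call. = FALSE)
    }
    traces <- do.call(rbind, traces)
  }
  stopifnot(is.matrix(traces), ncol(traces) >= 2L, nrow(traces) >= 1L)
  mx <- apply(traces, 1L, max)
  zero <- mx <= 0
  if (any(zero)) {
    message("excluding ", sum(zero), " all-zero trace(s)")
    traces <- traces[!zero, , drop = FALSE]
    mx <- mx[!zero]
  }
  if (!nrow(traces)) stop("no non-zero traces to aggregate", call. = FALSE)
  norm <- traces / mx
  n <- nrow(norm)
  se <- if (n > 1L) apply(norm, 2L, stats::sd) / sqrt(n) else
    rep(0, ncol(norm))
  out <- data.frame(
    time_h = if (is.null(times)) seq_len(ncol(norm)) else times,
    mean = colMeans(norm), se = se, n_cells = n)
  attr(out, "normalized") <- norm
  out
}
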