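#' Scene description for the synthetic smFISH image renderer
#'
#' Defines a single-cell field of view: diffraction-limited single-RNA spots
#' scattered through the cytoplasm, bright RNA granules sitting on P-body
#' loci, and the imaging/noise model. Optics defaults emulate a 60x/1.4NA
#' wide-field setup at 107 nm pixels (PSF sigma 1.3 px laterally, 2.5 px
#' axially, z step 300 nm); these are plausible-optics choices, not measured
#' values. The signal-to-noise ratio of a single spot is
#' `spot_amplitude / sqrt(background + read_noise_sd^2)`.
#'
#' @param dim Stack dimensions `c(z, y, x)` in voxels.
#' @param n_spots Number of cytoplasmic single-RNA spots.
#' @param spot_amplitude Peak intensity of one RNA molecule above background.
#' @param psf_sigma_xy,psf_sigma_z PSF Gaussian widths in pixels.
#' @param n_granules Number of RNA granules (one per P-body).
#' @param granule_molecules Range (2-vector) of molecules per granule,
#'   sampled uniformly; or a vector of length `n_granules` giving exact
#'   contents.
#' @param min_spot_separation Minimum lateral distance (px) between planted
#'   cytoplasmic spots whose z planes are within `2 * psf_sigma_z` of each
#'   other (default 4): planted single molecules are mutually resolvable at
#'   the diffraction limit. Set to 0 for fully random placement (closer
#'   pairs merge into single detections and are undercounted).
#' @param granule_jitter_xy Lateral scatter (sd, px) of molecules within a
#'   granule; all molecules of a granule share its z plane (the granule is
#'   sub-diffraction axially), so max-projected granule intensity stays
#'   exactly linear in molecule content.
#' @param background RNA-channel autofluorescent background (counts/voxel).
#' @param read_noise_sd Gaussian camera read noise (counts).
#' @param poisson_noise Apply Poisson shot noise (logical).
#' @param pbody_sigma,pbody_amplitude,pbody_background P-body channel blob
#'   width, peak intensity and background.
#' @param margin_xy,margin_z Placement margin from the stack borders (px).
#' @param seed Integer seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(dim = c(z = 12L, y = 192L, x = 192L),
                         n_spots = 200L, spot_amplitude = 100,
                         psf_sigma_xy = 1.3, psf_sigma_z = 2.5,
                         n_granules = 6L, granule_molecules = c(10L, 40L),
                         min_spot_separation = 4, granule_jitter_xy = 0.7,
                         background = 75, read_noise_sd = 5,
                         poisson_noise = TRUE,
                         pbody_sigma = 2.5, pbody_amplitude = 400,
                         pbody_background = 10,
                         margin_xy = 10L, margin_z = 3L, seed = 1L) {
  stopifnot(length(dim) == 3L, all(dim >= 1L), n_spots >= 0L,
            spot_amplitude > 0, psf_sigma_xy > 0, psf_sigma_z > 0,
            n_granules >= 0L, background >= 0, read_noise_sd >= 0,
            pbody_sigma > 0)
  structure(list(dim = as.integer(dim), n_spots = as.integer(n_spots),
                 spot_amplitude = spot_amplitude,
                 psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 n_granules = as.integer(n_granules),
                 granule_molecules = granule_molecules,
                 min_spot_separation = min_spot_separation,
                 granule_jitter_xy = granule_jitter_xy,
                 background = background, read_noise_sd = read_noise_sd,
                 poisson_noise = poisson_noise,
                 pbody_sigma = pbody_sigma, pbody_amplitude = pbody_amplitude,
                 pbody_background = pbody_background,
                 margin_xy = as.integer(margin_xy),
                 margin_z = as.integer(margin_z), seed = as.integer(seed)),
            class = "scene_config")
}

# Add one 3D Gaussian of peak `amp` at (z0, y0, x0) into `stack`, truncated
# at 4 sigma. 1-based voxel centers; sub-voxel positions allowed.
add_gaussian3 <- function(stack, z0, y0, x0, amp, sxy, sz) {
  d <- dim(stack)
  zi <- max(1L, floor(z0 - 4 * sz)):min(d[1L], ceiling(z0 + 4 * sz))
  yi <- max(1L, floor(y0 - 4 * sxy)):min(d[2L], ceiling(y0 + 4 * sxy))
  xi <- max(1L, floor(x0 - 4 * sxy)):min(d[3L], ceiling(x0 + 4 * sxy))
  gz <- exp(-(zi - z0)^2 / (2 * sz^2))
  gy <- exp(-(yi - y0)^2 / (2 * sxy^2))
  gx <- exp(-(xi - x0)^2 / (2 * sxy^2))
  stack[zi, yi, xi] <- stack[zi, yi, xi] + amp * (gz %o% gy %o% gx)
  stack
}

#' Render a synthetic two-channel smFISH image stack with ground truth
#'
#' The RNA channel is the sum of single-molecule 3D Gaussian PSFs (cytoplasmic
#' spots plus granule molecules clustered at P-body loci) over an
#' autofluorescent background, with optional Poisson shot noise and Gaussian
#' read noise. The P-body channel holds soft Gaussian blobs at the P-body
#' loci. Every generating quantity is returned as serializable ground truth.
#'
#' @param scene A [scene_config()].
#' @return A list with `rna` and `pbody` (numeric `(z, y, x)` arrays) and
#'   `truth`: data frames `spots` (z, y, x, amplitude) and `granules`
#'   (z, y, x, molecules), the analytic per-molecule max-projection
#'   integrated intensity `unit_intensity` (`amplitude * 2 * pi * sigma_xy^2`),
#'   and the full scene.
#' @export
render_stack <- function(scene = scene_config()) {
  stopifnot(inherits(scene, "scene_config"))
  d <- scene$dim
  with_seed(scene$seed, {
    mz <- scene$margin_z; mxy <- scene$margin_xy
    if (d[1L] <= 2 * mz || d[2L] <= 2 * mxy || d[3L] <= 2 * mxy) {
      stop("stack too small for the placement margins", call. = FALSE)
    }
    # P-body loci first so cytoplasmic spots can avoid them. Distinct
    # P-bodies keep 4 blob-widths of lateral separation: overlapping
    # organelles would have merged, and stacked loci are not additive in a
    # max projection.
    gran <- if (scene$n_granules > 0L) {
      gsep <- 4 * scene$pbody_sigma
      gy <- gx <- gz <- numeric(scene$n_granules)
      placed <- 0L
      tries <- 0L
      while (placed < scene$n_granules) {
        tries <- tries + 1L
        if (tries > 500L * scene$n_granules) {
          stop("could not place ", scene$n_granules,
               " separated P-bodies in this field", call. = FALSE)
        }
        y <- stats::runif(1, mxy + 1, d[2L] - mxy)
        x <- stats::runif(1, mxy + 1, d[3L] - mxy)
        if (placed > 0L &&
            any((y - gy[seq_len(placed)])^2 +
                (x - gx[seq_len(placed)])^2 <= gsep^2)) next
        placed <- placed + 1L
        gy[placed] <- y; gx[placed] <- x
        gz[placed] <- stats::runif(1, mz + 1, d[1L] - mz)
      }
      gm <- scene$granule_molecules
      mols <- if (length(gm) == scene$n_granules && scene$n_granules != 2L) {
        as.integer(gm)  # exact per-granule contents
      } else {
        lo <- as.integer(gm[1L]); hi <- as.integer(gm[2L])
        lo + sample.int(hi - lo + 1L, scene$n_granules, replace = TRUE) - 1L
      }
      data.frame(z = gz, y = gy, x = gx, molecules = mols)
    } else data.frame(z = numeric(), y = numeric(), x = numeric(),
                      molecules = integer())

    # cytoplasmic spots, rejection-sampled away from granule neighbourhoods
    # and (by default) from each other so planted molecules are resolvable
    keep_away <- 4 * scene$pbody_sigma
    sep <- scene$min_spot_separation
    sz <- sy <- sx <- numeric(scene$n_spots)
    n_placed <- 0L
    attempts <- 0L
    while (n_placed < scene$n_spots) {
      attempts <- attempts + 1L
      if (attempts > 200L * scene$n_spots) {
        stop("could not place ", scene$n_spots, " spots with separation ",
             sep, "; reduce n_spots or min_spot_separation", call. = FALSE)
      }
      z <- stats::runif(1, mz + 1, d[1L] - mz)
      y <- stats::runif(1, mxy + 1, d[2L] - mxy)
      x <- stats::runif(1, mxy + 1, d[3L] - mxy)
      if (nrow(gran) > 0L &&
          any((y - gran$y)^2 + (x - gran$x)^2 <= keep_away^2)) next
      if (sep > 0 && n_placed > 0L) {
        i <- seq_len(n_placed)
        if (any((y - sy[i])^2 + (x - sx[i])^2 <= sep^2 &
                abs(z - sz[i]) <= 2 * scene$psf_sigma_z)) next
      }
      n_placed <- n_placed + 1L
      sz[n_placed] <- z; sy[n_placed] <- y; sx[n_placed] <- x
    }
    spots <- data.frame(z = sz, y = sy, x = sx,
                        amplitude = rep(scene$spot_amplitude, scene$n_spots))

    rna <- array(0, dim = d)
    for (i in seq_len(nrow(spots))) {
      rna <- add_gaussian3(rna, spots$z[i], spots$y[i], spots$x[i],
                           spots$amplitude[i],
                           scene$psf_sigma_xy, scene$psf_sigma_z)
    }
    for (g in seq_len(nrow(gran))) {
      for (m in seq_len(gran$molecules[g])) {
        rna <- add_gaussian3(rna,
                             gran$z[g],
                             gran$y[g] + stats::rnorm(1, 0, scene$granule_jitter_xy),
                             gran$x[g] + stats::rnorm(1, 0, scene$granule_jitter_xy),
                             scene$spot_amplitude,
                             scene$psf_sigma_xy, scene$psf_sigma_z)
      }
    }
    rna_clean <- rna
    rna <- rna + scene$background
    if (scene$poisson_noise) {
      rna <- array(stats::rpois(length(rna), rna), dim = d)
    }
    if (scene$read_noise_sd > 0) {
      rna <- rna + stats::rnorm(length(rna), 0, scene$read_noise_sd)
    }
    rna <- pmax(rna, 0)

    pb <- array(0, dim = d)
    for (g in seq_len(nrow(gran))) {
      pb <- add_gaussian3(pb, gran$z[g], gran$y[g], gran$x[g],
                          scene$pbody_amplitude,
                          scene$pbody_sigma, scene$pbody_sigma)
    }
    pb <- pb + scene$pbody_background
    if (scene$poisson_noise) {
      pb <- array(stats::rpois(length(pb), pb), dim = d)
    }

    list(rna = rna, pbody = pb,
         truth = list(spots = spots, granules = gran,
                      unit_intensity = scene$spot_amplitude *
                        2 * pi * scene$psf_sigma_xy^2,
                      rna_clean_total = sum(rna_clean),
                      scene = scene, seed = scene$seed))
  })
}

#' Write / read a (z, y, x) stack as multi-page grayscale TIFF
#'
#' Intensities are scaled by `scale` into the 32-bit float TIFF samples.
#'
#' @param stack Numeric 3D array, `(z, y, x)`.
#' @param path TIFF file path.
#' @param scale Divisor applied before writing (float TIFF expects ~[0,1]).
#' @return `path` invisibly, or the array for the reader.
#' @export
write_stack_tiff <- function(stack, path, scale = 2^16) {
  stopifnot(length(dim(stack)) == 3L)
  pages <- lapply(seq_len(dim(stack)[1L]), function(z) stack[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale = 2^16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])
  out <- array(0, dim = c(length(pages), d[1L], d[2L]))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]] * scale
  out
}
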