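# Independent oracles and fixture helpers shared across the suite.

# Classical 4th-order Runge-Kutta with fixed step h for the linear system
# d/dt y = M y. For an autonomous linear system one RK4 step is exactly
# y <- (I + hM + (hM)^2/2 + (hM)^3/6 + (hM)^4/24) y, so the whole
# integration reduces to repeated application of a constant step matrix —
# an independent numerical route to the same trajectory the closed-form
# solver computes. Times are snapped to the step grid (pass times that are
# multiples of h for exact placement).
rk4_linear <- function(k_ct, k_pb, k_r, k_l, n0, times, h = 1e-3) {
  M <- matrix(c(-(k_ct + k_r), k_r, k_l, -(k_pb + k_l)), 2)
  A <- h * M
  R <- diag(2) + A + A %*% A / 2 + A %*% A %*% A / 6 +
    A %*% A %*% A %*% A / 24
  n_steps <- round(max(times) / h)
  want <- round(times / h)
  out <- matrix(NA_real_, length(times), 2)
  y <- n0
  hit <- which(want == 0L)
  if (length(hit)) out[hit, ] <- rep(y, each = length(hit))
  for (s in seq_len(n_steps)) {
    y <- R %*% y
    hit <- which(want == s)
    if (length(hit)) out[hit, ] <- rep(as.numeric(y), each = length(hit))
  }
  list(rna_ct = out[, 1], rna_pb = out[, 2])
}

# deSolve-based RK4 at fixed step: a second, fully external integrator used
# to spot-check a few cases (slower, so not used for the big sweeps).
rk4_desolve <- function(k_ct, k_pb, k_r, k_l, n0, times, h = 1e-3) {
  rhs <- function(t, y, p) {
    list(c(-(p[1] + p[3]) * y[1] + p[4] * y[2],
           p[3] * y[1] - (p[2] + p[4]) * y[2]))
  }
  grid <- sort(unique(c(seq(0, max(times), by = h), times)))
  sol <- deSolve::rk4(n0, grid, rhs, c(k_ct, k_pb, k_r, k_l))
  idx <- match(times, sol[, 1])
  list(rna_ct = sol[idx, 2], rna_pb = sol[idx, 3])
}

# One-to-one greedy matching of detections to planted spots within a
# tolerance; returns precision/recall/F1.
match_spots <- function(truth, detected, tol_xy = 2.5, tol_z = 2) {
  if (nrow(detected) == 0L) {
    return(list(tp = 0L, fp = 0L, fn = nrow(truth),
                precision = NA_real_, recall = 0, f1 = 0))
  }
  used <- logical(nrow(detected))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected$y - truth$y[i])^2 + (detected$x - truth$x[i])^2
    ok <- which(!used & d2 <= tol_xy^2 & abs(detected$z - truth$z[i]) <= tol_z)
    if (length(ok)) {
      used[ok[which.min(d2[ok])]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- sum(!used)
  fn <- nrow(truth) - tp
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = 2 * precision * recall / (precision + recall))
}

# Small test scene: fewer spots / smaller field than the default for speed.
test_scene <- function(seed, n_spots = 50L, n_granules = 2L,
                       granule_molecules = c(15L, 25L)) {
  scene_config(dim = c(z = 12L, y = 96L, x = 96L), n_spots = n_spots,
               n_granules = n_granules,
               granule_molecules = granule_molecules,
               margin_xy = 8L, seed = seed)
}

default_params <- function() rate_params(k_ct = 0.2, k_pb = 3.0, k_r = 1.0,
                                         k_l = 0, n0_ct = 1500)
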