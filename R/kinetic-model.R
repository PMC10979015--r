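#' Kinetic rate parameters of the two-compartment decay model
#'
#' Bundles the four first-order rate constants of the compartmental model of
#' induced mRNA decay together with the initial molecule counts in each
#' compartment. RNA in the cytoplasm decays with rate `k_ct` and is recruited
#' into P-bodies with rate `k_r`; RNA inside P-bodies decays with rate `k_pb`
#' and is released back to the cytoplasm with rate `k_l`. All rates are per
#' hour; counts are continuous because they model replicate means of per-cell
#' counts, not single molecules.
#'
#' @param k_ct Cytoplasmic decay rate (per hour).
#' @param k_pb P-body decay rate (per hour).
#' @param k_r Recruitment rate, cytoplasm to P-body (per hour).
#' @param k_l Release rate, P-body to cytoplasm (per hour).
#' @param n0_ct Initial cytoplasmic RNA count (molecules).
#' @param n0_pb Initial P-body RNA count (molecules). Defaults to 0: before
#'   decay induction essentially no reporter RNA resides in P-bodies.
#' @return An object of class `rate_params`.
#' @examples
#' p <- rate_params(k_ct = 0.2, k_pb = 3, k_r = 1, k_l = 0, n0_ct = 1500)
#' @export
rate_params <- function(k_ct, k_pb, k_r, k_l, n0_ct, n0_pb = 0) {
  vals <- c(k_ct = k_ct, k_pb = k_pb, k_r = k_r, k_l = k_l,
            n0_ct = n0_ct, n0_pb = n0_pb)
  if (any(!is.finite(vals))) {
    stop("all rate parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("rates and initial counts must be nonnegative; got negative ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  }
  structure(as.list(vals), class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Two-compartment decay rates (per hour):\n")
  cat(sprintf("  k_ct = %.4g  k_pb = %.4g  k_r = %.4g  k_l = %.4g\n",
              x$k_ct, x$k_pb, x$k_r, x$k_l))
  cat(sprintf("  initial counts: cytoplasm %.4g, P-body %.4g\n",
              x$n0_ct, x$n0_pb))
  invisible(x)
}

#' Model variants of the compartmental decay model
#'
#' The four nested variants considered when fitting: the unconstrained
#' four-rate model and three mechanistically motivated three-rate scenarios.
#'
#' * `"full"` — no constraint (4 free rates).
#' * `"no_pb_decay"` — P-bodies are pure storage: `k_pb = 0`.
#' * `"equal_decay"` — decay is equally fast in both compartments:
#'   `k_pb = k_ct`.
#' * `"no_leave"` — RNA recruited into a P-body does not leave: `k_l = 0`.
#'
#' @return Character vector of the four variant tags.
#' @export
model_variants <- function() {
  c("full", "no_pb_decay", "equal_decay", "no_leave")
}

match_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1L ||
      !(variant %in% model_variants())) {
    stop("unknown model variant: ", deparse(substitute(variant)),
         " (expected one of ", paste(model_variants(), collapse = ", "), ")",
         call. = FALSE)
  }
  variant
}

#' Apply a model-variant constraint to a parameter set
#'
#' Returns a copy of `params` with the variant's equality/zero constraint
#' imposed; `"full"` returns the input unchanged. The constrained variants
#' each have three independent rate parameters, the full model four.
#'
#' @param params A [rate_params()] object.
#' @param variant One of [model_variants()].
#' @return A `rate_params` object satisfying the constraint.
#' @examples
#' p <- rate_params(0.5, 2, 1, 0.3, 100)
#' apply_variant(p, "no_leave")$k_l    # 0
#' apply_variant(p, "equal_decay")$k_pb  # 0.5
#' @export
apply_variant <- function(params, variant) {
  stopifnot(inherits(params, "rate_params"))
  variant <- match_variant(variant)
  out <- params
  switch(variant,
    full        = out,
    no_pb_decay = { out$k_pb <- 0; out },
    equal_decay = { out$k_pb <- out$k_ct; out },
    no_leave    = { out$k_l <- 0; out }
  )
}

#' Number of free rate parameters of a variant
#'
#' @param variant One of [model_variants()].
#' @return 4 for `"full"`, 3 otherwise (rates only; fitted amplitudes are
#'   counted separately by the fitting routine).
#' @export
n_free_rates <- function(variant) {
  variant <- match_variant(variant)
  if (variant == "full") 4L else 3L
}

# System matrix M of d/dt (ct, pb) = M (ct, pb).
system_matrix <- function(params) {
  matrix(c(-(params$k_ct + params$k_r), params$k_r,
           params$k_l, -(params$k_pb + params$k_l)),
         nrow = 2)
}

#' Closed-form trajectory of the two-compartment decay model
#'
#' Solves the linear system \deqn{d/dt (RNA_{CT}, RNA_{PB}) = M (RNA_{CT},
#' RNA_{PB})} analytically via the eigen-structure of the 2x2 matrix
#' \eqn{M = [[-(k_{CT}+k_R), k_L], [k_R, -(k_{PB}+k_L)]]} and evaluates the
#' solution on `times`. For nonnegative rates the discriminant
#' \eqn{(a-b)^2 + 4 k_R k_L} is nonnegative, so both eigenvalues are real;
#' the matrix exponential is assembled from the spectral projectors, and the
#' (measure-zero) repeated-eigenvalue case is detected numerically and
#' handled by the defective-matrix limit \eqn{e^{Mt} = e^{\lambda t}(I + t(M -
#' \lambda I))}.
#'
#' @param params A [rate_params()] object.
#' @param times Nonnegative, nondecreasing time grid in hours.
#' @return A `trajectory` object: a data frame with columns `time_h`,
#'   `rna_ct`, `rna_pb`.
#' @examples
#' p <- rate_params(k_ct = log(2), k_pb = 0, k_r = 0, k_l = 0, n0_ct = 100)
#' solve_trajectory(p, c(0, 1))$rna_ct  # 100, 50
#' @export
solve_trajectory <- function(params, times) {
  stopifnot(inherits(params, "rate_params"))
  times <- as.numeric(times)
  if (length(times) == 0L || any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and nonnegative", call. = FALSE)
  }
  if (is.unsorted(times)) {
    stop("times must be ascending", call. = FALSE)
  }

  M <- system_matrix(params)
  a <- params$k_ct + params$k_r
  b <- params$k_pb + params$k_l
  disc <- (a - b)^2 + 4 * params$k_r * params$k_l
  s <- sqrt(max(disc, 0))
  lam1 <- (-(a + b) + s) / 2
  lam2 <- (-(a + b) - s) / 2
  n0 <- c(params$n0_ct, params$n0_pb)

  tol <- 1e-12 * max(abs(lam1), abs(lam2), 1)
  if (abs(lam1 - lam2) < tol) {
    # defective (or scalar) case: exp(Mt) = e^{lam t} (I + t (M - lam I))
    lam <- (lam1 + lam2) / 2
    N <- M - diag(lam, 2)
    sol <- vapply(times, function(t) {
      exp(lam * t) * ((diag(2) + t * N) %*% n0)
    }, numeric(2))
  } else {
    # spectral projectors: P1 = (M - lam2 I)/(lam1 - lam2), P2 = I - P1
    P1 <- (M - diag(lam2, 2)) / (lam1 - lam2)
    P2 <- diag(2) - P1
    v1 <- P1 %*% n0
    v2 <- P2 %*% n0
    sol <- vapply(times, function(t) {
      as.numeric(exp(lam1 * t) * v1 + exp(lam2 * t) * v2)
    }, numeric(2))
  }

  out <- data.frame(time_h = times,
                    rna_ct = pmax(sol[1, ], 0),
                    rna_pb = pmax(sol[2, ], 0))
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Half-life of a first-order decay rate
#'
#' @param rate Decay rate (per hour), strictly positive.
#' @return Half-life in hours, `log(2) / rate`.
#' @examples
#' half_life(log(2))  # 1
#' @export
half_life <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate <= 0)) {
    stop("rate must be strictly positive", call. = FALSE)
  }
  log(2) / rate
}

#' Write a trajectory to CSV
#'
#' @param trajectory A `trajectory` from [solve_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
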