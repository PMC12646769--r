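#' Maximum-likelihood fit of a gamma distribution
#'
#' Newton iteration on the shape profile likelihood (digamma equation),
#' started from the Choi-Wette closed-form approximation. Used for 5-min
#' step-length kernels and for the HMM's weighted M-step (via `w`).
#'
#' @param x positive observations.
#' @param w optional non-negative weights.
#' @return List with `shape`, `scale` and `n` (effective sample size).
#' @export
fit_gamma_mle <- function(x, w = NULL) {
  if (any(x <= 0)) stop("gamma observations must be positive")
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  mx <- sum(w * x) / sw
  mlx <- sum(w * log(x)) / sw
  s <- log(mx) - mlx
  if (s < 1e-12) stop("degenerate sample: all values (effectively) equal")
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-12 * k) { k <- k_new; break }
    k <- k_new
  }
  list(shape = k, scale = mx / k, n = sw)
}

#' Maximum-likelihood fit of a von Mises distribution
#'
#' Mean direction from the resultant vector; concentration from the
#' standard piecewise inversion of `A1(kappa) = I1/I0` (Fisher 1993).
#'
#' @param theta angles in radians.
#' @param w optional non-negative weights.
#' @param fix_mu if `TRUE`, constrain the mean direction to 0 (common in
#'   step-selection kernels); the concentration is then fitted to
#'   `mean(cos(theta))`.
#' @return List with `mu` (in `(-pi, pi]`), `kappa` and `n`.
#' @export
fit_vonmises_mle <- function(theta, w = NULL, fix_mu = FALSE) {
  if (is.null(w)) w <- rep(1, length(theta))
  sw <- sum(w)
  if (fix_mu) {
    mu <- 0
    rbar <- sum(w * cos(theta)) / sw
    rbar <- max(rbar, 0)
  } else {
    C <- sum(w * cos(theta)) / sw
    S <- sum(w * sin(theta)) / sw
    mu <- atan2(S, C)
    rbar <- sqrt(C^2 + S^2)
  }
  kappa <- a1inv(rbar)
  list(mu = mu, kappa = kappa, n = sw)
}

# Inverse of A1(kappa) = I1(kappa)/I0(kappa), Fisher's approximation.
a1inv <- function(r) {
  if (r >= 1) return(1e6)
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Fit per-individual, per-stage movement kernels
#'
#' For each (individual, movement stage) with at least `min_n` retained
#' steps, fits a gamma distribution to step lengths and a von Mises
#' distribution to turning angles (angles only exist for steps whose
#' predecessor was retained). Keys below the floor fall back to the
#' stage-pooled fit across individuals and are flagged.
#'
#' @param steps retained-step table from [discretize_5min()] (rows from
#'   several individuals may be concatenated).
#' @param min_n minimum steps per (individual, stage) key.
#' @param fix_mu passed to [fit_vonmises_mle()].
#' @return A data.frame keyed by `individual`, `stage`: `shape`, `scale`,
#'   `mu`, `kappa`, `n_steps`, `n_angles`, `pooled` (fallback flag).
#' @export
fit_step_distributions <- function(steps, min_n = 30, fix_mu = FALSE) {
  stopifnot(nrow(steps) > 0)
  key <- interaction(steps$individual, steps$stage, drop = TRUE)
  pooled <- lapply(split(steps, steps$stage), function(ss) {
    fit_key_dist(ss, fix_mu)
  })
  out <- lapply(levels(key), function(kk) {
    ss <- steps[key == kk, , drop = FALSE]
    id <- ss$individual[1]; st <- ss$stage[1]
    if (nrow(ss) >= min_n) {
      f <- fit_key_dist(ss, fix_mu)
      data.frame(individual = id, stage = st, shape = f$shape,
                 scale = f$scale, mu = f$mu, kappa = f$kappa,
                 n_steps = nrow(ss), n_angles = f$n_angles, pooled = FALSE)
    } else {
      f <- pooled[[st]]
      data.frame(individual = id, stage = st, shape = f$shape,
                 scale = f$scale, mu = f$mu, kappa = f$kappa,
                 n_steps = nrow(ss), n_angles = f$n_angles, pooled = TRUE)
    }
  })
  do.call(rbind, out)
}

fit_key_dist <- function(ss, fix_mu) {
  g <- fit_gamma_mle(ss$L)
  ang <- ss$turn_angle[!is.na(ss$turn_angle)]
  if (length(ang) >= 5) {
    v <- fit_vonmises_mle(ang, fix_mu = fix_mu)
  } else {
    v <- list(mu = 0, kappa = 1e-8)  # too few angles: uniform kernel
  }
  list(shape = g$shape, scale = g$scale, mu = v$mu, kappa = v$kappa,
       n_angles = length(ang))
}
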