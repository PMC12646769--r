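# Shared fixtures, all generated in code (no stored data).

# Small default landscape for fast tests.
test_landscape <- function(seed = 1, n_cells = 150, ...) {
  generate_landscape(landscape_config(n_cells = n_cells, res = 10,
                                      seed = seed, ...))
}

# A uniform landscape: all scrub, no roads/water, flat DEM. With beta = 0
# every candidate is equivalent, so selection must be uniform.
uniform_landscape <- function(n_cells = 150, seed = 1) {
  generate_landscape(landscape_config(
    n_cells = n_cells, res = 10, seed = seed,
    class_weights = c(scrub = 1 - 3e-9, glade = 1e-9, bare = 1e-9,
                      blackcotton = 1e-9),
    n_roads = 0, water_halfwidth = 0, riverine_halfwidth = 0,
    dem_amplitude = 0))
}

# Hand-built 1 Hz track: constant speed along +x, starting at (x0, y0).
straight_track <- function(v = 0.5, seconds = 3600, x0 = 500, y0 = 500,
                           id = "toy", t0 = 6 * 3600) {
  tr <- data.frame(individual = id, t = t0 + 0:seconds,
                   x = x0 + v * (0:seconds), y = y0,
                   res_flag = "hi", day = 1, stage = "resident")
  class(tr) <- c("sc_track", "data.frame")
  tr
}

# Track from explicit per-fix coordinates (1 Hz).
track_from_xy <- function(x, y, id = "toy", t0 = 6 * 3600) {
  tr <- data.frame(individual = id, t = t0 + seq_along(x) - 1,
                   x = x, y = y, res_flag = "hi", day = 1,
                   stage = "resident")
  class(tr) <- c("sc_track", "data.frame")
  tr
}

# Simulated matched case-control strata with known coefficients, built
# directly (independent of the landscape machinery): n_strata strata of
# 1 + m steps with standard-normal / binary covariates; the case is drawn
# with probability proportional to exp(beta' x).
simulate_strata <- function(n_strata, beta, m = 20, seed = 1,
                            binary = TRUE) {
  p <- length(beta)
  withr_seed <- function(code) stepcot:::with_seed(seed, code)
  withr_seed({
    n <- n_strata * (m + 1)
    X <- matrix(stats::rnorm(n), ncol = 1)
    if (p > 1) {
      more <- if (binary) {
        matrix(stats::rbinom(n * (p - 1), 1, 0.3), ncol = p - 1)
      } else {
        matrix(stats::rnorm(n * (p - 1)), ncol = p - 1)
      }
      X <- cbind(X, more)
    }
    colnames(X) <- paste0("x", seq_len(p))
    sid <- rep(seq_len(n_strata), each = m + 1)
    case <- numeric(n)
    for (s in seq_len(n_strata)) {
      idx <- which(sid == s)
      w <- exp(X[idx, , drop = FALSE] %*% beta)
      case[idx[sample.int(m + 1, 1, prob = w)]] <- 1
    }
    list(X = X, case = case, stratum = sid)
  })
}

# Independent oracle for the conditional likelihood: direct evaluation of
# the log conditional likelihood, used for brute-force grid maximisation.
clr_loglik_oracle <- function(beta, X, case, stratum) {
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (s in unique(stratum)) {
    idx <- stratum == s
    ll <- ll + eta[idx][case[idx] == 1] - log(sum(exp(eta[idx])))
  }
  ll
}

# Build a 1 Hz track with a planted stationary/moving regime switch at the
# 10 s window scale. The moving regime mixes three persistent travel
# speeds (~5, 10 and 18 m per window) — the multi-speed structure that
# motivates a 4-state model (one stationary plus three moving states) in
# this kind of tracking data; the stationary regime creeps ~0.5 m per
# window.
two_regime_track <- function(n_windows = 800, p_switch = 0.05, seed = 21) {
  stepcot:::with_seed(seed, {
    state <- integer(n_windows)
    state[1] <- 1
    for (i in 2:n_windows) {
      state[i] <- if (runif(1) < p_switch) 3 - state[i - 1] else state[i - 1]
    }
    sub <- sample(c(5, 10, 18), n_windows, replace = TRUE)
    for (i in 2:n_windows) if (runif(1) < 0.8) sub[i] <- sub[i - 1]
    head <- cumsum(rnorm(n_windows, 0, 0.3))
    win_len <- ifelse(state == 2,
                      rgamma(n_windows, 25, scale = sub / 25),
                      rgamma(n_windows, 100, scale = 0.005))
    dx <- win_len * sin(head); dy <- win_len * cos(head)
    x <- rep(cumsum(c(0, dx[-n_windows])), each = 10) +
      rep(dx / 10, each = 10) * rep(1:10, n_windows)
    y <- rep(cumsum(c(0, dy[-n_windows])), each = 10) +
      rep(dy / 10, each = 10) * rep(1:10, n_windows)
    list(track = track_from_xy(c(0, x), c(0, y)), state = state)
  })
}

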