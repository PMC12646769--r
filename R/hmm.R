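#' Build the 10-second step series used by the movement HMM
#'
#' Resamples the 1 Hz portion of a track to one position every 10 s
#' (within each contiguous 1 Hz run) and computes step lengths and turning
#' angles between consecutive resampled positions. Step lengths are
#' floored at 0.05 m so that perfectly stationary stretches remain inside
#' the gamma support.
#'
#' @param track an `"sc_track"`.
#' @param window resampling interval (s).
#' @return A data.frame: `run` (contiguous-series id), `len` (m), `angle`
#'   (radians, `NA` where undefined), `i_from`, `i_to` (row indices into
#'   the hi-res subset, attribute `"hires"`).
#' @export
hmm_steps <- function(track, window = 10) {
  hi <- track[track$res_flag == "hi", , drop = FALSE]
  rownames(hi) <- NULL
  if (nrow(hi) < 3 * window) stop("not enough 1 Hz data for HMM steps")
  brk <- c(0, which(diff(hi$t) != 1), nrow(hi))
  parts <- list()
  for (s in seq_len(length(brk) - 1)) {
    lo <- brk[s] + 1; up <- brk[s + 1]
    idx <- seq(lo, up, by = window)
    if (length(idx) < 3) next
    dx <- diff(hi$x[idx]); dy <- diff(hi$y[idx])
    len <- pmax(sqrt(dx^2 + dy^2), 0.05)
    bearing <- atan2(dx, dy)
    ang <- c(NA, diff(bearing))
    ang <- ((ang + pi) %% (2 * pi)) - pi
    ang[c(TRUE, len[-length(len)] < 0.5) | len < 0.5] <- NA  # angle needs movement
    parts[[length(parts) + 1]] <- data.frame(
      run = s, len = len, angle = ang,
      i_from = idx[-length(idx)], i_to = idx[-1])
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "hires") <- hi
  out
}

# log emission matrix (T x K) for gamma length + von Mises angle emissions
hmm_log_emission <- function(obs, par) {
  K <- length(par$shape)
  le <- matrix(0, nrow(obs), K)
  for (k in seq_len(K)) {
    le[, k] <- stats::dgamma(obs$len, shape = par$shape[k],
                             scale = par$scale[k], log = TRUE)
    ok <- !is.na(obs$angle)
    if (any(ok)) {
      kap <- par$kappa[k]
      l_i0 <- log(besselI(kap, 0, expon.scaled = TRUE)) + kap
      le[ok, k] <- le[ok, k] +
        kap * cos(obs$angle[ok] - par$mu[k]) - log(2 * pi) - l_i0
    }
  }
  le
}

# scaled forward-backward over independent runs; returns gamma (posterior),
# xi-sums (transition expectations) and the total log likelihood
hmm_fb <- function(le, runs, trans, init) {
  K <- ncol(le)
  n <- nrow(le)
  em <- exp(le - apply(le, 1, max))
  scal_log <- apply(le, 1, max)
  alpha <- matrix(0, n, K); beta <- matrix(0, n, K)
  cvec <- numeric(n)
  ll <- 0
  for (r in unique(runs)) {
    idx <- which(runs == r)
    a <- init * em[idx[1], ]
    cvec[idx[1]] <- sum(a)
    alpha[idx[1], ] <- a / cvec[idx[1]]
    for (t in idx[-1]) {
      a <- (alpha[t - 1, ] %*% trans) * em[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
    b <- rep(1, K)
    beta[idx[length(idx)], ] <- b
    for (t in rev(idx[-length(idx)])) {
      b <- trans %*% (em[t + 1, ] * beta[t + 1, ]) / cvec[t + 1]
      beta[t, ] <- b
    }
    ll <- ll + sum(log(cvec[idx])) + sum(scal_log[idx])
  }
  g <- alpha * beta
  g <- g / rowSums(g)
  # transition expectations over within-run consecutive pairs
  xi <- matrix(0, K, K)
  for (r in unique(runs)) {
    idx <- which(runs == r)
    if (length(idx) < 2) next
    t1 <- idx[-length(idx)]; t2 <- idx[-1]
    for (k in seq_len(K)) {
      for (l in seq_len(K)) {
        xi[k, l] <- xi[k, l] +
          sum(alpha[t1, k] * trans[k, l] * em[t2, l] * beta[t2, l] /
                cvec[t2])
      }
    }
  }
  list(gamma = g, xi = xi, loglik = ll)
}

#' Fit a 4-state movement hidden Markov model
#'
#' EM-fits a hidden Markov model to 10 s step lengths (gamma emissions)
#' and turning angles (von Mises emissions) of the 1 Hz track, then
#' relabels states in ascending order of mean step length, so state 1 is
#' the most stationary and states 2-4 are "moving". Several seeded random
#' starts are pre-iterated briefly and the best continued to convergence.
#' Each 1 Hz second inherits the Viterbi state of the 10 s window that
#' contains it.
#'
#' @param track an `"sc_track"` with 1 Hz data.
#' @param n_states number of states.
#' @param seed RNG seed for the random starts.
#' @param window emission window (s).
#' @param n_starts random starts.
#' @param max_iter EM iteration cap per start.
#' @param tol EM convergence threshold on the log-likelihood change.
#' @param max_fit_steps at most this many 10 s steps are used to estimate
#'   parameters (a leading contiguous block); decoding always uses all
#'   steps. Keeps EM cost bounded on long tracks.
#' @return An object of class `"sc_hmm"`: per-state `shape`, `scale`,
#'   `mu`, `kappa`, `trans`, `init`, `loglik`, `states` (per 10 s step),
#'   `moving` (per step), `second_state` and `second_moving` (per hi-res
#'   fix), `steps` (the step table), `converged`.
#' @export
fit_hmm <- function(track, n_states = 4, seed = 1L, window = 10,
                    n_starts = 5, max_iter = 100, tol = 1e-6,
                    max_fit_steps = 20000) {
  obs <- hmm_steps(track, window)
  if (nrow(obs) < 500) {
    stop("need at least 500 ten-second steps to fit the movement HMM (have ",
         nrow(obs), ")")
  }
  K <- n_states
  fit_obs <- if (nrow(obs) > max_fit_steps) {
    obs[seq_len(max_fit_steps), , drop = FALSE]
  } else obs

  with_seed(seed, {
    starts <- lapply(seq_len(n_starts), function(s) hmm_init(fit_obs, K))
    # short pre-EM on every start, keep the best
    pre <- lapply(starts, function(p) hmm_em(fit_obs, p, max_iter = 10,
                                             tol = tol))
    best <- pre[[which.max(vapply(pre, `[[`, 0, "loglik"))]]
    fit <- hmm_em(fit_obs, best$par, max_iter = max_iter, tol = tol)
  })

  # decode once, then relabel ascending by mean step length; exact ties
  # (degenerate identical states) are broken by decoded occupancy so the
  # dominant stationary state always carries label 1
  states0 <- hmm_viterbi(obs, fit$par)
  occ <- tabulate(states0, K)
  mu_len <- fit$par$shape * fit$par$scale
  o <- order(round(mu_len, 9), -occ)
  par <- list(shape = fit$par$shape[o], scale = fit$par$scale[o],
              mu = fit$par$mu[o], kappa = fit$par$kappa[o])
  trans <- fit$par$trans[o, o, drop = FALSE]
  init <- fit$par$init[o]
  par$trans <- trans; par$init <- init

  perm <- match(seq_len(K), o)     # old label -> new label
  states <- perm[states0]
  moving <- states >= 2

  # each 1 Hz second inherits its window's state
  hi <- attr(obs, "hires")
  sec_state <- rep(NA_integer_, nrow(hi))
  for (i in seq_len(nrow(obs))) {
    sec_state[obs$i_from[i]:obs$i_to[i]] <- states[i]
  }
  # trailing partial windows inherit the last decoded state of their run
  na_idx <- which(is.na(sec_state))
  if (length(na_idx)) {
    last <- cummax(ifelse(is.na(sec_state), 0, seq_along(sec_state)))
    ok <- last[na_idx] > 0
    sec_state[na_idx[ok]] <- sec_state[last[na_idx[ok]]]
  }

  structure(list(
    shape = par$shape, scale = par$scale, mu = par$mu, kappa = par$kappa,
    trans = trans, init = init,
    loglik = fit$loglik, converged = fit$converged,
    n_fit_steps = nrow(fit_obs),
    states = states, moving = moving,
    second_state = sec_state, second_moving = sec_state >= 2,
    steps = obs, window = window
  ), class = "sc_hmm")
}

hmm_init <- function(obs, K) {
  # random quantile anchors: different starts explore different
  # allocations of states to the length distribution (e.g. 1 slow + 3
  # fast vs 2 + 2); the best pre-EM log likelihood picks the basin
  qs <- stats::quantile(obs$len, probs = sort(stats::runif(K, 0.02, 0.98)))
  mns <- as.numeric(qs) * exp(stats::rnorm(K, 0, 0.2))
  shp <- rep(1.5, K)
  list(shape = shp, scale = mns / shp,
       mu = rep(0, K), kappa = stats::runif(K, 0.2, 1),
       trans = matrix(0.1 / (K - 1), K, K) + diag(0.9 - 0.1 / (K - 1), K),
       init = rep(1 / K, K))
}

hmm_em <- function(obs, par, max_iter = 100, tol = 1e-6) {
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    le <- hmm_log_emission(obs, par)
    fb <- hmm_fb(le, obs$run, par$trans, par$init)
    g <- fb$gamma
    K <- ncol(g)
    for (k in seq_len(K)) {
      w <- g[, k]
      # a state can concentrate on the floored (constant) stationary
      # lengths; represent it as a sharply peaked gamma instead of failing
      gm <- tryCatch(fit_gamma_mle(obs$len, w = w), error = function(e) {
        mx <- sum(w * obs$len) / sum(w)
        list(shape = 100, scale = mx / 100)
      })
      par$shape[k] <- gm$shape; par$scale[k] <- gm$scale
      ok <- !is.na(obs$angle)
      if (sum(w[ok]) > 1e-6) {
        vm <- fit_vonmises_mle(obs$angle[ok], w = w[ok])
        par$mu[k] <- vm$mu
        par$kappa[k] <- min(vm$kappa, 50)  # cap against degenerate spikes
      }
    }
    tr <- fb$xi
    par$trans <- tr / pmax(rowSums(tr), 1e-300)
    firsts <- which(!duplicated(obs$run))
    par$init <- colMeans(g[firsts, , drop = FALSE])
    if (abs(fb$loglik - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- fb$loglik
      break
    }
    ll_old <- fb$loglik
  }
  list(par = par, loglik = ll_old, converged = converged, iterations = it)
}

hmm_viterbi <- function(obs, par) {
  le <- hmm_log_emission(obs, par)
  K <- ncol(le)
  lt <- log(pmax(par$trans, 1e-300))
  li <- log(pmax(par$init, 1e-300))
  states <- integer(nrow(obs))
  for (r in unique(obs$run)) {
    idx <- which(obs$run == r)
    n <- length(idx)
    delta <- matrix(-Inf, n, K)
    psi <- matrix(0L, n, K)
    delta[1, ] <- li + le[idx[1], ]
    if (n > 1) for (t in 2:n) {
      for (k in seq_len(K)) {
        v <- delta[t - 1, ] + lt[, k]
        psi[t, k] <- which.max(v)
        delta[t, k] <- v[psi[t, k]] + le[idx[t], k]
      }
    }
    s <- integer(n)
    s[n] <- which.max(delta[n, ])
    if (n > 1) for (t in (n - 1):1) s[t] <- psi[t + 1, s[t + 1]]
    states[idx] <- s
  }
  states
}

#' @export
print.sc_hmm <- function(x, ...) {
  cat(sprintf("<sc_hmm> %d states, loglik %.2f (%s), %d steps decoded\n",
              length(x$shape), x$loglik,
              if (x$converged) "converged" else "not converged",
              length(x$states)))
  print(data.frame(state = seq_along(x$shape),
                   mean_len = x$shape * x$scale,
                   shape = x$shape, scale = x$scale, kappa = x$kappa,
                   occupancy = as.vector(table(factor(
                     x$states, levels = seq_along(x$shape)))) /
                     length(x$states)))
  invisible(x)
}
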