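#' Conditional logistic regression for matched case-control strata
#'
#' Maximises the stratified conditional likelihood
#' `prod_strata exp(b'x_case) / sum_j exp(b'x_j)` — the exact partial
#' likelihood a stratified Cox model would use with one event per stratum,
#' which is why step-selection analyses are conventionally fitted through a
#' Cox routine. Here it is fitted directly by Newton-Raphson with analytic
#' gradient and Hessian, starting from `beta = 0`, with step-halving; the
#' conditional log likelihood is concave, so iterates increase it
#' monotonically.
#'
#' Covariates that are constant within every stratum carry no information
#' (they cancel from the likelihood) and make the problem rank-deficient;
#' such aliased columns raise an error naming them. Perfect separation (a
#' covariate that always distinguishes the case) makes the MLE infinite;
#' this is detected when `max(abs(beta))` exceeds `diverge_bound` and the
#' fit is returned with `converged = FALSE` and `diverged = TRUE`.
#'
#' @param X numeric design matrix (rows = steps).
#' @param case logical or 0/1: exactly one case per stratum.
#' @param stratum stratum id per row.
#' @param tol_score convergence threshold on `max(abs(score))`.
#' @param tol_loglik convergence threshold on the log-likelihood change.
#' @param max_iter Newton iteration cap.
#' @param diverge_bound coefficient magnitude treated as divergence.
#' @return An object of class `"sc_clr_fit"`: `coef`, `se`, `vcov`
#'   (inverse observed information), `loglik`, `loglik_null`, `iterations`,
#'   `converged`, `diverged`, `score_norm`, `n_strata`.
#' @export
fit_clr <- function(X, case, stratum, tol_score = 1e-8, tol_loglik = 1e-10,
                    max_iter = 50L, diverge_bound = 15) {
  X <- as.matrix(X)
  case <- as.numeric(case)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sid <- as.integer(factor(stratum))
  ns <- max(sid)
  if (ns < 1) stop("need at least one stratum")
  tab <- rowsum(case, sid)
  if (any(tab != 1)) {
    stop("every stratum must contain exactly one case; stratum ",
         which(tab != 1)[1], " has ", tab[which(tab != 1)[1]])
  }
  # within-stratum centring exposes aliased (stratum-constant) columns
  Xc <- X - rowsum(X, sid)[sid, , drop = FALSE] /
    as.vector(table(sid))[sid]
  qr_d <- qr(Xc)
  if (qr_d$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qr_d$pivot[seq_len(qr_d$rank)])]
    stop("design is rank deficient after within-stratum centring; ",
         "aliased column(s): ", paste(bad, collapse = ", "))
  }

  p <- ncol(X)
  beta <- rep(0, p)
  ll_fun <- function(b) {
    eta <- as.vector(X %*% b)
    mx <- tapply_max(eta, sid, ns)
    w <- exp(eta - mx[sid])
    denom <- as.vector(rowsum(w, sid))
    list(ll = sum(eta[case == 1]) - sum(log(denom) + mx),
         w = w, denom = denom, eta = eta)
  }
  st <- ll_fun(beta)
  ll <- st$ll
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  score <- rep(NA_real_, p)
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    prob <- st$w / st$denom[sid]
    resid <- case - prob
    score <- as.vector(crossprod(X, resid))
    Sx <- rowsum(prob * X, sid)                 # per-stratum E[x]
    H <- crossprod(X, prob * X) - crossprod(Sx) # observed information
    if (max(abs(score)) < tol_score) { converged <- TRUE; break }
    delta <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(delta)) {
      delta <- solve(H + diag(1e-8, p), score)
    }
    # step-halving line search: concavity guarantees eventual ascent
    stepsize <- 1
    repeat {
      cand <- beta + stepsize * delta
      st_new <- ll_fun(cand)
      if (st_new$ll >= ll - 1e-12) break
      stepsize <- stepsize / 2
      if (stepsize < 1e-10) break
    }
    beta <- beta + stepsize * delta
    if (max(abs(beta)) > diverge_bound) {
      diverged <- TRUE
      st <- st_new
      break
    }
    dll <- st_new$ll - ll
    st <- st_new
    ll <- st$ll
    if (abs(dll) < tol_loglik) { converged <- TRUE }
    if (converged) {
      # recompute the score at the final beta for the report
      prob <- st$w / st$denom[sid]
      score <- as.vector(crossprod(X, case - prob))
      Sx <- rowsum(prob * X, sid)
      H <- crossprod(X, prob * X) - crossprod(Sx)
      break
    }
  }
  if (converged && max(abs(score)) >= 1e-4) converged <- FALSE
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  names(beta) <- colnames(X)
  fit <- list(coef = beta,
              se = sqrt(pmax(diag(vc), 0)),
              vcov = vc,
              loglik = ll,
              loglik_null = -sum(log(as.vector(table(sid)))),
              iterations = iter,
              converged = converged && !diverged,
              diverged = diverged,
              score_norm = max(abs(score)),
              n_strata = ns,
              terms = colnames(X))
  class(fit) <- "sc_clr_fit"
  if (diverged) {
    warning("conditional logistic fit diverged (possible separation); ",
            "coefficient bound ", diverge_bound, " exceeded")
  }
  fit
}

# max of v by group, groups must be 1..ns
tapply_max <- function(v, sid, ns) {
  out <- rep(-Inf, ns)
  o <- order(sid, v)
  # last element of each group after ordering is its max
  idx <- o[c(which(diff(sid[o]) != 0), length(o))]
  out[sid[idx]] <- v[idx]
  out
}

#' @export
print.sc_clr_fit <- function(x, ...) {
  cat(sprintf("<sc_clr_fit> %d strata, loglik %.4f, %s in %d iter\n",
              x$n_strata, x$loglik,
              if (x$converged) "converged" else
                if (x$diverged) "DIVERGED" else "NOT converged",
              x$iterations))
  print(data.frame(coef = x$coef, se = x$se))
  invisible(x)
}

#' Relative selection strength report for a conditional logistic fit
#'
#' Per model term: the relative selection strength `RSS = exp(beta)` (the
#' relative probability of choosing a location with the feature over the
#' reference, given equal availability), its log, a Wald confidence
#' interval, z statistic, p value and significance stars.
#'
#' @param fit an `"sc_clr_fit"`.
#' @param conf confidence level.
#' @return A data.frame with one row per term: `term`, `estimate`, `se`,
#'   `z`, `p`, `rss`, `log_rss`, `rss_lo`, `rss_hi`, `stars`.
#' @export
rss_report <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "sc_clr_fit"))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  z <- fit$coef / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  stars <- symnum(p, corr = FALSE, na = FALSE,
                  cutpoints = c(0, 0.001, 0.01, 0.05, 1),
                  symbols = c("***", "**", "*", ""))
  data.frame(
    term = names(fit$coef),
    estimate = unname(fit$coef),
    se = unname(fit$se),
    z = unname(z),
    p = unname(p),
    rss = exp(unname(fit$coef)),
    log_rss = unname(fit$coef),
    rss_lo = exp(unname(fit$coef - zq * fit$se)),
    rss_hi = exp(unname(fit$coef + zq * fit$se)),
    stars = as.character(stars),
    row.names = NULL
  )
}
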