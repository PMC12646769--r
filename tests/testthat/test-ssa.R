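make_step <- function(x_end = 120, y_end = 100, turn = 0) {
  data.frame(individual = "b1", step_id = 5, t_start = 0, t_end = 300,
             x_start = 100, y_start = 100, x_end = x_end, y_end = y_end,
             L = sqrt((x_end - 100)^2 + (y_end - 100)^2),
             bearing = atan2(x_end - 100, y_end - 100),
             turn_angle = turn, stage = "active_dispersal", day = 1)
}

test_that("a stratum holds m alternatives plus exactly one case", {
  d <- data.frame(shape = 2, scale = 30, mu = 0, kappa = 1.5)
  s <- stepcot:::with_seed(1, generate_alternatives(make_step(), d, m = 20))
  expect_equal(nrow(s), 21)
  expect_equal(sum(s$is_case), 1)
  expect_equal(s$is_case[1], 1L)
  expect_error(generate_alternatives(make_step(), d, m = 0), "positive")
})

test_that("concentrated kernels cluster alternatives at the observed geometry", {
  d <- data.frame(shape = 2e6, scale = 1e-5, mu = 0, kappa = 5e5)
  # gamma mean 20 m (tiny CV), kappa huge: every alternative ~ 20 m ahead
  st <- make_step(x_end = 120, y_end = 100, turn = 0)  # bearing due east
  s <- stepcot:::with_seed(2, generate_alternatives(st, d, m = 50))
  alt <- s[s$is_case == 0, ]
  expect_true(all(abs(alt$x - 120) < 1))
  expect_true(all(abs(alt$y - 100) < 1))
})

test_that("alternative lengths follow the fitted gamma (two-sample KS)", {
  d <- data.frame(shape = 2, scale = 30, mu = 0, kappa = 1.5)
  st <- make_step()
  s <- stepcot:::with_seed(13, {
    do.call(rbind, lapply(1:200, function(i) generate_alternatives(st, d, 50)))
  })
  lens <- s$L[s$is_case == 0]
  ref <- stepcot:::with_seed(14, rgamma(10000, 2, scale = 30))
  ks <- suppressWarnings(stats::ks.test(lens, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("steps without a previous bearing sample uniform directions", {
  d <- data.frame(shape = 2, scale = 30, mu = 0, kappa = 50)
  st <- make_step(turn = NA)
  s <- stepcot:::with_seed(3, generate_alternatives(st, d, m = 2000))
  expect_equal(unique(s$angle_class), "uniform")
  ang <- atan2(s$x[-1] - 100, s$y[-1] - 100)
  expect_gt(suppressWarnings(
    stats::chisq.test(table(cut(ang, seq(-pi, pi, length.out = 9))))$p.value),
    0.01)
})

test_that("post-hoc habitat filter removes strata by case and steps by class", {
  base <- data.frame(
    stratum_id = rep(1:3, each = 4),
    is_case = rep(c(1, 0, 0, 0), 3),
    cover = c("scrub", "glade", "bare", "scrub",       # alt on bare
              "bare", "scrub", "scrub", "glade",       # case on bare
              "scrub", "scrub", "glade", "glade"),     # untouched
    stage = "resident", individual = "b")
  class(base) <- c("sc_strata", "data.frame")
  out <- filter_habitat_posthoc(base, drop_classes = c("blackcotton", "bare"))
  expect_setequal(unique(out$stratum_id), c(1, 3))
  expect_equal(sum(out$stratum_id == 1), 3)   # lost one alternative
  expect_equal(sum(out$stratum_id == 3), 4)
  lg <- attr(out, "filter_log")
  expect_equal(lg$strata_dropped_by_case, 1)
  # no dropped classes present: identity
  clean <- base[base$cover %in% c("scrub", "glade"), ]
  class(clean) <- c("sc_strata", "data.frame")
  expect_equal(nrow(filter_habitat_posthoc(clean)), nrow(clean))
})

test_that("design variants have the documented column counts", {
  set.seed(8)
  n <- 60
  strata <- data.frame(
    stratum_id = rep(1:(n / 3), each = 3),
    is_case = rep(c(1, 0, 0), n / 3),
    road = rbinom(n, 1, 0.5), water = rbinom(n, 1, 0.5),
    glade = rbinom(n, 1, 0.5), riverine = rbinom(n, 1, 0.5),
    tri_z = rnorm(n),
    stage = rep(c("resident", "local_transience", "active_dispersal"),
                each = n / 3),
    individual = "b")
  co <- c("road", "water", "glade", "riverine")
  expect_equal(ncol(build_design(strata, "within_stage", co)$X), 12)
  expect_equal(ncol(build_design(strata, "vs_resident", co)$X), 12)
  expect_equal(ncol(build_design(strata, "two_level", co)$X), 8)
  expect_error(build_design(transform(strata, stage = "zig"), "two_level"),
               "stage")
})

test_that("two-stratum toy problem has the closed-form solution ln 2", {
  X <- matrix(c(1, 0, 0, 0, 1, 0), ncol = 1,
              dimnames = list(NULL, "x"))
  fit <- fit_clr(X, case = c(1, 0, 0, 1, 0, 0), stratum = rep(1:2, each = 3))
  expect_equal(unname(fit$coef), log(2), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-6)
})

test_that("stratum-constant covariates are rejected as rank deficient", {
  X <- matrix(rep(c(1, 2), each = 3), ncol = 1)
  expect_error(fit_clr(X, c(1, 0, 0, 1, 0, 0), rep(1:2, each = 3)),
               "rank deficient")
})

test_that("every stratum must have exactly one case", {
  X <- matrix(rnorm(6), ncol = 1)
  expect_error(fit_clr(X, c(1, 1, 0, 1, 0, 0), rep(1:2, each = 3)),
               "exactly one case")
})

test_that("fit matches brute-force likelihood search on tiny instances", {
  checked <- 0
  for (seed in c(5, 6, 8, 10, 11)) {
    # continuous covariates: tiny matched sets separate too easily on
    # binary ones, and a divergent MLE has no finite grid optimum
    sim <- simulate_strata(3, beta = c(0.4, -0.3), m = 4, seed = seed,
                           binary = FALSE)
    fit <- suppressWarnings(fit_clr(sim$X, sim$case, sim$stratum))
    if (fit$diverged) next  # no finite optimum to compare against
    checked <- checked + 1
    # oracle: grid search over the conditional log likelihood
    grid <- seq(-8, 8, by = 1e-3)
    prof <- function(dim) {
      vapply(grid, function(b) {
        bb <- fit$coef; bb[dim] <- b
        clr_loglik_oracle(bb, sim$X, sim$case, sim$stratum)
      }, 0)
    }
    for (dim in 1:2) {
      best <- grid[which.max(prof(dim))]
      expect_equal(unname(fit$coef[dim]), best, tolerance = 2e-3)
    }
  }
  expect_gte(checked, 3)
})

test_that("coefficients are invariant to stratum-constant covariate shifts", {
  sim <- simulate_strata(50, beta = c(0.8, -0.5), m = 10, seed = 3)
  f1 <- fit_clr(sim$X, sim$case, sim$stratum)
  shift <- rep(rnorm(50), each = 11)
  X2 <- sim$X + cbind(shift, 2 * shift)
  f2 <- fit_clr(X2, sim$case, sim$stratum)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-7)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
})

test_that("fit agrees with survival::clogit on a moderate problem", {
  skip_if_not_installed("survival")
  # clogit expands to a coxph call, which must be resolvable here
  coxph <- survival::coxph
  Surv <- survival::Surv
  strata <- survival::strata
  sim <- simulate_strata(300, beta = c(0.8, -0.5), m = 20, seed = 42)
  mine <- fit_clr(sim$X, sim$case, sim$stratum)
  df <- data.frame(case = sim$case, sim$X, s = sim$stratum)
  ref <- survival::clogit(case ~ x1 + x2 + strata(s), data = df)
  expect_equal(unname(mine$coef), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(mine$se), unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-6)
})

test_that("perfect separation is detected and reported", {
  # covariate 1 identifies the case in every stratum
  X <- matrix(rep(c(1, 0, 0), 30), ncol = 1)
  case <- rep(c(1, 0, 0), 30)
  expect_warning(fit <- fit_clr(X, case, rep(1:30, each = 3)),
                 "diverged")
  expect_true(fit$diverged)
  expect_false(fit$converged)
})

test_that("RSS report exponentiates and formats Wald inference", {
  sim <- simulate_strata(200, beta = c(0.5), m = 10, seed = 9)
  fit <- fit_clr(sim$X[, 1, drop = FALSE], sim$case, sim$stratum)
  tab <- rss_report(fit)
  expect_equal(tab$rss, exp(tab$estimate))
  expect_equal(tab$rss_lo, exp(tab$estimate - 1.96 * tab$se),
               tolerance = 1e-3)
  expect_equal(tab$log_rss, tab$estimate)
  # a null coefficient gives RSS 1 with a CI spanning 1
  f0 <- list(coef = c(road = 0), se = c(road = 0.05))
  class(f0) <- "sc_clr_fit"
  t0 <- rss_report(f0)
  expect_equal(t0$rss, 1)
  expect_lt(t0$rss_lo, 1); expect_gt(t0$rss_hi, 1)
  # the report reproduces the conventional RSS formatting
  f1 <- list(coef = c(road = log(1.166)), se = c(road = 0.05))
  class(f1) <- "sc_clr_fit"
  expect_equal(rss_report(f1)$rss, 1.166)
})

test_that("planted coefficients are recovered without bias (small sim)", {
  est <- t(vapply(1:20, function(r) {
    sim <- simulate_strata(300, beta = c(0.8, -0.5), m = 20, seed = 100 + r)
    fit_clr(sim$X, sim$case, sim$stratum)$coef
  }, c(0, 0)))
  expect_lt(abs(mean(est[, 1]) - 0.8), 0.1)
  expect_lt(abs(mean(est[, 2]) + 0.5), 0.15)
})

test_that("make_strata attaches covariates and honours the raster extent", {
  L <- test_landscape(seed = 4, n_cells = 200)
  w <- walker_config()
  tr <- simulate_track(L, w, rep("active_dispersal", 2), seed = 6)
  st <- discretize_5min(tr)
  dists <- fit_step_distributions(st)
  strata <- make_strata(st, dists, L, m = 10, seed = 2)
  sz <- table(strata$stratum_id)
  expect_true(all(sz <= 11))
  expect_equal(sum(strata$is_case), length(unique(strata$stratum_id)))
  expect_true(all(strata$cover %in% attr(L$cover, "levels")))
  # endpoints all inside the extent
  expect_true(all(strata$x >= 0 & strata$x < 2000))
  # deterministic under the same seed
  strata2 <- make_strata(st, dists, L, m = 10, seed = 2)
  expect_identical(strata$x, strata2$x)
})
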