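test_that("tracks are bit-identical under the same seed", {
  L <- test_landscape(seed = 1)
  w <- walker_config()
  a <- simulate_track(L, w, c("resident", "active_dispersal"), seed = 4)
  b <- simulate_track(L, w, c("resident", "active_dispersal"), seed = 4)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  c <- simulate_track(L, w, c("resident", "active_dispersal"), seed = 5)
  expect_false(identical(a$x, c$x))
})

test_that("a walker starting off-raster errors; stage labels validated", {
  L <- test_landscape(seed = 1)
  w <- walker_config()
  expect_error(simulate_track(L, w, "resident", start = c(-10, 50)),
               "outside")
  expect_error(simulate_track(L, w, "wandering"), "stage_schedule")
})

test_that("null selection picks uniformly among candidates", {
  # beta = 0 on a uniform landscape: the chosen candidate index must be
  # uniform on 1..m (chi-square GOF, alpha = 0.01)
  L <- uniform_landscape()
  w <- walker_config(beta = list(
    resident = c(road = 0, water = 0, glade = 0, riverine = 0, tri_z = 0),
    local_transience = c(road = 0, water = 0, glade = 0, riverine = 0,
                         tri_z = 0),
    active_dispersal = c(road = 0, water = 0, glade = 0, riverine = 0,
                         tri_z = 0)),
    drift = c(resident = 0, local_transience = 0, active_dispersal = 0),
    roost_return = 0)
  tr <- simulate_track(L, w, rep("local_transience", 8), seed = 7)
  picks <- attr(tr, "decisions")$pick
  gof <- suppressWarnings(
    stats::chisq.test(table(factor(picks, levels = 1:50))))
  expect_gt(gof$p.value, 0.01)
})

test_that("positive road selection overuses roads relative to availability", {
  L <- test_landscape(seed = 6, n_cells = 300)
  w <- walker_config()   # active beta_road > 0
  tr <- simulate_track(L, w, rep("active_dispersal", 8), seed = 7)
  dec <- attr(tr, "decisions")
  # availability: brute-force mean road share over all candidate sets
  avail <- mean(dec$cand_road_frac)
  used <- mean(dec$chosen_road)
  expect_gt(used, avail)
  # and the excess is larger than 3 binomial SEs of the used fraction
  expect_gt(used - avail, 3 * sqrt(used * (1 - used) / nrow(dec)))
})

test_that("resident days stay near the roost; active days classify active", {
  L <- test_landscape(seed = 1, n_cells = 300)
  w <- walker_config()
  tr <- simulate_track(L, w, rep("resident", 6), seed = 9)
  ds <- day_summaries(tr, resident = TRUE)
  expect_true(all(ds$D[-1] < 1200))
  expect_true(all(ds$classification[-1] == "resident"))
  L2 <- test_landscape(seed = 1, n_cells = 600)
  tr2 <- simulate_track(L2, w, rep("active_dispersal", 4), seed = 9)
  ds2 <- day_summaries(tr2, resident = FALSE)
  expect_true(all(ds2$classification[-1] == "active_dispersal"))
})

test_that("simulated step lengths recover the planted gamma within 10%", {
  # uniform landscape and zero beta so neither selection nor habitat
  # scaling distorts the kernel; >= 5000 pooled 5-min steps. A large
  # domain keeps boundary reflections (which shorten realised steps) rare.
  L <- uniform_landscape(n_cells = 800)
  shp <- 1.6; scl <- 45
  w <- walker_config(
    beta = list(
      resident = c(road = 0, water = 0, glade = 0, riverine = 0, tri_z = 0),
      local_transience = c(road = 0, water = 0, glade = 0, riverine = 0,
                           tri_z = 0),
      active_dispersal = c(road = 0, water = 0, glade = 0, riverine = 0,
                           tri_z = 0)),
    drift = c(resident = 0, local_transience = 0, active_dispersal = 0))
  tr <- simulate_track(L, w, rep("active_dispersal", 33), seed = 11)
  dec <- attr(tr, "decisions")
  expect_gte(nrow(dec), 5000)
  # decision-to-decision distances are the realised 5-min step lengths
  dx <- diff(dec$x); dy <- diff(dec$y)
  keep <- dec$step[-1] != 1       # skip overnight day joins
  len <- sqrt(dx^2 + dy^2)[keep]
  fit <- fit_gamma_mle(len)
  expect_lt(abs(fit$shape - shp) / shp, 0.10)
  expect_lt(abs(fit$scale - scl) / scl, 0.10)
})

test_that("dual-rate emission matches the tag duty cycle", {
  L <- test_landscape(seed = 1)
  w <- walker_config()
  tr <- simulate_track(L, w, rep("resident", 2), seed = 3)
  # 13 h of hi-res covers the whole duty day: identity
  full <- emit_dual_rate(tr, 13)
  expect_equal(nrow(full), nrow(tr))
  expect_true(all(full$res_flag == "hi"))
  # 0 h: one fix per 5-min boundary
  lo <- emit_dual_rate(tr, 0)
  expect_true(all(lo$res_flag == "lo"))
  expect_true(all(diff(lo$t[lo$day == 1]) == 300))
  # 4.5 h: per-day hi-res span bounded by 4.5 h
  mid <- emit_dual_rate(tr, 4.5)
  for (d in unique(mid$day)) {
    hi <- mid[mid$day == d & mid$res_flag == "hi", ]
    expect_lte(max(hi$t) - min(hi$t), 4.5 * 3600)
    expect_true(all(diff(hi$t) == 1))
  }
  # hi-res only on selected days
  sel <- emit_dual_rate(tr, 4.5, hi_res_days = 2)
  expect_true(all(sel$res_flag[sel$day == 1] == "lo"))
  expect_true(any(sel$res_flag[sel$day == 2] == "hi"))
})
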