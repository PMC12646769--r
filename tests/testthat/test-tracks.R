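test_that("track CSV round-trips and validates", {
  L <- test_landscape(seed = 1)
  w <- walker_config()
  tr <- emit_dual_rate(simulate_track(L, w, "resident", seed = 2), 0.5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, p)
  back <- read_tracks(p)
  expect_length(back, 1)
  b <- back[[1]]
  expect_equal(nrow(b), nrow(tr))
  expect_equal(b$x, tr$x, tolerance = 1e-6)
  expect_equal(diff(b$t), diff(tr$t))
  expect_equal(b$res_flag, tr$res_flag)
})

test_that("reader errors are specific", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("individual_id,timestamp,x", p)
  expect_error(read_tracks(p), "missing required column")
  # empty file with header -> empty collection
  writeLines("individual_id,timestamp,x,y", p)
  expect_length(read_tracks(p), 0)
  # duplicated timestamp names the bird
  writeLines(c("individual_id,timestamp,x,y",
               "b1,2019-09-07T06:00:00,0,0",
               "b1,2019-09-07T06:00:00,1,1"), p)
  expect_error(read_tracks(p), "b1")
  # two interleaved individuals come back as two sorted tracks
  writeLines(c("individual_id,timestamp,x,y",
               "b2,2019-09-07T06:00:01,5,5",
               "b1,2019-09-07T06:00:00,0,0",
               "b2,2019-09-07T06:00:00,4,4",
               "b1,2019-09-07T06:00:01,1,1"), p)
  two <- read_tracks(p)
  expect_setequal(names(two), c("b1", "b2"))
  expect_true(all(diff(two$b2$t) > 0))
})

test_that("a straight 0.5 m/s hour discretizes into 12 retained steps", {
  tr <- straight_track(v = 0.5, seconds = 3600)
  st <- discretize_5min(tr)
  expect_equal(nrow(st), 12)
  expect_equal(attr(st, "n_windows"), 12)
  expect_equal(st$L, rep(150, 12))
  expect_equal(st$turn_angle, c(NA, rep(0, 11)))
})

test_that("stationary tracks yield no retained steps", {
  tr <- track_from_xy(rep(100, 1000), rep(100, 1000))
  st <- discretize_5min(tr)
  expect_equal(nrow(st), 0)
  expect_equal(attr(st, "n_windows"), 3)
})

test_that("a dropped sub-10 m window breaks the turning-angle chain", {
  # window 1: 9.9 m, window 2: 12 m, window 3: 12 m
  v <- c(rep(9.9 / 300, 300), rep(12 / 300, 600))
  tr <- track_from_xy(c(0, cumsum(v)), rep(0, 901))
  st <- discretize_5min(tr)
  expect_equal(nrow(st), 2)
  expect_equal(st$step_id, c(2, 3))
  expect_true(is.na(st$turn_angle[1]))   # predecessor was dropped
  expect_equal(st$turn_angle[2], 0)      # contiguous retained pair
  # filtering is idempotent in effect: retained count <= window count
  expect_lte(nrow(st), attr(st, "n_windows"))
})

test_that("day classification applies both displacement rules", {
  expect_equal(classify_day(1600, 0.1), "active_dispersal")
  expect_equal(classify_day(1300, 0.35), "active_dispersal")
  expect_equal(classify_day(1300, 0.20), "local")
  expect_equal(classify_day(1300, 0.20, resident = TRUE), "resident")
  # boundary: exactly at the hard threshold is not active
  expect_equal(classify_day(1500, 0.2), "local")
  expect_equal(classify_day(1501, 0.2), "active_dispersal")
})

test_that("classification is monotone in displacement at fixed straightness", {
  S <- 0.25
  cls <- classify_day(seq(0, 3000, by = 10), S)
  active <- cls == "active_dispersal"
  expect_true(all(diff(as.integer(active)) >= 0))  # never flips back
})

test_that("roost extraction flags incomplete days and errors on corrupt P", {
  tr <- straight_track(v = 0.5, seconds = 6 * 3600)  # ends 12:00
  ro <- extract_roosts(tr)
  expect_false(ro$complete[1])
  full <- straight_track(v = 0.1, seconds = 13 * 3600 - 1)
  expect_true(extract_roosts(full)$complete[1])
})

test_that("settlement is detected and back-dated; short runs are not", {
  mk <- function(xs) data.frame(individual = "d", day = seq_along(xs),
                                evening_x = xs, evening_y = 0)
  # same roost for 14 days from day 6
  ro <- mk(c(seq(0, 5000, length.out = 5), rep(8000, 14) + rep(c(-40, 40), 7)))
  expect_equal(detect_settlement(ro, radius = 200, window = 14), 6)
  # 13-day run then a 2 km move: none
  ro2 <- mk(c(rep(0, 13), 2000, rep(4000, 3)))
  expect_true(is.na(detect_settlement(ro2, radius = 200, window = 14)))
  # all identical: settlement on day 1
  ro3 <- mk(rep(1000, 14))
  expect_equal(detect_settlement(ro3, radius = 200, window = 14), 1)
})

test_that("net displacements close at the radius and follow the restart rule", {
  tr <- straight_track(v = 1, seconds = 520)
  disp <- net_displacements_50m(tr)
  # oracle: apply the rule directly
  oracle <- local({
    x <- tr$x; n <- length(x); i <- 1; cnt <- 0
    while (TRUE) {
      j <- i
      while (j <= n && abs(x[j] - x[i]) < 50) j <- j + 1
      if (j > n) break
      cnt <- cnt + 1
      i <- j + 1
    }
    cnt
  })
  expect_equal(nrow(disp), oracle)
  expect_true(all(disp$d_true >= 50 & disp$d_true <= 52))
  # circling forever on a small circle (diameter < 50 m) never closes
  th <- seq(0, 40 * pi, length.out = 2000)
  circ <- track_from_xy(24 * cos(th), 24 * sin(th))
  expect_equal(nrow(net_displacements_50m(circ)), 0)
  # a 49 s track cannot close a 50 m displacement at 1 m/s
  expect_equal(nrow(net_displacements_50m(straight_track(v = 1,
                                                         seconds = 49))), 0)
})

test_that("displacement seconds never exceed track duration", {
  L <- test_landscape(seed = 2, n_cells = 300)
  tr <- simulate_track(L, walker_config(), "active_dispersal", seed = 13)
  disp <- net_displacements_50m(tr)
  expect_gt(nrow(disp), 0)
  expect_lte(sum(disp$n_seconds), diff(range(tr$t)))
  expect_true(all(disp$d_true >= 50))
})
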