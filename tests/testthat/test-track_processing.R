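# SDA filter, particle correction and hourly interpolation

make_track <- function(x_km, y_km, hours, lc = NULL, id = "w1") {
  n <- length(x_km)
  if (is.null(lc)) lc <- rep("1", n)
  ll <- proj_inv(km_proj, x_km * 1000, y_km * 1000)
  data.frame(animal_id = id,
             timestamp = as.POSIXct("2014-08-01", tz = "UTC") + 3600 * hours,
             lon = ll[, 1], lat = ll[, 2], lc = lc)
}

test_that("sda_filter removes class Z and nothing else on a clean track", {
  tr <- make_track(c(0, 1, 2, 3, 4), rep(0, 5), 0:4,
                   lc = c("1", "Z", "2", "Z", "B"))
  res <- sda_filter(tr)
  expect_identical(res$removed$reason, c("LC Z", "LC Z"))
  expect_identical(res$kept$lc, c("1", "2", "B"))
  # stationary animal: only the Z subset goes
  st <- make_track(rep(0, 6), rep(0, 6), 0:5,
                   lc = c("A", "Z", "B", "B", "Z", "3"))
  res2 <- sda_filter(st)
  expect_identical(sort(res2$removed$reason), c("LC Z", "LC Z"))
  expect_equal(nrow(res2$kept), 4)
})

test_that("sda_filter drops a fix needing 5 m/s both ways", {
  # apex displaced so both legs need ~4.4 m/s, with a wide (~77 deg) apex
  # angle so no spike rule applies; the flanking pair alone needs 2.8 m/s
  x <- c(0, 20, 40, 60, 80); y <- c(0, 0, 25, 0, 0)
  tr <- make_track(x, y, c(0, 2, 4, 6, 8))
  res <- sda_filter(tr)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$timestamp,
               as.POSIXct("2014-08-01", tz = "UTC") + 3600 * 4)
  expect_identical(res$removed$reason, "speed")
})

test_that("sda_filter removes an out-and-back spike apex", {
  # 3 km legs, ~10 degree internal angle, slow timing so speed is legal
  apex <- c(3 * cos(5 * pi / 180) * 2, 0)  # not used; geometry built below
  x <- c(0, 3 * cos(10 * pi / 180), 0.06)
  y <- c(0, 3 * sin(10 * pi / 180), 0.5)
  # place points: A=(0,0), B ~3 km away, C back near A (angle at B ~10 deg)
  A <- c(0, 0); B <- c(3, 0); C <- c(3 - 3 * cos(10 * pi / 180),
                                     3 * sin(10 * pi / 180))
  tr <- make_track(c(A[1], B[1], C[1], 0.2, 0.4),
                   c(A[2], B[2], C[2], 0.6, 0.8), c(0, 6, 12, 18, 24))
  res <- sda_filter(tr)
  expect_true(nrow(res$removed) == 1)
  expect_identical(res$removed$reason, "spike")
  expect_equal(res$removed$timestamp,
               as.POSIXct("2014-08-01", tz = "UTC") + 3600 * 6)
})

test_that("sda_filter is idempotent", {
  with_seed(5, for (k in 1:10) {
    tr <- random_short_track(sample(5:12, 1), seed = k + 100)
    r1 <- sda_filter(tr)
    if (nrow(r1$kept) == 0) next
    r2 <- sda_filter(r1$kept)
    expect_equal(nrow(r2$removed), 0)
    expect_equal(r2$kept$timestamp, r1$kept$timestamp)
  })
})

test_that("sda_filter equals the brute-force subset search on short tracks", {
  cfg <- sda_config()
  for (k in 1:40) {
    tr <- random_short_track(sample(4:8, 1), seed = 500 + k)
    got <- sda_filter(tr, cfg)
    want_idx <- sda_brute_force(tr, cfg)
    expect_equal(which(tr$timestamp %in% got$kept$timestamp), want_idx,
                 info = paste("track seed", 500 + k))
  }
})

test_that("sda_filter validates input ordering", {
  tr <- make_track(c(0, 1), c(0, 0), c(2, 1))
  expect_error(sda_filter(tr), "sorted")
  allz <- make_track(c(0, 1), c(0, 0), c(0, 1), lc = c("Z", "Z"))
  expect_warning(expect_warning(res <- sda_filter(allz), "removed"),
                 "removed")
  expect_equal(nrow(res$kept), 0)
})

test_that("correct_onland passes at-sea fixes and removes deep-inland fixes", {
  m <- square_world()
  # one at-sea fix, one fix at the island centre (25 km from any coast,
  # error radius 5 km -> all particles on land)
  tr <- make_track(c(-5, 25), c(0, 5), c(0, 1), lc = c("B", "B"))
  res <- correct_onland(tr, m, correction_config(seed = 9))
  expect_equal(nrow(res$track), 1)
  expect_identical(res$track$provenance, "original")
  expect_equal(res$track$lon, tr$lon[1])
  expect_equal(nrow(res$removed), 1)
  expect_identical(res$removed$reason, "no at-sea particles")
  expect_equal(res$n_onland, 1)
  expect_error(correct_onland(make_track(0, 0, 0, lc = "Z"), m,
                              correction_config()), "class Z")
  bad <- correction_config()
  bad$lc_errors <- bad$lc_errors[c("3", "2", "1", "A")]
  expect_error(correct_onland(make_track(0, 0, 0, lc = "B"), m, bad),
               "error radius")
})

test_that("correct_onland matches the half-disc centroid oracle", {
  m <- halfplane_coast()
  # fix 1 m inside land on a straight coast; uniform disc of radius R ->
  # at-sea particles are a half-disc whose centroid is 4R/(3*pi) seaward
  R <- 5000
  cfgE <- correction_config(n_particles = 50000, seed = 31,
                            lc_errors = lc_error_table(
                              c("3" = 100, "2" = 200, "1" = 500,
                                "A" = 1000, "B" = R)))
  p0 <- ll_of(0, -0.001)
  tr <- data.frame(animal_id = "w1",
                   timestamp = as.POSIXct("2014-08-01", tz = "UTC"),
                   lon = p0[1], lat = p0[2], lc = "B")
  res <- correct_onland(tr, m, cfgE)
  expect_identical(res$track$provenance, "particle-corrected")
  disp <- haversine_distance(tr$lon, tr$lat, res$track$lon, res$track$lat)
  want <- 4 * R / (3 * pi)
  se <- R * sqrt(0.25 - (4 / (3 * pi))^2) / sqrt(25000)
  expect_lt(abs(disp - want), 3 * se)
  # corrected point is seaward (north in this world)
  expect_gt(res$track$lat, tr$lat)
})

test_that("correct_onland is seed-deterministic and bounded by the radius", {
  m <- square_world()
  with_seed(3, {
    x <- runif(10, -1, 1); y <- runif(10, -6, 6)
  })
  tr <- make_track(x, y, 0:9, lc = rep(c("A", "B"), 5))
  cfg <- correction_config(seed = 77)
  r1 <- correct_onland(tr, m, cfg)
  r2 <- correct_onland(tr, m, cfg)
  expect_identical(r1, r2)
  moved <- haversine_distance(tr$lon[match(r1$track$timestamp, tr$timestamp)],
                              tr$lat[match(r1$track$timestamp, tr$timestamp)],
                              r1$track$lon, r1$track$lat)
  lim <- unname(cfg$lc_errors[r1$track$lc])
  expect_true(all(moved <= lim + 1e-6))
  # per-animal streams: adding another animal does not change animal w1
  tr2 <- rbind(tr, transform(tr, animal_id = "w2"))
  r3 <- correct_onland(tr2, m, cfg)
  w1 <- r3$track[r3$track$animal_id == "w1", ]
  rownames(w1) <- NULL
  expect_equal(w1[, names(r1$track)], r1$track)
})

test_that("interpolate_hourly: grid, collinearity, gap rule, land drops", {
  m <- square_world()
  # two fixes 4 h apart over open water, on the hour grid -> 5 points
  tr <- make_track(c(-10, -6), c(-10, 10), c(0, 4), lc = c("1", "1"))
  out <- interpolate_hourly(tr, m)
  expect_equal(nrow(out), 5)
  expect_equal(as.numeric(diff(out$timestamp), units = "hours"),
               rep(1, 4))
  xy <- proj_fwd(km_proj, out$lon, out$lat)
  fit <- stats::lm(xy[, 2] ~ xy[, 1])
  # collinear up to the (sub-mm/km) curvature difference between the
  # output's own projection and this test's reference projection
  expect_lt(max(abs(stats::resid(fit))), 0.05)
  # 13 h gap: no interior points
  tr2 <- make_track(c(-10, -6), c(-10, 10), c(0, 13), lc = c("1", "1"))
  out2 <- interpolate_hourly(tr2, m)
  expect_equal(nrow(out2), 0)
  # off-grid fix times never appear
  tr3 <- tr
  tr3$timestamp <- tr3$timestamp + 360   # 6 min past the hour
  out3 <- interpolate_hourly(tr3, m)
  expect_true(all(as.numeric(out3$timestamp) %% 3600 == 0))
  expect_equal(nrow(out3), 4)
  expect_warning(interpolate_hourly(tr[1, ], m), "fewer than 2")
})

test_that("interpolated points over a headland match a grid-replay oracle", {
  m <- square_world()
  # straight segment passing over the island's SW corner region
  tr <- make_track(c(-4, 8), c(-26, -16), c(0, 10), lc = c("1", "1"))
  out <- interpolate_hourly(tr, m)
  # oracle: rebuild the full grid and count on-land drops independently
  proj <- local_proj(c(mean(range(tr$lon)), mean(range(tr$lat))))
  xy <- proj_fwd(proj, tr$lon, tr$lat)
  hs <- seq(0, 10)
  f <- hs / 10
  gx <- xy[1, 1] + f * (xy[2, 1] - xy[1, 1])
  gy <- xy[1, 2] + f * (xy[2, 2] - xy[1, 2])
  ll <- proj_inv(proj, gx, gy)
  land <- point_on_land(ll[, 1], ll[, 2], m)
  expect_gt(sum(land), 0)            # the segment does cross the corner
  expect_equal(nrow(out), sum(!land))
  expect_equal(attr(out, "n_dropped"), sum(land))
})

test_that("processing_report reconciles and rounds percentages", {
  m <- square_world()
  with_seed(21, {
    x <- runif(40, -3, 1); y <- runif(40, -8, 8)
  })
  lc <- rep(c("3", "A", "B", "Z"), 10)
  tr <- make_track(x, y, seq(0, 78, by = 2), lc = lc)
  filt <- sda_filter(tr)
  corr <- correct_onland(filt$kept, m, correction_config(seed = 5))
  hourly <- interpolate_hourly(corr$track, m)
  rep <- processing_report(tr, filt, corr, hourly)
  all_row <- rep[rep$animal_id == "(all)", ]
  expect_equal(all_row$n_raw, 40)
  expect_equal(all_row$n_raw,
               nrow(filt$kept) + all_row$n_removed_lcz + all_row$n_removed_sda)
  expect_equal(all_row$pct_onland,
               round(100 * all_row$n_onland / all_row$n_raw))
  # per-animal rows sum to the pooled row
  per <- rep[rep$animal_id != "(all)", ]
  expect_equal(sum(per$n_raw), all_row$n_raw)
  expect_equal(sum(per$n_hourly), all_row$n_hourly)
  # printed-style arithmetic: 25 of 100 on land -> 25%
  expect_equal(round(100 * 25 / 100), 25)
  # inconsistent stages abort
  expect_error(processing_report(tr[-1, ], filt, corr, hourly), "reconcile")
})

test_that("the filter-correct-interpolate chain is seed-deterministic", {
  m <- square_world()
  with_seed(99, {
    x <- cumsum(runif(30, -1, 1)) - 3; y <- cumsum(runif(30, -1.5, 1.5))
  })
  tr <- make_track(x, y, seq(0, 58, by = 2),
                   lc = sample(c("1", "A", "B"), 30, TRUE))
  run <- function() {
    f <- sda_filter(tr)
    co <- correct_onland(f$kept, m, correction_config(seed = 4))
    interpolate_hourly(co$track, m)
  }
  expect_identical(run(), run())
})
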