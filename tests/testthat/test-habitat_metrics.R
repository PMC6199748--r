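# classification, ice joining, movement metrics, occupancy, budgets

test_that("movement_metrics: speed and turn on constructed geometry", {
  # eastward steps of exactly 3600 m (built with the geodesic oracle by
  # bisection on longitude at 78 N)
  lon_step <- stats::uniroot(function(dl)
    geodesic_distance(15, 78, 15 + dl, 78) - 3600, c(0.1, 0.2),
    tol = 1e-12)$root
  h <- data.frame(animal_id = "w", lon = 15 + (0:3) * lon_step,
                  lat = 78,
                  timestamp = as.POSIXct("2014-08-01", tz = "UTC") +
                    3600 * (0:3))
  mm <- movement_metrics(h)
  expect_true(is.na(mm$speed[1]))
  expect_equal(mm$speed[-1], rep(1, 3), tolerance = 1e-6)
  expect_true(all(is.na(mm$turn[c(1, 4)])))
  # note: an along-parallel track at 78 N is NOT straight; its tiny true
  # turning equals the meridian convergence per step, dlon * sin(lat)
  expect_equal(mm$turn[2], lon_step * sin(78 * pi / 180), tolerance = 0.02)
  # genuinely straight (locally planar) collinear points -> turn 0
  st <- hourly_df(c(0, 2, 4, 6), c(0, 1, 2, 3))
  expect_equal(movement_metrics(st)$turn[2:3], c(0, 0), tolerance = 1e-3)
  # exact out-and-back -> 180
  rev <- hourly_df(c(0, 5, 0), c(0, 0, 0))
  mr <- movement_metrics(rev)
  expect_equal(mr$turn[2], 180, tolerance = 1e-6)
  # right-angle turn -> 90
  ra <- hourly_df(c(0, 3, 3), c(0, 0, 3))
  expect_equal(movement_metrics(ra)$turn[2], 90, tolerance = 0.05)
})

test_that("movement metrics break at gaps and respect invariances", {
  h <- hourly_df(c(0, 1, 2, 3, 4), c(0, 0.5, 0, 0.5, 0))
  h$timestamp[4:5] <- h$timestamp[4:5] + 3600   # 2 h gap before point 4
  mm <- movement_metrics(h)
  expect_true(is.na(mm$speed[4]))
  expect_true(all(is.na(mm$turn[c(1, 3, 4, 5)])))
  expect_false(is.na(mm$turn[2]))
  # turn is invariant to rotating the whole track
  th <- 37 * pi / 180
  x <- c(0, 2, 3, 5, 4); y <- c(0, 1, 3, 2, 0)
  rot <- cbind(x * cos(th) - y * sin(th), x * sin(th) + y * cos(th))
  t1 <- movement_metrics(hourly_df(x, y))$turn
  t2 <- movement_metrics(hourly_df(rot[, 1], rot[, 2]))$turn
  expect_equal(t1, t2, tolerance = 0.02)
  # speed is invariant to translating the track
  s1 <- movement_metrics(hourly_df(x, y))$speed
  s2 <- movement_metrics(hourly_df(x + 30, y - 15))$speed
  expect_equal(s1, s2, tolerance = 0.005)
})

test_that("classify_habitat applies the precedence rules", {
  m <- square_world()           # fjord head (front) at x = 10, y in [-3,3]
  pts <- rbind(
    ll_of(7, 0),      # in fjord, 3 km from front -> Glacier-Fronts
    ll_of(2, 0),      # in fjord, 8 km from front -> Fjords
    ll_of(-2, 10),    # 2 km off the outer coast, outside fjords -> Coastal
    ll_of(-10, 10))   # 10 km offshore -> At-Sea
  h <- data.frame(animal_id = "w", lon = pts[, 1], lat = pts[, 2],
                  timestamp = as.POSIXct("2014-08-01", tz = "UTC") + 0:3)
  cl <- classify_habitat(h, m)
  expect_equal(as.character(cl$habitat),
               c("Glacier-Fronts", "Fjords", "Coastal", "At-Sea"))
  expect_equal(cl$dist_glacier[1], 3, tolerance = 0.02)
  expect_equal(cl$dist_coast[3], 2, tolerance = 0.02)
  # exactly 5 km from the front, inside the fjord: "less than" is strict,
  # so the location falls through to Fjords
  p5 <- ll_of(5, 0)
  h5 <- data.frame(animal_id = "w", lon = p5[1], lat = p5[2],
                   timestamp = as.POSIXct("2014-08-01", tz = "UTC"))
  cl5 <- classify_habitat(h5, m)
  expect_equal(cl5$dist_glacier, 5, tolerance = 1e-6)
  expect_equal(as.character(cl5$habitat), "Fjords")
  # missing layers are configuration errors
  m2 <- m; m2$glacier_fronts <- list()
  expect_error(classify_habitat(h, m2), "glacier")
  m3 <- m; m3$fjords <- list()
  expect_error(classify_habitat(h, m3), "fjord")
})

test_that("classification is exhaustive and mutually exclusive", {
  with_seed(17, {
    for (rep in 1:4) {
      spec <- archipelago_spec(n_fjords = sample(2:4, 1),
                               fjord_depth_km = runif(1, 15, 30),
                               fjord_width_km = runif(1, 6, 12),
                               retreat_km = runif(1, 0, 8),
                               jitter_km = 0.3, seed = rep)
      arch <- make_archipelago(spec)
      m <- arch$epoch1
      lon <- 15 + runif(300, -1.5, 3); lat <- 78 + runif(300, -1.2, 1.2)
      sea <- !point_on_land(lon, lat, m)
      h <- data.frame(animal_id = "w", lon = lon[sea], lat = lat[sea],
                      timestamp = as.POSIXct("2014-08-01", tz = "UTC") +
                        seq_len(sum(sea)))
      cl <- classify_habitat(h, m)
      expect_false(any(is.na(cl$habitat)))
      expect_true(all(cl$habitat %in% HABITAT_CLASSES))
      # glacier retreat can only lose Glacier-Fronts points, never gain
      cl2 <- classify_habitat(h, arch$epoch2)
      was_gf <- cl$habitat == "Glacier-Fronts"
      expect_true(all(which(cl2$habitat == "Glacier-Fronts") %in%
                      which(was_gf)))
    }
  })
})

test_that("assign_ice_type: same day, nearest day, outside coverage", {
  m <- square_world()
  d0 <- as.Date("2014-10-01")
  fields <- make_ice_fields(m, c(d0 - 30, d0, d0 + 20), d0 - 5)
  # pre-onset field is empty
  expect_length(fields[[1]]$polygons, 0)
  p <- ll_of(-1, 10)  # 1 km off the coast
  mk <- function(date) data.frame(animal_id = "w", lon = p[1], lat = p[2],
                                  timestamp = as.POSIXct(paste(date,
                                                               "06:00:00"),
                                                         tz = "UTC"))
  # same-day field, coastal point after freeze-up -> Fast ice
  expect_equal(as.character(assign_ice_type(mk(d0), fields)$ice_type),
               "Fast ice")
  # nearest field wins: two days after the empty field -> still Open Water
  expect_equal(as.character(assign_ice_type(mk(d0 - 28), fields)$ice_type),
               "Open Water")
  # far offshore point is outside all polygons -> Open Water
  far <- ll_of(-250, 10)
  hfar <- data.frame(animal_id = "w", lon = far[1], lat = far[2],
                     timestamp = as.POSIXct(paste(d0, "06:00:00"),
                                            tz = "UTC"))
  expect_equal(as.character(assign_ice_type(hfar, fields)$ice_type),
               "Open Water")
  expect_error(assign_ice_type(mk(d0), list()), "empty")
  # coverage is non-decreasing with date
  area_proxy <- vapply(fields, function(f) length(f$polygons), numeric(1))
  expect_true(all(diff(area_proxy) >= 0))
})

test_that("day_index anchors at 7 July and wraps across New Year", {
  t1 <- as.POSIXct("2014-07-07 00:00:00", tz = "UTC")
  expect_equal(day_index(t1), 0L)
  expect_equal(day_index(t1 + 86400), 1L)
  expect_equal(day_index(as.POSIXct("2015-01-07", tz = "UTC")), 184L)
  expect_equal(day_index(as.POSIXct("2014-07-06", tz = "UTC")), 364L)
})

test_that("occupancy_series one-hot encodes habitat", {
  m <- square_world()
  pts <- rbind(ll_of(8, 0), ll_of(-10, 10), ll_of(2, 0))
  h <- data.frame(animal_id = "w", lon = pts[, 1], lat = pts[, 2],
                  timestamp = as.POSIXct("2014-08-01", tz = "UTC") +
                    3600 * (0:2))
  occ <- occupancy_series(classify_habitat(h, m))
  ind <- as.matrix(occ[, c("occ_glacier", "occ_fjords", "occ_coastal",
                           "occ_atsea")])
  expect_true(all(rowSums(ind) == 1))
  expect_equal(ind[1, "occ_glacier"], c(occ_glacier = 1))
  expect_equal(ind[2, "occ_atsea"], c(occ_atsea = 1))
  expect_equal(ind[3, "occ_fjords"], c(occ_fjords = 1))
})

test_that("summarize_time_budget: exact splits and normalization", {
  # 60/40 split constructed directly
  h <- data.frame(animal_id = "w",
                  timestamp = as.POSIXct("2014-08-01", tz = "UTC") +
                    3600 * (0:99),
                  habitat = factor(rep(c("Glacier-Fronts", "Fjords"),
                                       c(60, 40)),
                                   levels = HABITAT_CLASSES))
  b <- summarize_time_budget(h, by = "pooled")
  expect_equal(b$proportion[b$class == "Glacier-Fronts"], 0.6)
  expect_equal(b$proportion[b$class == "Fjords"], 0.4)
  expect_equal(sum(b$proportion), 1, tolerance = 1e-12)
  # single animal in one habitat -> proportion 1
  h2 <- h[1:10, ]; h2$habitat <- factor("Coastal", levels = HABITAT_CLASSES)
  b2 <- summarize_time_budget(h2, by = "animal")
  expect_equal(b2$proportion[b2$class == "Coastal"], 1)
  # monthly grouping counts animals with >= 1 location in the month
  h3 <- rbind(h, transform(h[1:5, ], animal_id = "w2"))
  b3 <- summarize_time_budget(h3, by = "month")
  expect_equal(unique(b3$n_animals), 2L)
  expect_equal(unique(b3$group), "2014-08")
})
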