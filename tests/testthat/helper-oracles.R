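# Shared fixtures and independent oracles used across the suite.

# --- tiny geometric worlds, built in a planar km frame around (15E, 78N) ---

km_proj <- local_proj(c(15, 78))
km_to_ll <- function(m) proj_inv(km_proj, m[, 1] * 1000, m[, 2] * 1000)
ll_of <- function(x_km, y_km) drop(proj_inv(km_proj, x_km * 1000, y_km * 1000))

# square island [0,40] x [-20,20] km with one 10x6 km fjord cut into the
# west coast at y in [-3,3], glacier front across the fjord head
square_world <- function(fjord_depth = 10) {
  ring <- rbind(c(0, -20),
                c(0, -3), c(fjord_depth, -3), c(fjord_depth, 3), c(0, 3),
                c(0, 20), c(40, 20), c(40, -20), c(0, -20))
  coast_model("test",
              land = list(list(km_to_ll(ring))),
              glacier_fronts = list(km_to_ll(rbind(c(fjord_depth, -3),
                                                   c(fjord_depth, 3)))),
              fjords = list(list(km_to_ll(rbind(c(0, -3), c(fjord_depth, -3),
                                                c(fjord_depth, 3), c(0, 3),
                                                c(0, -3))))))
}

# winding-number point-in-polygon oracle (independent of the ray-casting
# implementation)
winding_inside <- function(lon, lat, ring) {
  x <- ring[, 1] - lon; y <- ring[, 2] - lat
  n <- nrow(ring)
  ang <- 0
  for (i in seq_len(n - 1)) {
    a1 <- atan2(y[i], x[i]); a2 <- atan2(y[i + 1], x[i + 1])
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

# brute-force distance to polylines: densify each segment at `step_m` and
# take the minimum vertex distance (haversine)
brute_dist_km <- function(lon, lat, lines, step_m = 50) {
  best <- Inf
  for (m in lines) {
    for (i in seq_len(nrow(m) - 1)) {
      L <- haversine_distance(m[i, 1], m[i, 2], m[i + 1, 1], m[i + 1, 2])
      k <- max(1, ceiling(L / step_m))
      f <- seq(0, 1, length.out = k + 1)
      lonv <- m[i, 1] + f * (m[i + 1, 1] - m[i, 1])
      latv <- m[i, 2] + f * (m[i + 1, 2] - m[i, 2])
      best <- min(best, min(haversine_distance(lon, lat, lonv, latv)))
    }
  }
  best / 1000
}

# --- SDA brute-force oracle -------------------------------------------------

# validity of a kept subsequence under the filter's post-conditions,
# recomputed from lon/lat with this file's own arithmetic
sda_valid_subseq <- function(keep_idx, lon, lat, tsec, cfg, bbox_idx = NULL) {
  if (length(keep_idx) < 3) return(TRUE)
  if (is.null(bbox_idx)) bbox_idx <- seq_along(lon)
  proj <- local_proj(c((min(lon[bbox_idx]) + max(lon[bbox_idx])) / 2,
                       (min(lat[bbox_idx]) + max(lat[bbox_idx])) / 2))
  xy <- proj_fwd(proj, lon, lat)
  for (k in 2:(length(keep_idx) - 1)) {
    p <- keep_idx[k - 1]; i <- keep_idx[k]; q <- keep_idx[k + 1]
    d1 <- sqrt(sum((xy[i, ] - xy[p, ])^2))
    d2 <- sqrt(sum((xy[q, ] - xy[i, ])^2))
    s1 <- d1 / (tsec[i] - tsec[p]); s2 <- d2 / (tsec[q] - tsec[i])
    if (s1 > cfg$vmax && s2 > cfg$vmax) return(FALSE)
    if (d1 > 0 && d2 > 0) {
      v1 <- xy[p, ] - xy[i, ]; v2 <- xy[q, ] - xy[i, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) / (d1 * d2)))) * 180 / pi
      for (r in cfg$spike_rules)
        if (ang < r[1] && d1 / 1000 > r[2] && d2 / 1000 > r[2]) return(FALSE)
    }
  }
  TRUE
}

# exhaustive maximal-retention subset search over non-Z fixes (n <= ~12);
# ties prefer keeping earlier fixes (lexicographically smallest kept set)
sda_brute_force <- function(track, cfg) {
  nz <- which(track$lc != "Z")
  n <- length(nz)
  tsec <- as.numeric(track$timestamp)
  best <- integer(0)
  for (size in n:0) {
    if (size < length(best)) break
    cand <- utils::combn(n, size, simplify = FALSE)
    ok <- Filter(function(s) sda_valid_subseq(nz[s], track$lon, track$lat,
                                              tsec, cfg, bbox_idx = nz), cand)
    if (length(ok)) {
      # combn emits in lexicographic order, so the first valid one wins
      best <- nz[ok[[1]]]
      break
    }
  }
  sort(best)
}

# random short track with occasional large outliers, for oracle comparison
random_short_track <- function(n, seed) {
  with_seed(seed, {
    t0 <- as.POSIXct("2014-08-01", tz = "UTC")
    lon <- 15 + cumsum(stats::rnorm(n, 0, 0.01))
    lat <- 78 + cumsum(stats::rnorm(n, 0, 0.004))
    out <- stats::runif(n) < 0.2
    lon[out] <- lon[out] + stats::runif(sum(out), -0.6, 0.6)
    lat[out] <- lat[out] + stats::runif(sum(out), -0.25, 0.25)
    data.frame(animal_id = "t",
               timestamp = t0 + cumsum(stats::runif(n, 1200, 7200)),
               lon = lon, lat = lat,
               lc = sample(c("3", "2", "1", "A", "B", "Z"), n, TRUE,
                           prob = c(0.1, 0.1, 0.2, 0.25, 0.3, 0.05)))
  })
}

# straight east-west coastline world: land is everything south of y = 0
# (a very wide box), so "seaward" is +y
halfplane_coast <- function() {
  xs <- seq(-300, 300, by = 2)
  ring <- rbind(cbind(xs, 0), c(300, -300), c(-300, -300), c(-300, 0))
  coast_model("halfplane", land = list(list(km_to_ll(ring))),
              glacier_fronts = list(km_to_ll(rbind(c(-1, -50), c(1, -50)))),
              fjords = list(list(km_to_ll(rbind(c(-290, -299), c(-289, -299),
                                                c(-289, -298), c(-290, -298),
                                                c(-290, -299))))))
}

hourly_df <- function(x_km, y_km, start = "2014-08-01 00:00:00",
                      id = "w1", step = 3600) {
  ll <- proj_inv(km_proj, x_km * 1000, y_km * 1000)
  data.frame(animal_id = id,
             timestamp = as.POSIXct(start, tz = "UTC") +
               step * (seq_along(x_km) - 1),
             lon = ll[, 1], lat = ll[, 2])
}

# --- movement-model simulation (shared by model and acceptance tests) ---

# balanced classified-track builder: each animal visits every habitat,
# values = cell mean + random intercept + AR1(rho) noise
sim_movement_data <- function(n_per_period = 3, n_per_cell = 60,
                              mu, sd_id = 0, rho = 0, sd_e = 1e-6, seed = 1) {
  pers <- c("1995-2001", "2013-2016")
  out <- list()
  with_seed(seed, {
    for (p in seq_along(pers)) for (a in seq_len(n_per_period)) {
      id <- sprintf("p%da%d", p, a)
      b <- stats::rnorm(1, 0, sd_id)
      hab <- rep(HABITAT_CLASSES, each = n_per_cell)
      n <- length(hab)
      e <- stats::filter(stats::rnorm(n, 0, sd_e), rho, method = "recursive")
      e <- as.numeric(e) * sqrt(1 - rho^2)
      val <- mu[cbind(hab, pers[p])] + b + e
      out[[id]] <- data.frame(
        animal_id = id, period = pers[p], habitat = hab,
        timestamp = as.POSIXct("2014-08-01", tz = "UTC") + 3600 * (0:(n - 1)),
        speed = exp(val), turn = val)
    }
  })
  do.call(rbind, out)
}

mu_speed <- matrix(c(-0.75, -0.75 - 0.34,
                     -0.75 + 0.30, -0.75 + 0.30 - 0.34 - 0.097,
                     -0.75 + 0.28, -0.75 + 0.28 - 0.34 - 0.002,
                     -0.75 + 0.35, -0.75 + 0.35 - 0.34 + 0.042),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(HABITAT_CLASSES,
                                   c("1995-2001", "2013-2016")))

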