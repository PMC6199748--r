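# Synthetic world with known ground truth: an archipelago with fjords and
# tidal glacier fronts (two epochs, the second with retreated fronts),
# behaviour-state correlated-random-walk whale tracks, Argos-like
# observations with class-dependent error, and seasonal sea-ice fields.
# Geometry is built in a planar km frame and mapped to lon/lat through the
# local azimuthal equidistant projection, so planar km are true km.

#' Archipelago geometry specification
#'
#' One elongated island whose west coast is incised by rectangular fjords,
#' each capped by a tidal glacier front. Between epochs the fronts retreat
#' landward by `retreat_km`, deepening the fjords (land area shrinks).
#'
#' @param n_fjords number of fjords (default 3).
#' @param fjord_depth_km,fjord_width_km fjord dimensions (defaults 25, 8).
#' @param retreat_km glacier retreat between epochs (default 5, >= 0).
#' @param island_length_km,island_width_km island dimensions (200, 60).
#' @param origin lon/lat of the island centre (default c(15, 78)).
#' @param coast_step_km coastline vertex spacing (default 2).
#' @param jitter_km uniform jitter applied to non-corner coastline vertices
#'   (default 0; generation retries with halved jitter if a ring
#'   self-intersects).
#' @param seed RNG seed for the jitter.
#' @return an `archipelago_spec` object.
#' @export
archipelago_spec <- function(n_fjords = 3, fjord_depth_km = 25,
                             fjord_width_km = 8, retreat_km = 5,
                             island_length_km = 200, island_width_km = 60,
                             origin = c(15, 78), coast_step_km = 2,
                             jitter_km = 0, seed = 1) {
  stopifnot(n_fjords >= 1, retreat_km >= 0, fjord_depth_km > 0,
            fjord_width_km > 0,
            n_fjords * 2 * fjord_width_km < island_length_km)
  structure(as.list(environment()), class = "archipelago_spec")
}

densify_xy <- function(pts, step_km) {
  out <- pts[1, , drop = FALSE]
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / step_km))
    f <- seq_len(k) / k
    out <- rbind(out, cbind(a[1] + f * (b[1] - a[1]),
                            a[2] + f * (b[2] - a[2])))
  }
  out
}

#' Generate the two-epoch coast model pair
#'
#' @param spec an [archipelago_spec()].
#' @return list with elements `epoch1` and `epoch2`, each a [coast_model()],
#'   plus `proj` (the km-frame projection).
#' @export
make_archipelago <- function(spec) {
  proj <- local_proj(spec$origin)
  L <- spec$island_length_km; W <- spec$island_width_km
  n <- spec$n_fjords; D <- spec$fjord_depth_km; Wf <- spec$fjord_width_km
  centres <- seq(-L / 2 + L / (n + 1), L / 2 - L / (n + 1), length.out = n)
  build <- function(depth, label) {
    # outer ring, counter-clockwise from the SW corner; west coast at x = 0
    ring <- matrix(c(0, -L / 2), ncol = 2)
    for (y0 in centres) {
      ring <- rbind(ring,
                    c(0, y0 - Wf / 2), c(depth, y0 - Wf / 2),
                    c(depth, y0 + Wf / 2), c(0, y0 + Wf / 2))
    }
    ring <- rbind(ring, c(0, L / 2), c(W, L / 2), c(W, -L / 2), c(0, -L / 2))
    ring <- densify_xy(ring, spec$coast_step_km)
    ring <- jitter_ring(ring, spec$jitter_km, spec$seed, depth, L, W)
    to_ll <- function(m) proj_inv(proj, m[, 1] * 1000, m[, 2] * 1000)
    land <- list(list(to_ll(ring)))
    fronts <- lapply(centres, function(y0)
      to_ll(densify_xy(rbind(c(depth, y0 - Wf / 2), c(depth, y0 + Wf / 2)),
                       spec$coast_step_km)))
    fjords <- lapply(centres, function(y0)
      list(to_ll(rbind(c(0, y0 - Wf / 2), c(depth, y0 - Wf / 2),
                       c(depth, y0 + Wf / 2), c(0, y0 + Wf / 2),
                       c(0, y0 - Wf / 2)))))
    coast_model(label, land = land, glacier_fronts = fronts, fjords = fjords)
  }
  list(epoch1 = build(D, "epoch1"),
       epoch2 = build(D + spec$retreat_km, "epoch2"),
       proj = proj)
}

# jitter interior coastline vertices; retry with halved amplitude on
# self-intersection, then give up (jitter = 0 is always valid)
jitter_ring <- function(ring, jitter_km, seed, depth, L, W) {
  if (jitter_km <= 0) return(ring)
  amp <- jitter_km
  for (attempt in 1:3) {
    r <- with_seed(seed + attempt, {
      j <- ring
      corner <- (abs(j[, 1]) < 1e-9 | abs(j[, 1] - depth) < 1e-9 |
                 abs(j[, 1] - W) < 1e-9) &
                (abs(abs(j[, 2]) - L / 2) < 1e-9)
      idx <- which(!corner)
      idx <- idx[idx != 1 & idx != nrow(j)]
      j[idx, ] <- j[idx, ] + matrix(stats::runif(2 * length(idx), -amp, amp),
                                    ncol = 2)
      j[nrow(j), ] <- j[1, ]
      j
    })
    if (!ring_self_intersects(close_ring(r))) return(r)
    amp <- amp / 2
  }
  stop("could not generate a valid jittered coastline", call. = FALSE)
}

#' Behaviour specification for the track simulator
#'
#' Four behaviour states, one per habitat class, with a dwell-dominated
#' transition matrix, per-state log-normal speeds (m/s) and folded-normal
#' heading changes (degrees). Glacier-front behaviour is slow and tortuous
#' (area-restricted search); transit states are fast and directed. After
#' `offshore_onset_day` (day-of-season index) a per-hour hazard pushes
#' animals into the At-Sea state, emulating freeze-up.
#'
#' @param transition 4x4 row-stochastic matrix over
#'   (Glacier-Fronts, Fjords, Coastal, At-Sea).
#' @param speed_meanlog,speed_sdlog per-state log-normal speed parameters.
#' @param turn_sd per-state heading-change SD, degrees.
#' @param offshore_onset_day day-of-season after which the offshore hazard
#'   applies (default 120, i.e. early November).
#' @param offshore_hazard per-hour probability of being pushed At-Sea after
#'   onset (default 0.02).
#' @param period period label carried onto simulated data.
#' @return a `behaviour_spec` object.
#' @export
behaviour_spec <- function(
    transition = matrix(c(0.975, 0.010, 0.010, 0.005,
                          0.035, 0.935, 0.020, 0.010,
                          0.045, 0.030, 0.915, 0.010,
                          0.020, 0.010, 0.040, 0.930),
                        4, 4, byrow = TRUE,
                        dimnames = list(HABITAT_CLASSES, HABITAT_CLASSES)),
    speed_meanlog = c(log(0.45), log(0.8), log(1.1), log(0.9)),
    speed_sdlog = c(0.6, 0.5, 0.4, 0.5),
    turn_sd = c(70, 40, 18, 30),
    offshore_onset_day = 120, offshore_hazard = 0.02,
    period = "1995-2001") {
  stopifnot(all(abs(rowSums(transition) - 1) < 1e-9),
            all(transition >= 0), length(speed_meanlog) == 4,
            length(speed_sdlog) == 4, length(turn_sd) == 4)
  structure(list(transition = transition, speed_meanlog = speed_meanlog,
                 speed_sdlog = speed_sdlog, turn_sd = turn_sd,
                 offshore_onset_day = offshore_onset_day,
                 offshore_hazard = offshore_hazard, period = period),
            class = "behaviour_spec")
}

# planar even-odd crossing test for one point against precomputed segments;
# assumes disjoint land polygons (true for generated worlds)
fast_pip <- function(x, y, segs) {
  sel <- (segs[, 2] > y) != (segs[, 4] > y)
  if (!any(sel)) return(FALSE)
  x1 <- segs[sel, 1]; y1 <- segs[sel, 2]; x2 <- segs[sel, 3]; y2 <- segs[sel, 4]
  sum(x < (x2 - x1) * (y - y1) / (y2 - y1) + x1) %% 2 == 1
}

project_rings <- function(polys, proj) {
  segs <- NULL
  for (poly in polys) for (ring in poly) {
    xy <- proj_fwd(proj, ring[, 1], ring[, 2])
    n <- nrow(xy)
    segs <- rbind(segs, cbind(xy[-n, 1], xy[-n, 2], xy[-1, 1], xy[-1, 2]))
  }
  segs
}

#' Simulate behaviour-state whale tracks with known truth
#'
#' Hourly correlated random walk: each hour the behaviour state updates by
#' the transition matrix (plus the seasonal offshore hazard), the heading
#' gets a state-dependent Gaussian increment plus a pull toward the state's
#' anchor habitat, and the step length is a state-dependent log-normal speed
#' times one hour. Steps that land on shore are redrawn up to 20 times, then
#' the heading is reflected; as a last resort the animal holds position.
#'
#' @param model a [coast_model()].
#' @param behaviour a [behaviour_spec()].
#' @param n_animals number of animals.
#' @param days tracking duration per animal (recycled).
#' @param seed global seed; per-animal streams derived from it.
#' @param start_dates POSIXct deployment times (recycled; default
#'   2014-07-20 00:00 UTC).
#' @param id_prefix animal id prefix.
#' @return a `sim_truth` list: `truth` (animal_id, timestamp, lon, lat,
#'   state, habitat), `budgets` (per-animal true habitat proportions),
#'   `model`, `behaviour`.
#' @export
simulate_tracks <- function(model, behaviour, n_animals, days, seed = 1,
                            start_dates = as.POSIXct("2014-07-20",
                                                     tz = "UTC"),
                            id_prefix = "whale") {
  if (!length(model$glacier_fronts))
    stop("model has no glacier fronts; Glacier-Fronts state unreachable",
         call. = FALSE)
  days <- rep_len(days, n_animals)
  start_dates <- rep_len(start_dates, n_animals)
  all_lon <- unlist(lapply(model$land, function(p) p[[1]][, 1]))
  all_lat <- unlist(lapply(model$land, function(p) p[[1]][, 2]))
  proj <- track_proj(all_lon, all_lat)
  land_segs <- project_rings(model$land, proj)
  coast_segs <- project_segments(model$coastline, proj)
  front_segs <- project_segments(model$glacier_fronts, proj)
  fronts_mid <- t(vapply(model$glacier_fronts, function(m) {
    xy <- proj_fwd(proj, m[, 1], m[, 2]); colMeans(xy)
  }, numeric(2)))
  fjord_ctr <- t(vapply(model$fjords, function(p) {
    r <- p[[1]]; xy <- proj_fwd(proj, r[-nrow(r), 1], r[-nrow(r), 2])
    colMeans(xy)
  }, numeric(2)))
  # seaward direction reference: centroid of land, so "offshore" points away
  land_ctr <- colMeans(cbind(land_segs[, 1], land_segs[, 2]))
  nearest_target <- function(p, tgt) {
    d2 <- (tgt[, 1] - p[1])^2 + (tgt[, 2] - p[2])^2
    tgt[which.min(d2), ]
  }
  nearest_on_segs <- function(p, segs) {
    dx <- segs[, "x2"] - segs[, "x1"]
    dy <- segs[, "y2"] - segs[, "y1"]
    len2 <- pmax(dx^2 + dy^2, 1e-12)
    tt <- ((p[1] - segs[, "x1"]) * dx + (p[2] - segs[, "y1"]) * dy) / len2
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    cx <- segs[, "x1"] + tt * dx; cy <- segs[, "y1"] + tt * dy
    i <- which.min((cx - p[1])^2 + (cy - p[2])^2)
    c(cx[i], cy[i])
  }
  states <- HABITAT_CLASSES
  res <- list()
  for (a in seq_len(n_animals)) {
    id <- sprintf("%s%02d", id_prefix, a)
    n_h <- days[a] * 24L
    with_seed(derive_seed(seed, id), {
      f0 <- fronts_mid[(a - 1) %% nrow(fronts_mid) + 1, ]
      # start 1.5 km seaward (toward the fjord mouth) of a glacier front
      dir0 <- (land_ctr - f0); dir0 <- -dir0 / sqrt(sum(dir0^2))
      pos <- f0 + 1500 * dir0
      if (fast_pip(pos[1], pos[2], land_segs)) pos <- f0 + 3000 * dir0
      h <- stats::runif(1, 0, 360)
      st <- 1L
      P <- matrix(NA_real_, n_h, 2)
      S <- integer(n_h)
      tstamp <- start_dates[a] + 3600 * (seq_len(n_h) - 1)
      didx <- day_index(tstamp)
      for (t in seq_len(n_h)) {
        st <- sample.int(4L, 1L, prob = behaviour$transition[st, ])
        if (didx[t] >= behaviour$offshore_onset_day &&
            stats::runif(1) < behaviour$offshore_hazard) st <- 4L
        cp <- nearest_on_segs(pos, coast_segs)
        away <- pos - cp
        d_coast <- sqrt(sum(away^2))
        away <- if (d_coast > 1) away / d_coast else
          (pos - land_ctr) / max(sqrt(sum((pos - land_ctr)^2)), 1)
        fp <- nearest_on_segs(pos, front_segs)
        d_front <- sqrt(sum((pos - fp)^2))
        tgt <- switch(st,
          fp,                          # Glacier-Fronts: the front line
          if (nrow(fjord_ctr)) nearest_target(pos, fjord_ctr)
            else fp,
          cp + 2000 * away,            # Coastal: hug the shoreline
          cp + 12000 * away)           # At-Sea: sit ~12 km offshore
        d_tgt <- if (st == 1L) d_front else sqrt(sum((tgt - pos)^2))
        pull <- if (st == 1L) {
          if (d_front > 2000) 0.7 else 0.1
        } else if (d_tgt > 3000) 0.5 else 0.08
        brg <- atan2(tgt[1] - pos[1], tgt[2] - pos[2]) * 180 / pi
        dh <- ((brg - h + 180) %% 360) - 180
        base_h <- h + pull * dh
        moved <- FALSE
        for (try in 1:20) {
          hh <- base_h + stats::rnorm(1, 0, behaviour$turn_sd[st])
          sp <- stats::rlnorm(1, behaviour$speed_meanlog[st],
                              behaviour$speed_sdlog[st])
          stp <- min(sp, 3) * 3600
          cand <- pos + stp * c(sin(hh * pi / 180), cos(hh * pi / 180))
          if (!fast_pip(cand[1], cand[2], land_segs)) {
            pos <- cand; h <- hh; moved <- TRUE; break
          }
        }
        if (!moved) {
          hh <- base_h + 180
          sp <- stats::rlnorm(1, behaviour$speed_meanlog[st],
                              behaviour$speed_sdlog[st])
          cand <- pos + min(sp, 3) * 3600 *
            c(sin(hh * pi / 180), cos(hh * pi / 180))
          if (!fast_pip(cand[1], cand[2], land_segs)) { pos <- cand; h <- hh }
        }
        P[t, ] <- pos
        S[t] <- st
      }
      ll <- proj_inv(proj, P[, 1], P[, 2])
      res[[id]] <- data.frame(animal_id = id, timestamp = tstamp,
                              lon = ll[, 1], lat = ll[, 2],
                              state = states[S])
    })
  }
  truth <- do.call(rbind, res)
  rownames(truth) <- NULL
  truth <- classify_habitat(truth, model)
  truth$habitat <- as.character(truth$habitat)
  budgets <- summarize_time_budget(
    transform(truth, habitat = factor(habitat, levels = HABITAT_CLASSES)),
    by = "animal")
  structure(list(truth = truth, budgets = budgets, model = model,
                 behaviour = behaviour),
            class = "sim_truth")
}

#' Thin and perturb a true track into Argos-like fixes
#'
#' Observation times follow an exponential-gap process (mean
#' `mean_interval` hours) snapped to the truth's hourly grid; each retained
#' fix draws a location class from `lc_mix` and is displaced uniformly in
#' the disc of that class's error radius (class Z uses the class-B radius).
#' With coastal truth this places a realistic share of fixes on land.
#'
#' @param truth a `sim_truth` from [simulate_tracks()].
#' @param lc_mix named probabilities over classes 3,2,1,A,B,Z (sum 1).
#' @param lc_errors an [lc_error_table()].
#' @param mean_interval mean hours between uplinks (> 0).
#' @param seed global seed.
#' @return Argos track data.frame (animal_id, timestamp, lon, lat, lc).
#' @export
observe_argos <- function(truth,
                          lc_mix = c("3" = 0.08, "2" = 0.12, "1" = 0.2,
                                     "A" = 0.25, "B" = 0.32, "Z" = 0.03),
                          lc_errors = lc_error_table(),
                          mean_interval = 2, seed = 1) {
  if (mean_interval <= 0) stop("mean_interval must be > 0", call. = FALSE)
  if (abs(sum(lc_mix) - 1) > 1e-9) stop("lc_mix must sum to 1", call. = FALSE)
  stopifnot(all(names(lc_mix) %in% LC_LEVELS))
  tr <- truth$truth
  out <- list()
  for (id in unique(tr$animal_id)) {
    ta <- tr[tr$animal_id == id, , drop = FALSE]
    n_h <- nrow(ta)
    with_seed(derive_seed(seed + 7L, id), {
      gaps <- stats::rexp(ceiling(2 * n_h / mean_interval) + 10,
                          rate = 1 / mean_interval)
      times <- unique(pmin(n_h, pmax(1, round(cumsum(gaps)))))
      times <- times[times <= n_h]
      if (!length(times)) times <- 1L
      lc <- sample(names(lc_mix), length(times), replace = TRUE,
                   prob = lc_mix)
      rad <- unname(lc_errors[ifelse(lc == "Z", "B", lc)])
      r <- rad * sqrt(stats::runif(length(times)))
      th <- stats::runif(length(times), 0, 2 * pi)
      lon <- numeric(length(times)); lat <- numeric(length(times))
      for (i in seq_along(times)) {
        pr <- local_proj(c(ta$lon[times[i]], ta$lat[times[i]]))
        ll <- proj_inv(pr, r[i] * cos(th[i]), r[i] * sin(th[i]))
        lon[i] <- ll[1]; lat[i] <- ll[2]
      }
      out[[id]] <- data.frame(animal_id = id,
                              timestamp = ta$timestamp[times],
                              lon = lon, lat = lat, lc = lc)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Seasonal sea-ice fields as coastal bands
#'
#' Before the freeze onset every point is Open Water (an empty field).
#' After onset a fast-ice band grows outward from the island, with drift-ice
#' classes banded seaward of it; coverage is non-decreasing in date. Bands
#' are expanded bounding boxes of the land - crude, but valid typed
#' polygons that exercise point-in-polygon and nearest-day logic.
#'
#' @param model a [coast_model()].
#' @param dates Date vector (sorted).
#' @param onset_date first freezing date.
#' @param seed unused placeholder for interface stability.
#' @return list of ice fields (`date`, `polygons`, `types`).
#' @export
make_ice_fields <- function(model, dates, onset_date, seed = 1) {
  dates <- as.Date(dates)
  if (is.unsorted(dates)) stop("dates must be sorted", call. = FALSE)
  onset_date <- as.Date(onset_date)
  all_lon <- unlist(lapply(model$land, function(p) p[[1]][, 1]))
  all_lat <- unlist(lapply(model$land, function(p) p[[1]][, 2]))
  proj <- track_proj(all_lon, all_lat)
  xy <- proj_fwd(proj, all_lon, all_lat)
  bb <- c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
  box <- function(pad_m) {
    m <- rbind(c(bb[1] - pad_m, bb[2] - pad_m), c(bb[3] + pad_m, bb[2] - pad_m),
               c(bb[3] + pad_m, bb[4] + pad_m), c(bb[1] - pad_m, bb[4] + pad_m),
               c(bb[1] - pad_m, bb[2] - pad_m))
    as_polygon(proj_inv(proj, m[, 1], m[, 2]))
  }
  lapply(dates, function(d) {
    prog <- as.numeric(d - onset_date)
    if (prog < 0) return(list(date = d, polygons = list(), types = character(0)))
    w_fast <- min(200 * prog, 12000)             # fast ice: up to 12 km out
    w_band <- 6000 + 100 * prog                  # each drift band
    pads <- w_fast + w_band * (1:4)
    list(date = d,
         polygons = c(list(box(w_fast)), lapply(pads, box)),
         types = c("Fast ice", "Very Close Drift Ice", "Close Drift Ice",
                   "Open Drift Ice", "Very Open Drift Ice"))
  })
}

#' Shipped simulation fixtures
#'
#' Two self-contained parameter bundles mirroring the two study periods:
#' `fixture_period1` has fewer-quality tags (larger error radii, sparser
#' uplinks), shorter records around 51 days, 18 animals, early freeze
#' onset and epoch-1 geometry; `fixture_period2` has 16 animals, records
#' around 87 days, smaller radii, denser uplinks, later onset and
#' epoch-2 (retreated) geometry.
#'
#' @param n_animals,mean_days overrides for scaled-down test runs.
#' @return a `fixture` list of generator arguments.
#' @export
fixture_period1 <- function(n_animals = 18, mean_days = 51) {
  list(name = "period1", epoch = "epoch1", n_animals = n_animals,
       mean_days = mean_days, sd_days = 31, min_days = 2, max_days = 163,
       start_date = as.POSIXct("1999-07-20", tz = "UTC"),
       stagger_days = 4,
       lc_mix = c("3" = 0.04, "2" = 0.08, "1" = 0.16, "A" = 0.27,
                  "B" = 0.41, "Z" = 0.04),
       lc_errors = lc_error_table(c("3" = 500, "2" = 1000, "1" = 2000,
                                    "A" = 4000, "B" = 8000)),
       mean_interval = 3,
       behaviour = behaviour_spec(offshore_onset_day = 100,
                                  period = "1995-2001"),
       onset_date = as.Date("1999-10-15"))
}

#' @rdname fixture_period1
#' @export
fixture_period2 <- function(n_animals = 16, mean_days = 87) {
  list(name = "period2", epoch = "epoch2", n_animals = n_animals,
       mean_days = mean_days, sd_days = 52, min_days = 2, max_days = 163,
       start_date = as.POSIXct("2014-07-20", tz = "UTC"),
       stagger_days = 4,
       lc_mix = c("3" = 0.05, "2" = 0.08, "1" = 0.14, "A" = 0.25,
                  "B" = 0.45, "Z" = 0.03),
       lc_errors = lc_error_table(c("3" = 250, "2" = 500, "1" = 1500,
                                    "A" = 3000, "B" = 6000)),
       mean_interval = 1.5,
       behaviour = behaviour_spec(offshore_onset_day = 130,
                                  period = "2013-2016"),
       onset_date = as.Date("2014-11-15"))
}

#' Run a fixture end to end
#'
#' Builds the archipelago, simulates tracks with per-animal durations drawn
#' around the fixture's mean, observes them through the Argos error model
#' and generates matching ice fields.
#'
#' @param fixture from [fixture_period1()] / [fixture_period2()].
#' @param seed global seed.
#' @param arch_spec optional [archipelago_spec()] override.
#' @return list: `model` (coast model for the fixture's epoch), `truth`,
#'   `argos`, `ice`, `fixture`.
#' @export
simulate_fixture <- function(fixture, seed = 1, arch_spec = archipelago_spec()) {
  arch <- make_archipelago(arch_spec)
  model <- arch[[fixture$epoch]]
  days <- with_seed(seed + 13L, pmin(fixture$max_days, pmax(
    fixture$min_days,
    round(stats::rnorm(fixture$n_animals, fixture$mean_days,
                       fixture$sd_days)))))
  starts <- fixture$start_date +
    86400 * fixture$stagger_days * (seq_len(fixture$n_animals) - 1)
  truth <- simulate_tracks(model, fixture$behaviour, fixture$n_animals,
                           days, seed = seed, start_dates = starts,
                           id_prefix = paste0(fixture$name, "-"))
  truth$truth$period <- fixture$behaviour$period
  argos <- observe_argos(truth, lc_mix = fixture$lc_mix,
                         lc_errors = fixture$lc_errors,
                         mean_interval = fixture$mean_interval, seed = seed)
  date_rng <- range(as.Date(truth$truth$timestamp, tz = "UTC"))
  ice_dates <- seq(date_rng[1], date_rng[2], by = "7 days")
  ice <- make_ice_fields(model, ice_dates, fixture$onset_date, seed = seed)
  list(model = model, truth = truth, argos = argos, ice = ice,
       fixture = fixture)
}
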