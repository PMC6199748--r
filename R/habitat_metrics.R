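# Per-hour habitat classification against epoch geometry, sea-ice joining,
# movement metrics (speed, turning angle) and time-budget summaries.

#' Habitat classification configuration
#' @param radius_threshold km; distance below which a location is tied to a
#'   glacier front or to the coast (default 5, chosen to absorb combined
#'   Argos and geometry errors).
#' @return a `habitat_config` object.
#' @export
habitat_config <- function(radius_threshold = 5) {
  stopifnot(radius_threshold > 0)
  structure(list(radius_threshold = radius_threshold),
            class = "habitat_config")
}

#' Days since the most recent 7 July
#'
#' Season index anchored at the earliest tagging date of the study design
#' (7 July). The index wraps at the NEXT 7 July, so mid-winter values run
#' past 150-210 instead of resetting at New Year.
#' @param timestamp POSIXct (UTC) vector.
#' @return integer vector, >= 0.
#' @export
day_index <- function(timestamp) {
  d <- as.Date(timestamp, tz = "UTC")
  y <- as.integer(format(d, "%Y"))
  anchor <- as.Date(sprintf("%d-07-07", y))
  anchor[d < anchor] <- as.Date(sprintf("%d-07-07", y[d < anchor] - 1L))
  as.integer(d - anchor)
}

#' Hourly movement metrics: speed and turning angle
#'
#' Within runs of consecutive hourly locations, speed at location i is the
#' geodesic distance from i-1 divided by elapsed seconds (m/s); the turning
#' angle at i is the unsigned deviation between the heading into i and the
#' heading out of i, in [0, 180] degrees (0 = straight ahead). Speed is
#' missing at segment starts, turn at segment starts and ends. Gaps longer
#' than the hourly step break a segment.
#'
#' @param hourly data.frame (animal_id, timestamp, lon, lat), time-sorted.
#' @param step expected spacing in seconds (default 3600).
#' @return `hourly` with `speed` and `turn` columns added.
#' @export
movement_metrics <- function(hourly, step = 3600) {
  hourly$speed <- NA_real_
  hourly$turn <- NA_real_
  if (!nrow(hourly)) return(hourly)
  for (id in unique(hourly$animal_id)) {
    sel <- which(hourly$animal_id == id)
    tr <- hourly[sel, , drop = FALSE]
    tsec <- as.numeric(tr$timestamp)
    n <- nrow(tr)
    prev_ok <- c(FALSE, diff(tsec) == step)
    next_ok <- c(prev_ok[-1], FALSE)
    sp <- rep(NA_real_, n)
    if (any(prev_ok)) {
      i <- which(prev_ok)
      sp[i] <- geodesic_distance(tr$lon[i - 1], tr$lat[i - 1],
                                 tr$lon[i], tr$lat[i]) / step
    }
    tu <- rep(NA_real_, n)
    for (i in which(prev_ok & next_ok)) {
      proj <- local_proj(c(tr$lon[i], tr$lat[i]))
      a <- proj_fwd(proj, tr$lon[i - 1], tr$lat[i - 1])
      b <- proj_fwd(proj, tr$lon[i + 1], tr$lat[i + 1])
      h_in <- atan2(-a[1], -a[2])       # heading from i-1 into i
      h_out <- atan2(b[1], b[2])        # heading from i to i+1
      dev <- abs(h_out - h_in) * 180 / pi
      if (length(dev) && !is.na(dev)) {
        if (dev > 180) dev <- 360 - dev
        if (sqrt(sum(a^2)) > 0 && sqrt(sum(b^2)) > 0) tu[i] <- dev
      }
    }
    hourly$speed[sel] <- sp
    hourly$turn[sel] <- tu
  }
  hourly
}

#' Classify hourly locations into the four habitat classes
#'
#' Precedence: Glacier-Fronts (distance to nearest glacier front strictly
#' below the threshold), then Fjords (inside a fjord polygon), then Coastal
#' (distance to nearest coastline strictly below the threshold), then
#' At-Sea. Both spatial metrics (km) are reported.
#'
#' @param hourly data.frame with lon/lat columns.
#' @param model a [coast_model()] with non-empty coastline, glacier-front
#'   and fjord layers.
#' @param cfg a [habitat_config()].
#' @return `hourly` with `dist_coast`, `dist_glacier` (km) and `habitat`
#'   (factor with levels `HABITAT_CLASSES`) columns added.
#' @export
classify_habitat <- function(hourly, model, cfg = habitat_config()) {
  if (!length(model$glacier_fronts))
    stop("coast model has no glacier-front layer", call. = FALSE)
  if (!length(model$fjords))
    stop("coast model has no fjord layer", call. = FALSE)
  if (!length(model$coastline))
    stop("coast model has no coastline layer", call. = FALSE)
  if (!nrow(hourly)) {
    hourly$dist_coast <- hourly$dist_glacier <- numeric(0)
    hourly$habitat <- factor(character(0), levels = HABITAT_CLASSES)
    return(hourly)
  }
  proj <- track_proj(hourly$lon, hourly$lat)
  dg <- distances_to_lines(hourly$lon, hourly$lat, model$glacier_fronts, proj)
  dc <- distances_to_lines(hourly$lon, hourly$lat, model$coastline, proj)
  infj <- point_in_fjord(hourly$lon, hourly$lat, model)
  thr <- cfg$radius_threshold
  hab <- ifelse(dg < thr, "Glacier-Fronts",
         ifelse(infj, "Fjords",
         ifelse(dc < thr, "Coastal", "At-Sea")))
  hourly$dist_coast <- dc
  hourly$dist_glacier <- dg
  hourly$habitat <- factor(hab, levels = HABITAT_CLASSES)
  hourly
}

#' Join sea-ice type onto hourly locations
#'
#' Uses the ice field whose date is nearest to the location's date (ties go
#' to the earlier field). Within a field, the first typed polygon containing
#' the point wins; points outside all coverage are Open Water.
#'
#' @param hourly data.frame with timestamp/lon/lat.
#' @param fields list of ice fields (`date`, `polygons`, `types`), e.g. from
#'   [make_ice_fields()] or [read_ice_geojson()].
#' @return `hourly` with an `ice_type` factor column added.
#' @export
assign_ice_type <- function(hourly, fields) {
  if (!length(fields)) stop("empty ice field set", call. = FALSE)
  dates <- as.Date(vapply(fields, function(f) as.character(f$date), ""))
  pd <- as.Date(hourly$timestamp, tz = "UTC")
  ice <- rep("Open Water", nrow(hourly))
  if (nrow(hourly)) {
    # nearest field per point; tie -> earlier date (fields sorted by date)
    ord <- order(dates)
    dates <- dates[ord]; fields <- fields[ord]
    idx <- vapply(as.numeric(pd), function(x) {
      dd <- abs(as.numeric(dates) - x)
      which(dd == min(dd))[1]
    }, integer(1))
    for (k in unique(idx)) {
      sel <- which(idx == k)
      f <- fields[[k]]
      if (!length(f$polygons)) next
      assigned <- rep(FALSE, length(sel))
      for (j in seq_along(f$polygons)) {
        todo <- sel[!assigned]
        if (!length(todo)) break
        hit <- points_in_polygons(hourly$lon[todo], hourly$lat[todo],
                                  list(f$polygons[[j]]),
                                  boundary_is_inside = TRUE)
        ice[todo[hit]] <- f$types[j]
        assigned[match(todo[hit], sel)] <- TRUE
      }
    }
  }
  hourly$ice_type <- factor(ice, levels = ICE_TYPES)
  hourly
}

#' Per-hour occupancy indicators
#'
#' One-hot encodes the habitat class of each hourly location and attaches
#' the day-of-season index ([day_index()]).
#'
#' @param classified output of [classify_habitat()], with a `period` column
#'   (optional; carried through when present).
#' @return data.frame with binary columns `occ_glacier`, `occ_fjords`,
#'   `occ_coastal`, `occ_atsea` plus `day_index`.
#' @export
occupancy_series <- function(classified) {
  stopifnot("habitat" %in% names(classified))
  out <- classified
  out$occ_glacier <- as.integer(classified$habitat == "Glacier-Fronts")
  out$occ_fjords <- as.integer(classified$habitat == "Fjords")
  out$occ_coastal <- as.integer(classified$habitat == "Coastal")
  out$occ_atsea <- as.integer(classified$habitat == "At-Sea")
  out$day_index <- day_index(classified$timestamp)
  out
}

#' Time-budget summaries over habitat (or ice) classes
#'
#' Proportion of hourly locations per class, pooled or grouped by animal,
#' calendar month (UTC) or period. Proportions sum to 1 within each group;
#' the number of animals contributing at least one location to the group is
#' reported.
#'
#' @param classified data.frame with `habitat` (or `ice_type`) and
#'   `animal_id`, `timestamp`, optionally `period` columns.
#' @param by grouping: "pooled", "animal", "month" or "period".
#' @param what "habitat" or "ice".
#' @return long data.frame (group, class, n, proportion, n_animals).
#' @export
summarize_time_budget <- function(classified,
                                  by = c("pooled", "animal", "month", "period"),
                                  what = c("habitat", "ice")) {
  by <- match.arg(by); what <- match.arg(what)
  col <- if (what == "habitat") "habitat" else "ice_type"
  lev <- if (what == "habitat") HABITAT_CLASSES else ICE_TYPES
  if (!col %in% names(classified)) stop("column ", col, " missing", call. = FALSE)
  grp <- switch(by,
    pooled = rep("(all)", nrow(classified)),
    animal = as.character(classified$animal_id),
    month = format(classified$timestamp, "%Y-%m", tz = "UTC"),
    period = as.character(classified$period))
  out <- list()
  for (g in sort(unique(grp))) {
    sel <- grp == g
    n_tot <- sum(sel)
    if (n_tot == 0) { warning("empty group ", g, " omitted"); next }
    tab <- table(factor(as.character(classified[[col]][sel]), levels = lev))
    out[[g]] <- data.frame(
      group = g, class = factor(lev, levels = lev),
      n = as.integer(tab), proportion = as.numeric(tab) / n_tot,
      n_animals = length(unique(classified$animal_id[sel])))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
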