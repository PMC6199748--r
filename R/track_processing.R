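# Three-stage track filtration: speed-distance-angle (SDA) filter, particle
# correction of on-land fixes, and hourly along-track interpolation.
#
# An Argos track is a data.frame with columns animal_id (character),
# timestamp (POSIXct, UTC), lon, lat (degrees) and lc (one of 3,2,1,A,B,Z),
# time-sorted within animal.

#' SDA filter configuration
#'
#' @param vmax sustained-swim-speed ceiling, m/s (default 3).
#' @param spike_rules list of c(max_angle_deg, min_leg_km) pairs; a spike
#'   (out-and-back triple) is removable when its apex angle is below
#'   max_angle and both legs exceed min_leg. Defaults: (15, 2.5), (25, 5).
#' @param max_skip implementation bound on consecutive interior removals
#'   considered by the exact search (default 10; any real track needs far
#'   fewer).
#' @return an `sda_config` object.
#' @export
sda_config <- function(vmax = 3,
                       spike_rules = list(c(15, 2.5), c(25, 5)),
                       max_skip = 10L) {
  stopifnot(vmax > 0, max_skip >= 1)
  for (r in spike_rules) stopifnot(length(r) == 2, r[1] > 0, r[2] > 0)
  structure(list(vmax = vmax, spike_rules = spike_rules,
                 max_skip = as.integer(max_skip)), class = "sda_config")
}

#' Per-location-class Argos error radii
#'
#' Radii (metres) indexed by location class. The literature does not pin a
#' single canonical table; these defaults are typical published magnitudes
#' and should be replaced with period-specific values where known. Radii
#' must be non-increasing with quality: B >= A >= 1 >= 2 >= 3.
#'
#' @param radii named numeric vector over classes "3","2","1","A","B".
#' @return named numeric vector of class `lc_error_table`.
#' @export
lc_error_table <- function(radii = c("3" = 250, "2" = 500, "1" = 1500,
                                     "A" = 2500, "B" = 5000)) {
  need <- c("3", "2", "1", "A", "B")
  if (!all(need %in% names(radii)))
    stop("lc error table must cover classes 3,2,1,A,B", call. = FALSE)
  radii <- radii[need]
  if (any(radii <= 0)) stop("error radii must be > 0", call. = FALSE)
  if (any(diff(unname(radii)) < 0))
    stop("error radii must be non-increasing from B to 3", call. = FALSE)
  structure(radii, class = "lc_error_table")
}

#' On-land particle correction configuration
#' @param n_particles particles drawn per on-land fix (default 50).
#' @param seed global RNG seed; per-animal streams are derived from it.
#' @param lc_errors an [lc_error_table()].
#' @return a `correction_config` object.
#' @export
correction_config <- function(n_particles = 50L, seed = 1L,
                              lc_errors = lc_error_table()) {
  stopifnot(n_particles >= 1)
  structure(list(n_particles = as.integer(n_particles),
                 seed = as.integer(seed), lc_errors = lc_errors),
            class = "correction_config")
}

#' Interpolation configuration
#' @param step output spacing in seconds (default 3600 = 1 h).
#' @param max_gap gaps longer than this (seconds) are not interpolated
#'   (default 12 h).
#' @return an `interp_config` object.
#' @export
interp_config <- function(step = 3600, max_gap = 12 * 3600) {
  stopifnot(step > 0, step <= max_gap)
  structure(list(step = step, max_gap = max_gap), class = "interp_config")
}

check_track_df <- function(track) {
  need <- c("animal_id", "timestamp", "lon", "lat", "lc")
  if (!all(need %in% names(track)))
    stop("track must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!inherits(track$timestamp, "POSIXct"))
    stop("timestamp must be POSIXct", call. = FALSE)
  for (id in unique(track$animal_id)) {
    tt <- track$timestamp[track$animal_id == id]
    if (is.unsorted(tt, strictly = TRUE))
      stop("track not strictly time-sorted for animal ", id, call. = FALSE)
  }
  invisible(TRUE)
}

# ---- SDA filter -------------------------------------------------------------

# Validity of the kept subsequence is local to consecutive kept triples
# (p, i, n): a kept fix may not need speed > vmax from BOTH kept neighbours,
# nor form an out-and-back spike under any rule. The filter computes the
# maximum-retention subsequence satisfying this (ties: keep earliest fixes),
# by dynamic programming over the last two kept indices with a bounded
# interior skip window. The result is a fixed point: re-filtering removes
# nothing.
sda_one <- function(xy, tsec, cfg) {
  n <- nrow(xy)
  if (n <= 2) return(seq_len(n))
  w <- min(cfg$max_skip + 1L, n - 1L)
  # pairwise distances d[i, k] between fix i and fix i+k, k = 1..w
  dmat <- matrix(NA_real_, n, w)
  for (k in seq_len(w)) {
    idx <- seq_len(n - k)
    dmat[idx, k] <- sqrt((xy[idx + k, 1] - xy[idx, 1])^2 +
                         (xy[idx + k, 2] - xy[idx, 2])^2)
  }
  dist_ij <- function(i, j) dmat[i, j - i]
  speed_ij <- function(i, j) {
    dt <- tsec[j] - tsec[i]
    if (dt <= 0) Inf else dist_ij(i, j) / dt
  }
  triple_ok <- function(p, i, q) {
    if (p == 0L) return(TRUE)
    if (speed_ij(p, i) > cfg$vmax && speed_ij(i, q) > cfg$vmax) return(FALSE)
    v1 <- xy[p, ] - xy[i, ]; v2 <- xy[q, ] - xy[i, ]
    l1 <- dist_ij(p, i); l2 <- dist_ij(i, q)
    if (l1 > 0 && l2 > 0) {
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (l1 * l2)))) * 180 / pi
      for (r in cfg$spike_rules)
        if (ang < r[1] && l1 / 1000 > r[2] && l2 / 1000 > r[2]) return(FALSE)
    }
    TRUE
  }
  # g[[j]][p+1] = max kept count from j onward given previous kept fix p
  # (p = 0 means j is the first kept fix); computed right to left
  g <- vector("list", n)
  for (j in n:1) {
    prevs <- c(0L, if (j > 1L) seq.int(max(1L, j - w), j - 1L) else integer(0))
    gj <- numeric(length(prevs))
    names(gj) <- prevs
    nexts <- if (j < n) seq.int(j + 1L, min(n, j + w)) else integer(0)
    for (ip in seq_along(prevs)) {
      p <- prevs[ip]
      best <- 1  # j may be the last kept fix
      for (q in nexts) {
        if (triple_ok(p, j, q)) {
          cand <- 1 + g[[q]][as.character(j)]
          if (!is.na(cand) && cand > best) best <- cand
        }
      }
      gj[ip] <- best
    }
    g[[j]] <- gj
  }
  starts <- vapply(seq_len(n), function(j) g[[j]]["0"], numeric(1))
  best <- max(starts)
  # reconstruct lexicographically smallest optimal kept sequence
  kept <- integer(0)
  j <- which(starts == best)[1]
  p <- 0L
  kept <- j
  remaining <- best - 1
  while (remaining > 0) {
    found <- FALSE
    for (q in (if (j < n) seq.int(j + 1L, min(n, j + w)) else integer(0))) {
      if (triple_ok(p, j, q) &&
          !is.na(g[[q]][as.character(j)]) &&
          g[[q]][as.character(j)] == remaining) {
        kept <- c(kept, q); p <- j; j <- q
        remaining <- remaining - 1; found <- TRUE; break
      }
    }
    if (!found) stop("internal error: SDA reconstruction failed")
  }
  kept
}

#' Speed-distance-angle filter for Argos tracks
#'
#' Removes every class-Z fix, then the smallest set of fixes such that no
#' kept fix needs speed above `vmax` from both kept neighbours and no kept
#' interior fix forms an out-and-back spike (apex angle below a rule's
#' threshold with both legs longer than the rule's minimum). The retained
#' set is maximal; ties prefer keeping earlier fixes. Distances and angles
#' are computed in a local azimuthal equidistant projection centred on each
#' animal's track.
#'
#' @param track Argos track data.frame (may hold several animals).
#' @param cfg an [sda_config()].
#' @return list with `kept` (the filtered track) and `removed` (removed rows
#'   with a `reason` column: "LC Z", "speed", "spike" or "SDA").
#' @export
sda_filter <- function(track, cfg = sda_config()) {
  check_track_df(track)
  if (nrow(track) == 0)
    return(list(kept = track, removed = cbind(track, reason = character(0))))
  res_kept <- list(); res_rem <- list()
  for (id in unique(track$animal_id)) {
    tr <- track[track$animal_id == id, , drop = FALSE]
    isZ <- tr$lc == "Z"
    remZ <- tr[isZ, , drop = FALSE]
    if (nrow(remZ)) remZ$reason <- "LC Z"
    tr2 <- tr[!isZ, , drop = FALSE]
    if (nrow(tr2) == 0) {
      warning("all fixes removed for animal ", id)
      res_rem[[id]] <- remZ
      next
    }
    proj <- track_proj(tr2$lon, tr2$lat)
    xy <- proj_fwd(proj, tr2$lon, tr2$lat)
    tsec <- as.numeric(tr2$timestamp)
    kept_idx <- sda_one(xy, tsec, cfg)
    rem_idx <- setdiff(seq_len(nrow(tr2)), kept_idx)
    rem <- tr2[rem_idx, , drop = FALSE]
    if (nrow(rem))
      rem$reason <- vapply(rem_idx, function(i)
        removal_reason(i, kept_idx, xy, tsec, cfg), character(1))
    kept <- tr2[kept_idx, , drop = FALSE]
    both <- rbind(remZ, rem)
    both <- both[order(both$timestamp), , drop = FALSE]
    res_kept[[id]] <- kept
    res_rem[[id]] <- both
  }
  kept <- do.call(rbind, res_kept)
  removed <- do.call(rbind, res_rem)
  if (is.null(kept)) kept <- track[0, , drop = FALSE]
  if (is.null(removed)) removed <- cbind(track[0, , drop = FALSE],
                                         reason = character(0))
  rownames(kept) <- NULL; rownames(removed) <- NULL
  if (nrow(kept) == 0) warning("all fixes removed by SDA filter")
  list(kept = kept, removed = removed)
}

# label a removed fix by the condition it violates against its kept
# neighbours (diagnostic only; the kept set is defined by the search)
removal_reason <- function(i, kept_idx, xy, tsec, cfg) {
  p <- max(c(0L, kept_idx[kept_idx < i]))
  q <- min(c(nrow(xy) + 1L, kept_idx[kept_idx > i]))
  if (p == 0L || q > nrow(xy)) return("SDA")
  d1 <- sqrt(sum((xy[i, ] - xy[p, ])^2))
  d2 <- sqrt(sum((xy[q, ] - xy[i, ])^2))
  s1 <- d1 / max(tsec[i] - tsec[p], 1e-9)
  s2 <- d2 / max(tsec[q] - tsec[i], 1e-9)
  v1 <- xy[p, ] - xy[i, ]; v2 <- xy[q, ] - xy[i, ]
  if (d1 > 0 && d2 > 0) {
    ang <- acos(min(1, max(-1, sum(v1 * v2) / (d1 * d2)))) * 180 / pi
    for (r in cfg$spike_rules)
      if (ang < r[1] && d1 / 1000 > r[2] && d2 / 1000 > r[2]) return("spike")
  }
  if (s1 > cfg$vmax && s2 > cfg$vmax) return("speed")
  "SDA"
}

# ---- particle correction ----------------------------------------------------

#' Correct on-land fixes with a simplified particle filter
#'
#' Each on-land fix spawns `n_particles` points uniform in the disc of its
#' class error radius (in a local projection centred on the fix); the fix is
#' replaced by the mean of the at-sea particles. Fixes with no at-sea
#' particle, or whose corrected position is still on land, are removed.
#' At-sea fixes pass through untouched. One RNG stream per animal, derived
#' from the global seed, so results do not depend on batch composition.
#'
#' @param track SDA-filtered Argos track (no class Z).
#' @param model a [coast_model()].
#' @param cfg a [correction_config()].
#' @return list with `track` (corrected fixes, plus a `provenance` column
#'   "original"/"particle-corrected"), `removed` (with `reason`), and
#'   `n_onland` (count of fixes that started on land).
#' @export
correct_onland <- function(track, model, cfg = correction_config()) {
  check_track_df(track)
  if (any(track$lc == "Z")) stop("track contains class Z; run sda_filter first",
                                 call. = FALSE)
  miss <- setdiff(unique(track$lc), names(cfg$lc_errors))
  if (length(miss))
    stop("no error radius for location class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- list(); rem <- list()
  for (id in unique(track$animal_id)) {
    tr <- track[track$animal_id == id, , drop = FALSE]
    onland <- point_on_land(tr$lon, tr$lat, model)
    tr$provenance <- ifelse(onland, NA_character_, "original")
    keep <- rep(TRUE, nrow(tr))
    reason <- rep(NA_character_, nrow(tr))
    with_seed(derive_seed(cfg$seed, id), {
      for (i in which(onland)) {
        R <- unname(cfg$lc_errors[tr$lc[i]])
        r <- R * sqrt(stats::runif(cfg$n_particles))
        th <- stats::runif(cfg$n_particles, 0, 2 * pi)
        px <- r * cos(th); py <- r * sin(th)
        proj <- local_proj(c(tr$lon[i], tr$lat[i]))
        ll <- proj_inv(proj, px, py)
        atsea <- !point_on_land(ll[, 1], ll[, 2], model)
        if (!any(atsea)) {
          keep[i] <- FALSE; reason[i] <- "no at-sea particles"; next
        }
        ctr <- proj_inv(proj, mean(px[atsea]), mean(py[atsea]))
        if (point_on_land(ctr[1], ctr[2], model)) {
          keep[i] <- FALSE; reason[i] <- "still on land"; next
        }
        tr$lon[i] <- ctr[1]; tr$lat[i] <- ctr[2]
        tr$provenance[i] <- "particle-corrected"
      }
    })
    r <- tr[!keep, , drop = FALSE]
    if (nrow(r)) { r$reason <- reason[!keep]; r$provenance <- NULL }
    out[[id]] <- tr[keep, , drop = FALSE]
    rem[[id]] <- r
    attr(out, "n_onland") <- c(attr(out, "n_onland"), sum(onland))
  }
  n_onland <- sum(attr(out, "n_onland"))
  track2 <- do.call(rbind, out); rownames(track2) <- NULL
  removed <- do.call(rbind, rem)
  if (is.null(removed))
    removed <- cbind(track[0, , drop = FALSE], reason = character(0))
  rownames(removed) <- NULL
  list(track = track2, removed = removed, n_onland = n_onland)
}

# ---- hourly interpolation ---------------------------------------------------

#' Interpolate a corrected track onto the whole-hour grid
#'
#' Linear interpolation in a local projection between consecutive fixes.
#' Output timestamps are whole UTC hours inside each between-fix segment; no
#' points are generated inside gaps longer than `max_gap`; interpolated
#' points that land on shore are dropped. Original fix times off the hour
#' grid do not appear in the output.
#'
#' @param track corrected Argos track (all at sea), one or more animals.
#' @param model a [coast_model()] used to drop on-land interpolations.
#' @param cfg an [interp_config()].
#' @return data.frame (animal_id, timestamp, lon, lat) of hourly locations;
#'   attributes `n_generated` and `n_dropped` carry interpolation
#'   bookkeeping.
#' @export
interpolate_hourly <- function(track, model, cfg = interp_config()) {
  trk_chk <- track
  if (!"lc" %in% names(trk_chk)) trk_chk$lc <- "3"
  check_track_df(trk_chk)
  res <- list(); n_gen <- 0L; n_drop <- 0L
  for (id in unique(track$animal_id)) {
    tr <- track[track$animal_id == id, , drop = FALSE]
    if (nrow(tr) < 2) {
      warning("animal ", id, ": fewer than 2 fixes, nothing to interpolate")
      next
    }
    proj <- track_proj(tr$lon, tr$lat)
    xy <- proj_fwd(proj, tr$lon, tr$lat)
    tsec <- as.numeric(tr$timestamp)
    ts_all <- numeric(0); xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(nrow(tr) - 1)) {
      dt <- tsec[i + 1] - tsec[i]
      if (dt > cfg$max_gap) next
      h1 <- ceiling(tsec[i] / cfg$step - 1e-9) * cfg$step
      h2 <- floor(tsec[i + 1] / cfg$step + 1e-9) * cfg$step
      if (h2 < h1) next
      hs <- seq(h1, h2, by = cfg$step)
      f <- if (dt == 0) rep(0, length(hs)) else (hs - tsec[i]) / dt
      ts_all <- c(ts_all, hs)
      xs <- c(xs, xy[i, 1] + f * (xy[i + 1, 1] - xy[i, 1]))
      ys <- c(ys, xy[i, 2] + f * (xy[i + 1, 2] - xy[i, 2]))
    }
    if (!length(ts_all)) next
    dup <- duplicated(ts_all)
    ts_all <- ts_all[!dup]; xs <- xs[!dup]; ys <- ys[!dup]
    ll <- proj_inv(proj, xs, ys)
    n_gen <- n_gen + length(ts_all)
    land <- point_on_land(ll[, 1], ll[, 2], model)
    n_drop <- n_drop + sum(land)
    if (all(land)) next
    res[[id]] <- data.frame(
      animal_id = id,
      timestamp = as.POSIXct(ts_all[!land], origin = "1970-01-01", tz = "UTC"),
      lon = ll[!land, 1], lat = ll[!land, 2])
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(animal_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      lon = numeric(0), lat = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_generated") <- n_gen
  attr(out, "n_dropped") <- n_drop
  out
}

# ---- report -----------------------------------------------------------------

#' Stage-by-stage processing bookkeeping
#'
#' Reconciles the four pipeline stages and reports, pooled and per animal:
#' raw fix count, SDA removals by reason, on-land count and integer
#' percentage of all fixes, successfully-corrected percentage of on-land
#' fixes, removals after correction, and interpolated-point count with
#' percentage dropped on land.
#'
#' @param raw the raw Argos track.
#' @param filtered the [sda_filter()] result.
#' @param corrected the [correct_onland()] result.
#' @param interpolated the [interpolate_hourly()] result.
#' @return data.frame, one row per animal plus a "(all)" row.
#' @export
processing_report <- function(raw, filtered, corrected, interpolated) {
  if (nrow(raw) != nrow(filtered$kept) + nrow(filtered$removed))
    stop("internal error: SDA counts do not reconcile", call. = FALSE)
  if (nrow(filtered$kept) != nrow(corrected$track) + nrow(corrected$removed))
    stop("internal error: correction counts do not reconcile", call. = FALSE)
  ids <- unique(raw$animal_id)
  row_for <- function(id) {
    rawn <- if (id == "(all)") nrow(raw) else sum(raw$animal_id == id)
    sel <- function(df) if (id == "(all)") df else
      df[df$animal_id == id, , drop = FALSE]
    remf <- sel(filtered$removed)
    corr <- sel(corrected$track)
    remc <- sel(corrected$removed)
    onland <- sum(corr$provenance == "particle-corrected") + nrow(remc)
    ngen <- attr(interpolated, "n_generated")
    ndrop <- attr(interpolated, "n_dropped")
    data.frame(
      animal_id = id, n_raw = rawn,
      n_removed_lcz = sum(remf$reason == "LC Z"),
      n_removed_sda = sum(remf$reason != "LC Z"),
      n_onland = onland,
      pct_onland = round(100 * onland / max(rawn, 1)),
      pct_corrected = if (onland > 0)
        round(100 * sum(corr$provenance == "particle-corrected") / onland)
        else NA_real_,
      n_removed_after_correction = nrow(remc),
      n_hourly = if (id == "(all)") nrow(interpolated) else
        sum(interpolated$animal_id == id),
      pct_interp_dropped = if (id == "(all)" && !is.null(ngen) && ngen > 0)
        round(100 * ndrop / ngen) else NA_real_)
  }
  out <- do.call(rbind, lapply(c(ids, "(all)"), row_for))
  rownames(out) <- NULL
  out
}
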