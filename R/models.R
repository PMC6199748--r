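# Seasonal occupancy smooths (binomial GAMM: day-of-season smooth per
# period, individual random intercept, within-individual AR1) and
# movement-metric mixed models (Gaussian LMM on log speed / turning angle
# with habitat x period fixed effects and the same error structure).

occ_column <- c("Glacier-Fronts" = "occ_glacier", "Fjords" = "occ_fjords",
                "Coastal" = "occ_coastal", "At-Sea" = "occ_atsea")

# integer hour position within animal; AR1 correlation decays as rho^gap so
# long gaps effectively break the chain
hour_position <- function(timestamp) as.integer(round(as.numeric(timestamp) / 3600))

#' Seasonal occupancy smooth for one habitat class
#'
#' Penalized-spline logistic regression of the habitat indicator on the
#' day-of-season index, with a separate smooth per period (period as a
#' by-variable), an individual random intercept and an AR1 residual process
#' within individual (fitted with `mgcv::gamm`, i.e. PQL via `nlme`).
#' Smoothness is selected internally by the fitter.
#'
#' @param series output of [occupancy_series()]; needs `period` and
#'   `animal_id` columns, at least two animals and both periods.
#' @param habitat one of `HABITAT_CLASSES`.
#' @param k spline basis dimension (default 10).
#' @param random_intercept,ar1 toggle the random effect / correlation
#'   structure; with both off an ordinary `mgcv::gam` is fitted.
#' @param day_grid day-index grid for the returned curves.
#' @return an `occupancy_fit`: list with `habitat`, `curves` (data.frame
#'   day_index, period, fit, lo95, hi95 on the probability scale),
#'   `ar1` coefficient, `ranef_var`, and the underlying `fit` object.
#' @export
fit_occupancy <- function(series, habitat, k = 10,
                          random_intercept = TRUE, ar1 = TRUE,
                          day_grid = NULL) {
  habitat <- match.arg(habitat, HABITAT_CLASSES)
  col <- occ_column[[habitat]]
  if (!col %in% names(series)) stop("series lacks column ", col, call. = FALSE)
  if (!all(c("period", "animal_id", "day_index") %in% names(series)))
    stop("series needs period, animal_id, day_index columns", call. = FALSE)
  d <- data.frame(y = series[[col]],
                  day_index = series$day_index,
                  period = factor(series$period),
                  animal_id = factor(series$animal_id))
  if ("timestamp" %in% names(series)) d$hpos <- hour_position(series$timestamp)
  else d$hpos <- stats::ave(seq_len(nrow(d)), d$animal_id, FUN = seq_along)
  if (length(unique(d$animal_id)) < 2)
    stop("need at least 2 animals", call. = FALSE)
  if (length(levels(d$period)) < 2)
    stop("both periods must be present", call. = FALSE)
  if (all(d$y == 0) || all(d$y == 1))
    stop("degenerate fit: indicator for habitat '", habitat,
         "' is constant", call. = FALSE)
  form <- y ~ period + s(day_index, by = period, k = k)
  if (!random_intercept && !ar1) {
    g <- mgcv::gam(form, family = stats::binomial(), data = d, method = "REML")
    lme_part <- NULL
  } else {
    g <- mgcv::gamm(form, family = stats::binomial(), data = d,
                    random = if (random_intercept) list(animal_id = ~1) else NULL,
                    correlation = if (ar1)
                      nlme::corAR1(form = ~ hpos | animal_id) else NULL,
                    niterPQL = 20, verbosePQL = FALSE)
    lme_part <- g$lme
    g <- g$gam
  }
  phi <- NA_real_; rv <- NA_real_
  if (!is.null(lme_part)) {
    cs <- lme_part$modelStruct$corStruct
    if (!is.null(cs)) phi <- as.numeric(stats::coef(cs, unconstrained = FALSE))
    rv <- tryCatch({
      vc <- nlme::VarCorr(lme_part)
      i <- grep("animal", rownames(vc))
      if (length(i)) as.numeric(vc[max(i) + 1, "Variance"]) else NA_real_
    }, error = function(e) NA_real_)
  }
  if (is.null(day_grid))
    day_grid <- seq(min(d$day_index), max(d$day_index), by = 1)
  nd <- expand.grid(day_index = day_grid, period = levels(d$period))
  pr <- mgcv::predict.gam(g, newdata = nd, type = "link", se.fit = TRUE)
  curves <- data.frame(day_index = nd$day_index, period = nd$period,
                       fit = stats::plogis(pr$fit),
                       lo95 = stats::plogis(pr$fit - 1.96 * pr$se.fit),
                       hi95 = stats::plogis(pr$fit + 1.96 * pr$se.fit))
  structure(list(habitat = habitat, curves = curves, ar1 = phi,
                 ranef_var = rv, fit = g, lme = lme_part),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("<occupancy_fit>", x$habitat, "\n")
  cat("  AR1 coefficient:", format(x$ar1, digits = 3), "\n")
  cat("  random-intercept variance:", format(x$ranef_var, digits = 3), "\n")
  cat("  curve grid:", length(unique(x$curves$day_index)), "days x",
      length(unique(x$curves$period)), "periods\n")
  invisible(x)
}

#' Do the two period bands separate?
#'
#' For each day in `days`, TRUE when the pointwise 95% bands of the two
#' periods do not overlap. Used for the band-overlap style of model
#' assessment.
#' @param fit an `occupancy_fit`.
#' @param days day-index values to check (default: all grid days).
#' @return named logical vector.
#' @export
bands_separate <- function(fit, days = NULL) {
  cv <- fit$curves
  pers <- levels(cv$period)[1:2]
  if (is.null(days)) days <- unique(cv$day_index)
  out <- vapply(days, function(d) {
    a <- cv[cv$day_index == d & cv$period == pers[1], ]
    b <- cv[cv$day_index == d & cv$period == pers[2], ]
    if (!nrow(a) || !nrow(b)) return(NA)
    a$lo95 > b$hi95 || b$lo95 > a$hi95
  }, logical(1))
  names(out) <- days
  out
}

#' Movement-metric mixed model
#'
#' Gaussian linear mixed model of log swimming speed or turning angle on
#' habitat class, period and their interaction, with an individual random
#' intercept and within-individual AR1 errors. Reference levels are the
#' Glacier-Fronts habitat and the first period, so coefficient rows read as
#' contrasts against glacier-front behaviour in the early period.
#'
#' @param classified data.frame with `speed`/`turn`, `habitat`, `period`,
#'   `animal_id`, `timestamp`.
#' @param metric "log_speed" or "turn".
#' @return a `coefficient_table` data.frame (term, Value, Std.error,
#'   P.value) with the `lme` fit attached as attribute "fit".
#' @export
fit_movement_model <- function(classified, metric = c("log_speed", "turn")) {
  metric <- match.arg(metric)
  value <- if (metric == "log_speed") log(classified$speed) else classified$turn
  d <- data.frame(value = value,
                  habitat = factor(as.character(classified$habitat),
                                   levels = HABITAT_CLASSES),
                  period = factor(classified$period),
                  animal_id = factor(classified$animal_id),
                  hpos = hour_position(classified$timestamp))
  d <- d[is.finite(d$value) & !is.na(d$habitat), , drop = FALSE]
  cells <- table(d$habitat, d$period)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("rank deficiency: no data for ",
         paste(sprintf("%s x %s", rownames(cells)[bad[, 1]],
                       colnames(cells)[bad[, 2]]), collapse = "; "),
         call. = FALSE)
  }
  d$habitat <- droplevels(d$habitat)
  fit <- nlme::lme(value ~ habitat * period, random = ~ 1 | animal_id,
                   correlation = nlme::corAR1(form = ~ hpos | animal_id),
                   data = d, method = "REML",
                   control = nlme::lmeControl(opt = "optim", maxIter = 100,
                                              msMaxIter = 100, returnObject = TRUE))
  tt <- summary(fit)$tTable
  out <- data.frame(term = rownames(tt), Value = tt[, "Value"],
                    Std.error = tt[, "Std.Error"],
                    P.value = tt[, "p-value"], row.names = NULL)
  attr(out, "fit") <- fit
  attr(out, "metric") <- metric
  class(out) <- c("coefficient_table", "data.frame")
  out
}

#' Mean, SD and bootstrap CI of movement metrics per habitat and period
#'
#' Nonparametric bootstrap: resample animals with replacement, then each
#' chosen animal's locations with replacement; percentile 95% interval of
#' the cell mean. Deterministic under a fixed seed. Empty cells are
#' reported as missing.
#'
#' @param classified data.frame with `speed`, `turn`, `habitat`, `period`,
#'   `animal_id`.
#' @param metric "speed" or "turn".
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return data.frame (habitat, period, n, mean, sd, lo95, hi95).
#' @export
summarize_metrics_by_class <- function(classified, metric = c("speed", "turn"),
                                       n_boot = 1000, seed = 1) {
  metric <- match.arg(metric)
  v <- classified[[metric]]
  ok <- !is.na(v)
  d <- data.frame(value = v[ok],
                  habitat = as.character(classified$habitat)[ok],
                  period = as.character(classified$period)[ok],
                  animal_id = as.character(classified$animal_id)[ok])
  grid <- expand.grid(habitat = HABITAT_CLASSES,
                      period = sort(unique(d$period)),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- d[d$habitat == grid$habitat[i] & d$period == grid$period[i], ]
    if (!nrow(cell))
      return(data.frame(habitat = grid$habitat[i], period = grid$period[i],
                        n = 0L, mean = NA_real_, sd = NA_real_,
                        lo95 = NA_real_, hi95 = NA_real_))
    ids <- unique(cell$animal_id)
    by_id <- split(cell$value, cell$animal_id)
    bs <- with_seed(seed + i, vapply(seq_len(n_boot), function(b) {
      pick <- sample(ids, length(ids), replace = TRUE)
      mean(unlist(lapply(by_id[pick], function(x)
        x[sample.int(length(x), length(x), replace = TRUE)])))
    }, numeric(1)))
    ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    data.frame(habitat = grid$habitat[i], period = grid$period[i],
               n = nrow(cell), mean = mean(cell$value),
               sd = stats::sd(cell$value),
               lo95 = if (nrow(cell) == 1 && length(ids) == 1) cell$value[1] else ci[1],
               hi95 = if (nrow(cell) == 1 && length(ids) == 1) cell$value[1] else ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
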