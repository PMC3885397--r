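#' Abundance-weighted population maturity ogive
#'
#' When mature and immature fish are distributed differently in space and
#' season, an ogive fitted to pooled samples is biased unless sampling is
#' proportional to abundance. The weighted estimator predicts the proportion
#' mature per latitudinal area and season from a model with a discrete
#' latitude factor, then averages the area curves with weights equal to the
#' estimated proportion of female abundance by 5-cm length class in each
#' area: `W_las = N_as * p_las * f_las / sum_a(N_as * p_las * f_las)`, where
#' `N_as` is relative abundance (both sexes, e.g. CPUE-derived), `p_las` the
#' within-area length composition and `f_las` the proportion female. Treating
#' the weights as known, the variance of the weighted average is
#' `sum_a W_las^2 Var(p_hat_las)` on the proportion scale.
#'
#' @name weighted_ogive
NULL

#' The discrete-latitude area model specification
#'
#' Length as a 2-df cubic spline, latitude as a three-level band factor,
#' season with two levels, a latitude-by-season interaction, and the
#' fishing-set random intercept.
#'
#' @param band_edges_degS Interior band edges.
#' @return A [model_spec()].
#' @export
area_model_spec <- function(band_edges_degS = c(23, 29)) {
  model_spec(predictor = "length", predictor_df = 2, lat = "discrete3",
             season_levels = 2, lat_x_season = TRUE,
             band_edges_degS = band_edges_degS)
}

#' Area- and season-specific maturity ogives
#'
#' Fits the discrete-latitude model and predicts the proportion mature with
#' its variance at 5-cm length-class midpoints for every latitudinal area and
#' season. Prediction variances are carried on the proportion scale via the
#' delta method.
#'
#' @param records Fish data.frame (see [build_design()]); every band-season
#'   stratum must contain data.
#' @param midpoints Length-class midpoints to predict at; defaults to the
#'   5-cm classes covering the observed lengths.
#' @param band_edges_degS Interior latitude band edges.
#' @param level Confidence level.
#' @return List with `predictions` (data.frame: midpoint, length_class,
#'   area, season, p, var, lower, upper) and `fit`.
#' @export
area_season_ogives <- function(records, midpoints = NULL,
                               band_edges_degS = c(23, 29), level = 0.95) {
  band <- latitude_band(records$latitude_degS, band_edges_degS)
  season <- season_of_month(records$month, 2)
  tab <- table(factor(band, levels = 1:3), factor(season, levels = 1:2))
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("empty band-season stratum: area ", empty[1, 1], ", season ",
         empty[1, 2], call. = FALSE)
  }
  if (is.null(midpoints)) {
    lc <- length_class(records$fork_length_cm)
    midpoints <- sort(unique(lc$midpoint))
  }
  fit <- fit_logistic_glmm(
    build_design(records, area_model_spec(band_edges_degS)))
  grid <- expand.grid(midpoint = midpoints, area = 1:3, season = 1:2)
  nd <- data.frame(fork_length_cm = grid$midpoint, area = grid$area,
                   season = grid$season)
  pr <- predict_proportion(fit, nd, level = level)
  grid$length_class <- paste0(grid$midpoint - 2, "-", grid$midpoint + 2)
  grid$p <- pr$proportion
  grid$var <- (pr$proportion * (1 - pr$proportion))^2 * pr$se_logit^2
  grid$lower <- pr$lower
  grid$upper <- pr$upper
  list(predictions = grid, fit = fit)
}

#' Abundance weights by length class, area and season
#'
#' `W_las` is the estimated proportion of female abundance in area `a` among
#' fish of length class `l` in season `s`: the product of relative abundance
#' `N_as`, length composition `p_las` and proportion female `f_las`,
#' normalised over areas within each (length class, season). Cells missing in
#' every area are undefined and propagate as `NA`; cells missing in some
#' areas drop those areas and renormalise over the rest.
#'
#' @param abundance data.frame with `area`, `season`, `N` (non-negative,
#'   relative scale).
#' @param composition data.frame with `midpoint` (or `length_class`), `area`,
#'   `season`, `p` (length composition within area-season) and `f`
#'   (proportion female).
#' @return `composition` with columns `raw` (`N*p*f`) and `W` appended.
#' @export
compute_weights <- function(abundance, composition) {
  stopifnot(all(c("area", "season", "N") %in% names(abundance)),
            all(c("area", "season", "p", "f") %in% names(composition)))
  if (any(abundance$N < 0, na.rm = TRUE) ||
      any(composition$p < 0, na.rm = TRUE) ||
      any(composition$f < 0 | composition$f > 1, na.rm = TRUE)) {
    stop("abundance and composition entries must be non-negative (f in [0,1])",
         call. = FALSE)
  }
  comp <- merge(composition, abundance, by = c("area", "season"),
                all.x = TRUE, sort = FALSE)
  comp$raw <- comp$N * comp$p * comp$f
  keyv <- if ("midpoint" %in% names(comp)) comp$midpoint else
    comp$length_class
  key <- paste(keyv, comp$season, sep = "|")
  tot <- tapply(comp$raw, key, function(v) sum(v, na.rm = TRUE))
  denom <- as.vector(tot[key])
  comp$W <- ifelse(is.na(comp$raw) | denom <= 0, NA_real_,
                   comp$raw / denom)
  # cells undefined in every area stay NA; partial cells renormalise above
  comp[order(comp$season, comp$area, keyv), ]
}

#' Combine area ogives into the weighted population ogive
#'
#' `P_ls = sum_a W_las * p_hat_las` with variance
#' `sum_a W_las^2 Var(p_hat_las)` (weights treated as known, which
#' understates the uncertainty: no variance is attached to the abundance,
#' length-composition or sex-ratio inputs). Confidence intervals are normal
#' intervals on the proportion scale truncated to [0, 1].
#'
#' @param predictions Area predictions from [area_season_ogives()]
#'   (`midpoint`, `area`, `season`, `p`, `var`).
#' @param weights Weight table from [compute_weights()] (`midpoint`, `area`,
#'   `season`, `W`).
#' @param level Confidence level.
#' @return An object of class `ogive_estimate`: data.frame per (midpoint,
#'   season) with `estimate`, `variance`, `ci_low`, `ci_high`, `n_areas`,
#'   plus the per-area long table in `attr(, "by_area")`. CIs exclude weight
#'   uncertainty.
#' @export
combine_weighted <- function(predictions, weights, level = 0.95) {
  m <- merge(predictions, weights[, c("midpoint", "area", "season", "W")],
             by = c("midpoint", "area", "season"), all.x = TRUE, sort = FALSE)
  if (any(!is.na(m$W) & m$W > 0 & !is.finite(m$var))) {
    stop("missing prediction variance where a weight is positive",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  key <- paste(m$midpoint, m$season, sep = "|")
  parts <- split(m, key)
  rows <- lapply(parts, function(d) {
    ok <- !is.na(d$W)
    if (!any(ok)) {
      return(data.frame(midpoint = d$midpoint[1], season = d$season[1],
                        estimate = NA_real_, variance = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, n_areas = 0L))
    }
    w <- d$W[ok] / sum(d$W[ok])   # renormalise over available areas
    est <- sum(w * d$p[ok])
    v <- sum(w^2 * d$var[ok])
    data.frame(midpoint = d$midpoint[1], season = d$season[1],
               estimate = est, variance = v,
               ci_low = max(est - z * sqrt(v), 0),
               ci_high = min(est + z * sqrt(v), 1),
               n_areas = sum(ok))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$season, out$midpoint), ]
  rownames(out) <- NULL
  attr(out, "by_area") <- m
  attr(out, "note") <-
    "CIs exclude uncertainty in the abundance/composition/sex-ratio weights"
  class(out) <- c("ogive_estimate", "data.frame")
  out
}

#' Weighted population ogive, end to end
#'
#' Convenience wrapper: fits the discrete-latitude area model, computes the
#' abundance weights, and combines them.
#'
#' @inheritParams area_season_ogives
#' @param abundance,composition See [compute_weights()].
#' @return List with `ogive` (an `ogive_estimate`), `weights`, `area_ogives`.
#' @export
weighted_ogive <- function(records, abundance, composition,
                           band_edges_degS = c(23, 29), level = 0.95) {
  ao <- area_season_ogives(records,
                           midpoints = sort(unique(composition$midpoint)),
                           band_edges_degS = band_edges_degS, level = level)
  w <- compute_weights(abundance, composition)
  og <- combine_weighted(ao$predictions, w, level = level)
  list(ogive = og, weights = w, area_ogives = ao)
}

#' Unweighted seasonal ogive
#'
#' The customary logistic model of maturity on fork length (with the
#' fishing-set random intercept retained), fitted to one season's data with
#' no latitude covariate. Its length at 50% maturity is `-b0 / b1`.
#'
#' @param records Fish data.frame.
#' @param season Season (2-level coding) to subset to.
#' @return List with `fit` (a `glmm_fit`), `l50`, and `curve(lengths)`.
#' @export
fit_unweighted <- function(records, season = 1) {
  s <- season_of_month(records$month, 2)
  d <- records[s == season, , drop = FALSE]
  y <- extract_maturity(d)
  if (length(unique(y)) < 2) {
    stop("season ", season, " data contain a single maturity state",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, fork_length_cm = d$fork_length_cm)
  fit <- fit_logistic_glmm(X, y = y, groups = as.character(d$set_id))
  l50 <- -fit$beta[1] / fit$beta[2]
  list(fit = fit, l50 = unname(l50),
       curve = function(lengths) {
         logistic(fit$beta[1] + fit$beta[2] * lengths)
       })
}

#' Length at a maturity quantile from an ogive table
#'
#' For `q < 1`, linear interpolation between the 5-cm class midpoints
#' bracketing the first upward crossing of `q`; for `q = 1`, the smallest
#' class whose estimate reaches `full_threshold` (default 0.99, since fitted
#' curves approach 1 only asymptotically).
#'
#' @param ogive An `ogive_estimate` (or data.frame with `midpoint`, `season`,
#'   `estimate`).
#' @param q Quantile in (0, 1].
#' @param season Season to evaluate.
#' @param full_threshold Proportion operationalising "100% mature".
#' @return Length (cm), or `NA` with a `reason` attribute if the ogive never
#'   reaches `q` within the grid.
#' @export
length_at_quantile <- function(ogive, q = 0.5, season = 1,
                               full_threshold = 0.99) {
  stopifnot(q > 0, q <= 1)
  d <- ogive[ogive$season == season & !is.na(ogive$estimate), , drop = FALSE]
  d <- d[order(d$midpoint), ]
  if (nrow(d) < 2) {
    return(structure(NA_real_, reason = "fewer than two defined classes"))
  }
  p <- d$estimate
  L <- d$midpoint
  if (q == 1) {
    i <- which(p >= full_threshold)
    if (!length(i)) {
      return(structure(NA_real_,
                       reason = "ogive never reaches the full threshold"))
    }
    return(L[min(i)])
  }
  if (p[1] >= q) return(L[1])
  up <- which(p[-length(p)] < q & p[-1] >= q)
  if (!length(up)) {
    return(structure(NA_real_, reason = "no upward crossing in grid span"))
  }
  i <- up[1]
  L[i] + (q - p[i]) / (p[i + 1] - p[i]) * (L[i + 1] - L[i])
}
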