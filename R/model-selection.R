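#' Multi-model inference for maturity models
#'
#' Candidate models differing in spline flexibility, spatial covariates,
#' season resolution and interactions are compared with Akaike's information
#' criterion corrected for small samples (AICc). Models within 2 AICc of the
#' best describe the data about equally well; Akaike weights quantify the
#' relative evidence for each model within the candidate set.
#'
#' @name model_selection
NULL

#' AICc
#'
#' `-2 logLik + 2k + 2k(k+1)/(n-k-1)` with `k` parameters and `n`
#' observations. The parameter count includes the random-intercept variance;
#' the observation count is the number of fish.
#'
#' @param loglik Maximised log-likelihood.
#' @param n_params Number of estimated parameters `k`.
#' @param n_obs Number of observations `n`; must exceed `k + 2` so the
#'   small-sample correction term has a denominator greater than 1.
#' @return AICc value.
#' @export
#' @examples
#' aicc(-100, 3, 100)  # 206.25
aicc <- function(loglik, n_params, n_obs) {
  k <- n_params
  if (n_obs <= k + 2) {
    stop("AICc undefined: n (", n_obs, ") must exceed k + 2 (", k + 2, ")",
         call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' @rdname aicc
#' @param fit A `glmm_fit`.
#' @export
aicc_fit <- function(fit) aicc(fit$loglik, fit$n_params, fit$n_obs)

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_r exp(-Delta_r / 2)` with
#' `Delta_i = AICc_i - min(AICc)`; the subtraction of the minimum makes the
#' computation stable, and the weights are invariant to adding a constant to
#' every AICc value.
#'
#' @param aicc_values Numeric vector of AICc (or delta-AICc) values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values) || any(!is.finite(aicc_values))) {
    stop("aicc_values must be a non-empty finite vector", call. = FALSE)
  }
  d <- aicc_values - min(aicc_values)
  e <- exp(-d / 2)
  e / sum(e)
}

#' Candidate model grid
#'
#' Expands the default comparison axes: predictor spline df in {1, 2, 6},
#' latitude absent or a 2-df spline, longitude absent or linear, 2 or 4
#' season levels, and each available interaction on or off (interactions are
#' only generated alongside their main effects).
#'
#' @param predictor `"length"` or `"age"`.
#' @param predictor_df,lat_df,lon_df,season_levels Axis values; `NA` in
#'   `lat_df` / 0 in `lon_df` means the covariate is absent.
#' @return List of [model_spec()] objects.
#' @export
candidate_grid <- function(predictor = "length",
                           predictor_df = c(1, 2, 6),
                           lat_df = c(NA, 2),
                           lon_df = c(0, 1),
                           season_levels = c(2, 4)) {
  specs <- list()
  for (pdf in predictor_df) for (ldf in lat_df) for (odf in lon_df)
    for (ssn in season_levels) {
      lat_int <- if (is.na(ldf)) FALSE else c(FALSE, TRUE)
      lon_int <- if (odf == 0) FALSE else c(FALSE, TRUE)
      for (li in lat_int) for (oi in lon_int) {
        specs[[length(specs) + 1]] <- model_spec(
          predictor = predictor, predictor_df = pdf,
          lat = if (is.na(ldf)) "none" else "spline",
          lat_df = if (is.na(ldf)) 2 else ldf,
          lon_df = odf, season_levels = ssn,
          lat_x_season = li, lon_x_season = oi)
      }
    }
  specs
}

#' Fit and compare candidate models by AICc
#'
#' Fits every candidate with [fit_logistic_glmm()], drops fits that fail or
#' do not converge (with a warning naming them), and returns a comparison
#' table sorted by AICc with delta-AICc and Akaike weights.
#'
#' @param records Fish data.frame (see [build_design()]).
#' @param candidate_specs List of [model_spec()] objects (default:
#'   [candidate_grid()]).
#' @param keep_fits Keep the fitted models in the result.
#' @return An object of class `model_comparison`: list with `table`
#'   (model_id, predictor, predictor_df, lat, lat_df, lon_df, season_levels,
#'   lat_x_season, lon_x_season, n_params, loglik, aicc, delta_aicc,
#'   akaike_weight) and, optionally, `fits`.
#' @export
compare_models <- function(records, candidate_specs = candidate_grid(),
                           keep_fits = TRUE) {
  stopifnot(length(candidate_specs) > 0)
  fits <- vector("list", length(candidate_specs))
  ok <- logical(length(candidate_specs))
  for (i in seq_along(candidate_specs)) {
    spec <- candidate_specs[[i]]
    fits[[i]] <- tryCatch(
      fit_logistic_glmm(build_design(records, spec)),
      error = function(e) e)
    ok[i] <- inherits(fits[[i]], "glmm_fit") && fits[[i]]$converged
    if (!ok[i]) {
      msg <- if (inherits(fits[[i]], "error")) conditionMessage(fits[[i]])
        else "did not converge"
      warning("model ", spec$model_id, " excluded: ", msg, call. = FALSE)
    }
  }
  if (!any(ok)) stop("all candidate model fits failed", call. = FALSE)
  specs <- candidate_specs[ok]
  fits <- fits[ok]
  tab <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]; f <- fits[[i]]
    data.frame(model_id = s$model_id, predictor = s$predictor,
               predictor_df = s$predictor_df, lat = s$lat,
               lat_df = if (s$lat == "spline") s$lat_df else NA_integer_,
               lon_df = s$lon_df, season_levels = s$season_levels,
               lat_x_season = s$lat_x_season, lon_x_season = s$lon_x_season,
               n_params = f$n_params, loglik = f$loglik,
               aicc = aicc_fit(f), stringsAsFactors = FALSE)
  }))
  ord <- order(tab$aicc)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$akaike_weight <- akaike_weights(tab$aicc)
  rownames(tab) <- NULL
  names(fits) <- tab$model_id
  out <- list(table = tab, fits = if (keep_fits) fits else NULL)
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- x$table
  tab$loglik <- round(tab$loglik, 2)
  tab$aicc <- round(tab$aicc, 2)
  tab$delta_aicc <- round(tab$delta_aicc, 2)
  tab$akaike_weight <- sprintf("%.1f%%", 100 * tab$akaike_weight)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Length versus age as a predictor of maturity
#'
#' Fits the same model structure twice -- once with fork length, once with
#' age as the spline predictor -- on the identical subset of fish having both
#' measurements, and compares the pair by AICc. The default structure is a
#' 6-df predictor spline, a 2-df latitude spline, four season levels and a
#' latitude-by-season interaction.
#'
#' @param records Fish data.frame with both `fork_length_cm` and `age_years`.
#' @param predictor_df,lat_df,season_levels,lat_x_season Shared structure.
#' @return A `model_comparison` over the two fits.
#' @export
head_to_head <- function(records, predictor_df = 6, lat_df = 2,
                         season_levels = 4, lat_x_season = TRUE) {
  if (!"age_years" %in% names(records) || any(is.na(records$age_years))) {
    stop("head-to-head comparison requires an age for every record",
         call. = FALSE)
  }
  specs <- lapply(c("length", "age"), function(pr) {
    model_spec(predictor = pr, predictor_df = predictor_df, lat = "spline",
               lat_df = lat_df, season_levels = season_levels,
               lat_x_season = lat_x_season)
  })
  compare_models(records, specs)
}

#' Length at 50% maturity by latitude
#'
#' For each latitude, evaluates the fitted maturity-at-length curve over the
#' observed length span and returns the smallest length at which the
#' predicted proportion crosses 0.5 from below (root-found to 0.01 cm).
#' Confidence bounds are the lengths at which the upper and lower 95%
#' logit-scale prediction bands cross 0.5: the upper band crosses first,
#' giving the lower length bound. Latitudes whose curve never crosses 0.5
#' yield `NA` with a reason.
#'
#' @param fit A `glmm_fit` with length as predictor.
#' @param latitudes Latitude grid (degrees south).
#' @param season Season level at which to predict.
#' @param level Confidence level.
#' @param newdata_extra Named list of fixed values for any further covariates
#'   (e.g. `longitude_degE`); defaults to the training medians.
#' @return data.frame with `latitude_degS`, `l50`, `ci_low`, `ci_high`,
#'   `note`.
#' @export
l50_by_latitude <- function(fit, latitudes, season = 1, level = 0.95,
                            newdata_extra = list()) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (fit$design$spec$predictor != "length") {
    stop("l50_by_latitude requires a length-based model", call. = FALSE)
  }
  rng <- fit$design$bases$predictor$range
  base <- fit$design$ref
  base[names(newdata_extra)] <- newdata_extra
  out <- lapply(latitudes, function(lat) {
    nd <- function(L) {
      d <- data.frame(fork_length_cm = L, latitude_degS = lat,
                      season = season)
      for (v in names(base)) d[[v]] <- base[[v]]
      d
    }
    pr <- function(L, col) predict_proportion(fit, nd(L), level = level)[[col]]
    l50 <- first_crossing(function(L) pr(L, "proportion"), rng)
    lo <- first_crossing(function(L) pr(L, "upper"), rng)
    hi <- first_crossing(function(L) pr(L, "lower"), rng)
    data.frame(latitude_degS = lat, l50 = l50, ci_low = lo, ci_high = hi,
               note = if (is.na(l50)) "no 0.5 crossing in length span" else "")
  })
  do.call(rbind, out)
}

# Smallest x in [rng] where f crosses 0.5 from below, to 0.01 precision.
first_crossing <- function(f, rng, target = 0.5, tol = 0.005) {
  grid <- seq(rng[1], rng[2], by = 0.5)
  v <- vapply(grid, f, numeric(1))
  if (any(!is.finite(v))) stop("non-finite predictions", call. = FALSE)
  up <- which(v[-length(v)] < target & v[-1] >= target)
  if (!length(up)) {
    if (v[1] >= target) return(rng[1])
    return(NA_real_)
  }
  i <- up[1]
  stats::uniroot(function(x) f(x) - target, c(grid[i], grid[i + 1]),
                 tol = tol)$root
}
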