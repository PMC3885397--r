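#' Spline and mixed-model machinery for maturity-at-length
#'
#' Maturity (1 = mature) is modelled as a binomial response with logit link.
#' Fork length (or age), latitude and longitude enter either linearly or as
#' cubic regression splines with knots at equally spaced quantiles of the
#' observed data; season is a factor with 2 or 4 levels; fishing set enters as
#' a Gaussian random intercept because fish from one set are not independent.
#' The marginal likelihood is maximised under the Laplace approximation, with
#' per-set modes found by nested Newton iterations, and can be cross-checked
#' against an adaptive Gauss--Hermite quadrature evaluation.
#'
#' @name spline_glmm
NULL

#' Cubic spline basis with quantile knots
#'
#' For `df >= 2`, a natural cubic spline basis ([splines::ns()]) with `df`
#' columns: `df - 1` interior knots at equally spaced quantiles of `x` and
#' boundary knots at the data range, i.e. `df + 1` nodes in total, so the
#' degrees of freedom equal the node count minus one. `df = 1` is the plain
#' (centred) linear term. Knots are stored so the basis can be re-evaluated at
#' new data.
#'
#' @param x Numeric vector.
#' @param df Degrees of freedom (positive integer).
#' @return An object of class `spline_basis`: list with `matrix` (n x df),
#'   `df`, `knots`, `boundary`, `center`, `range`.
#' @export
spline_basis <- function(x, df) {
  stopifnot(df >= 1, df == round(df))
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("spline variable contains non-finite values",
                               call. = FALSE)
  n_distinct <- length(unique(x))
  if (length(x) <= df || n_distinct < df + 1) {
    stop("too few distinct values (", n_distinct,
         ") for a spline with df = ", df, call. = FALSE)
  }
  if (df == 1) {
    ctr <- mean(x)
    out <- list(matrix = matrix(x - ctr, ncol = 1,
                                dimnames = list(NULL, "lin")),
                df = 1L, knots = numeric(0), boundary = range(x),
                center = ctr, range = range(x))
  } else {
    probs <- seq_len(df - 1) / df
    knots <- unname(stats::quantile(x, probs, type = 7))
    bd <- range(x)
    B <- splines::ns(x, knots = knots, Boundary.knots = bd)
    colnames(B) <- paste0("s", seq_len(ncol(B)))
    out <- list(matrix = unclass(B)[, , drop = FALSE], df = as.integer(df),
                knots = knots, boundary = bd, center = NA_real_,
                range = bd)
  }
  class(out) <- "spline_basis"
  out
}

#' Evaluate a stored spline basis at new values
#'
#' @param basis A `spline_basis` object.
#' @param x New values.
#' @return Matrix with `basis$df` columns.
#' @export
eval_basis <- function(basis, x) {
  stopifnot(inherits(basis, "spline_basis"))
  x <- as.numeric(x)
  if (basis$df == 1) {
    matrix(x - basis$center, ncol = 1, dimnames = list(NULL, "lin"))
  } else {
    B <- splines::ns(x, knots = basis$knots,
                     Boundary.knots = basis$boundary)
    colnames(B) <- paste0("s", seq_len(ncol(B)))
    unclass(B)[, , drop = FALSE]
  }
}

#' Specify a maturity model
#'
#' @param predictor `"length"` or `"age"`.
#' @param predictor_df Spline df for the predictor (1 = linear).
#' @param lat Latitude term: `"none"`, `"spline"`, or `"discrete3"`
#'   (three bands: < 23, 23--29, > 29 degrees S, northern band as reference).
#' @param lat_df Spline df for latitude (ignored unless `lat = "spline"`).
#' @param lon_df Longitude spline df; 0 omits longitude.
#' @param season_levels 2 (reference Apr--Sep) or 4 (reference Jan--Mar).
#' @param lat_x_season,lon_x_season Include the interaction with season.
#' @param band_edges_degS Interior band edges for `lat = "discrete3"`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(predictor = c("length", "age"), predictor_df = 2,
                       lat = c("none", "spline", "discrete3"), lat_df = 2,
                       lon_df = 0, season_levels = 2,
                       lat_x_season = FALSE, lon_x_season = FALSE,
                       band_edges_degS = c(23, 29)) {
  predictor <- match.arg(predictor)
  lat <- match.arg(lat)
  stopifnot(predictor_df >= 1, season_levels %in% c(2, 4), lon_df >= 0)
  if (lat_x_season && lat == "none") {
    stop("lat_x_season requires a latitude main effect", call. = FALSE)
  }
  if (lon_x_season && lon_df == 0) {
    stop("lon_x_season requires a longitude main effect", call. = FALSE)
  }
  spec <- list(predictor = predictor, predictor_df = as.integer(predictor_df),
               lat = lat, lat_df = as.integer(lat_df),
               lon_df = as.integer(lon_df),
               season_levels = as.integer(season_levels),
               lat_x_season = lat_x_season, lon_x_season = lon_x_season,
               band_edges_degS = band_edges_degS)
  spec$model_id <- with(spec, paste0(
    substr(predictor, 1, 3), predictor_df,
    "_lat", if (lat == "none") "0" else if (lat == "spline") lat_df else "D3",
    "_lon", lon_df, "_ssn", season_levels,
    if (lat_x_season) "_LxS" else "", if (lon_x_season) "_OxS" else ""))
  class(spec) <- "model_spec"
  spec
}

season_columns <- function(season, levels) {
  if (levels == 2) {
    # reference Apr-Sep (season 2)
    m <- matrix(as.numeric(season == 1), ncol = 1,
                dimnames = list(NULL, "ssn1"))
  } else {
    m <- sapply(2:4, function(q) as.numeric(season == q))
    colnames(m) <- paste0("ssnQ", 2:4)
  }
  m
}

#' Build the fixed-effects design for a model specification
#'
#' Columns are: intercept, predictor spline, latitude term (spline or two
#' band indicators with the northern band < 23 degrees S as reference),
#' longitude term, season factor (reference Apr--Sep with 2 levels, Jan--Mar
#' with 4), and interaction columns formed as products. Maturity is coded
#' 1 = mature. Groups are fishing-set ids.
#'
#' @param records Fish data.frame with `fork_length_cm` (and `age_years` for
#'   age models), `latitude_degS`, `longitude_degE`, `month`, `set_id`, and a
#'   maturity column (`mature` logical, or `maturity` with values
#'   mature/immature).
#' @param spec A [model_spec()].
#' @return A `glmm_design`: list with `X`, `y`, `groups`, `spec`, `bases`,
#'   `terms` (column block map).
#' @export
build_design <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(if (spec$predictor == "length") "fork_length_cm" else "age_years",
            if (spec$lat != "none") "latitude_degS",
            if (spec$lon_df > 0) "longitude_degE",
            "month", "set_id")
  miss <- need[!need %in% names(records) |
                 vapply(need, function(v) v %in% names(records) &&
                          all(is.na(records[[v]])), logical(1))]
  if (length(miss)) {
    stop("records are missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- extract_maturity(records)

  bases <- list()
  blocks <- list(intercept = matrix(1, nrow(records), 1,
                                    dimnames = list(NULL, "(Intercept)")))

  xv <- if (spec$predictor == "length") records$fork_length_cm else
    records$age_years
  bases$predictor <- spline_basis(xv, spec$predictor_df)
  P <- bases$predictor$matrix
  colnames(P) <- paste0(spec$predictor, "_", colnames(P))
  blocks$predictor <- P

  lat_cols <- NULL
  if (spec$lat == "spline") {
    bases$lat <- spline_basis(records$latitude_degS, spec$lat_df)
    lat_cols <- bases$lat$matrix
    colnames(lat_cols) <- paste0("lat_", colnames(lat_cols))
  } else if (spec$lat == "discrete3") {
    band <- latitude_band(records$latitude_degS, spec$band_edges_degS)
    lat_cols <- cbind(band2 = as.numeric(band == 2),
                      band3 = as.numeric(band == 3))
  }
  if (!is.null(lat_cols)) blocks$lat <- lat_cols

  lon_cols <- NULL
  if (spec$lon_df > 0) {
    bases$lon <- spline_basis(records$longitude_degE, spec$lon_df)
    lon_cols <- bases$lon$matrix
    colnames(lon_cols) <- paste0("lon_", colnames(lon_cols))
    blocks$lon <- lon_cols
  }

  season <- season_of_month(records$month, spec$season_levels)
  ssn_cols <- season_columns(season, spec$season_levels)
  blocks$season <- ssn_cols

  if (spec$lat_x_season) {
    blocks$lat_x_season <- interaction_columns(lat_cols, ssn_cols)
  }
  if (spec$lon_x_season) {
    blocks$lon_x_season <- interaction_columns(lon_cols, ssn_cols)
  }

  X <- do.call(cbind, blocks)
  terms <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  ref <- list()
  if (spec$lon_df > 0) {
    ref$longitude_degE <- stats::median(records$longitude_degE)
  }
  out <- list(X = X, y = y, groups = as.character(records$set_id),
              spec = spec, bases = bases, terms = terms, ref = ref)
  class(out) <- "glmm_design"
  out
}

extract_maturity <- function(records) {
  if ("mature" %in% names(records)) {
    y <- as.numeric(records$mature)
  } else if ("maturity" %in% names(records)) {
    y <- as.numeric(records$maturity == "mature")
  } else {
    stop("records need a 'mature' (logical) or 'maturity' ",
         "(mature/immature) column", call. = FALSE)
  }
  if (any(is.na(y))) stop("maturity contains missing values", call. = FALSE)
  y
}

interaction_columns <- function(a, b) {
  out <- do.call(cbind, lapply(seq_len(ncol(b)), function(j) {
    m <- a * b[, j]
    colnames(m) <- paste0(colnames(a), ":", colnames(b)[j])
    m
  }))
  out
}

# Rebuild the fixed-effects row block for new data using stored knots.
design_rows <- function(design, newdata) {
  spec <- design$spec
  n <- nrow(newdata)
  blocks <- list(intercept = matrix(1, n, 1))
  xv <- if (spec$predictor == "length") newdata$fork_length_cm else
    newdata$age_years
  blocks$predictor <- eval_basis(design$bases$predictor, xv)
  if (spec$lat == "spline") {
    blocks$lat <- eval_basis(design$bases$lat, newdata$latitude_degS)
  } else if (spec$lat == "discrete3") {
    band <- if ("area" %in% names(newdata)) newdata$area else
      latitude_band(newdata$latitude_degS, spec$band_edges_degS)
    if (!all(band %in% 1:3)) stop("unknown latitude band level", call. = FALSE)
    blocks$lat <- cbind(band2 = as.numeric(band == 2),
                        band3 = as.numeric(band == 3))
  }
  if (spec$lon_df > 0) {
    blocks$lon <- eval_basis(design$bases$lon, newdata$longitude_degE)
  }
  season <- if ("season" %in% names(newdata)) as.integer(newdata$season) else
    season_of_month(newdata$month, spec$season_levels)
  if (!all(season %in% seq_len(spec$season_levels))) {
    stop("unknown season level", call. = FALSE)
  }
  ssn <- season_columns(season, spec$season_levels)
  blocks$season <- ssn
  if (spec$lat_x_season) {
    blocks$lat_x_season <- interaction_columns(blocks$lat, ssn)
  }
  if (spec$lon_x_season) {
    blocks$lon_x_season <- interaction_columns(blocks$lon, ssn)
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- colnames(design$X)
  X
}

# Numerically stable Bernoulli log-likelihood contributions at linear
# predictor eta with response y in {0,1}.
bernoulli_ll <- function(y, eta) {
  y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
}

# Find the per-group posterior modes b (length G) of the random intercepts by
# damped Newton iteration; returns modes, the mode-level information, and the
# conditional log-likelihood at the modes.
group_modes <- function(eta0, y, gidx, G, sigma, tol = 1e-10, max_iter = 50) {
  b <- numeric(G)
  inv_v <- 1 / sigma^2
  obj <- function(b) {
    eta <- eta0 + b[gidx]
    rowsum_vec(bernoulli_ll(y, eta), gidx, G) - 0.5 * b^2 * inv_v
  }
  f <- obj(b)
  for (it in seq_len(max_iter)) {
    eta <- eta0 + b[gidx]
    mu <- logistic(eta)
    grad <- rowsum_vec(y - mu, gidx, G) - b * inv_v
    W <- rowsum_vec(mu * (1 - mu), gidx, G)
    step <- grad / (W + inv_v)
    b_new <- b + step
    f_new <- obj(b_new)
    halv <- 0
    while (any(f_new < f - 1e-12) && halv < 30) {
      bad <- f_new < f - 1e-12
      step[bad] <- step[bad] / 2
      b_new <- b + step
      f_new <- obj(b_new)
      halv <- halv + 1
    }
    conv <- max(abs(step)) < tol
    b <- b_new
    f <- f_new
    if (conv) break
  }
  eta <- eta0 + b[gidx]
  mu <- logistic(eta)
  W <- rowsum_vec(mu * (1 - mu), gidx, G)
  list(b = b, W = W, cond_ll = rowsum_vec(bernoulli_ll(y, eta), gidx, G))
}

rowsum_vec <- function(x, gidx, G) {
  out <- numeric(G)
  agg <- rowsum(x, gidx, reorder = FALSE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Laplace-approximate marginal log-likelihood
#'
#' For a binomial logit model with a single Gaussian random intercept, each
#' group's integral over its random effect is approximated by a Laplace
#' expansion around the posterior mode, found by damped Newton iterations.
#' At `sigma = 0` this is exactly the plain Bernoulli log-likelihood.
#'
#' @param beta Fixed-effect vector.
#' @param sigma Random-intercept standard deviation (`>= 0`).
#' @param X Design matrix.
#' @param y 0/1 response.
#' @param groups Group labels (fishing-set ids).
#' @return Scalar log-likelihood.
#' @export
laplace_loglik <- function(beta, sigma, X, y, groups) {
  eta0 <- drop(X %*% beta)
  if (sigma < 1e-10) return(sum(bernoulli_ll(y, eta0)))
  gf <- factor(groups)
  gidx <- as.integer(gf)
  G <- nlevels(gf)
  m <- group_modes(eta0, y, gidx, G, sigma)
  sum(m$cond_ll) - sum(m$b^2) / (2 * sigma^2) -
    0.5 * sum(log1p(sigma^2 * m$W))
}

#' Fit a binomial logit mixed model by Laplace approximation
#'
#' Maximises the Laplace-approximate marginal likelihood over the fixed
#' effects and the set-level standard deviation, with the standard deviation
#' box-constrained at zero; at the boundary the fit collapses to plain
#' logistic regression. Starting values come from an (unpenalised) logistic
#' regression. The covariance of the fixed effects is the inverse of the
#' numerically differentiated Hessian of the negative marginal log-likelihood
#' at the optimum.
#'
#' @param design A `glmm_design` from [build_design()], or a design matrix
#'   (then supply `y` and `groups`).
#' @param y,groups Response and group labels when `design` is a bare matrix.
#' @param fix_sigma Optionally fix the random-intercept SD (e.g. 0).
#' @param sigma_start Starting value for the SD.
#' @return An object of class `glmm_fit` with elements `beta`, `cov_beta`,
#'   `sigma_set`, `loglik`, `n_obs`, `n_params`, `converged`, `design`.
#' @export
fit_logistic_glmm <- function(design, y = NULL, groups = NULL,
                              fix_sigma = NULL, sigma_start = 0.5) {
  if (inherits(design, "glmm_design")) {
    X <- design$X; y <- design$y; groups <- design$groups
    dsg <- design
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    dsg <- NULL
  }
  if (length(unique(groups)) < 2 && is.null(fix_sigma)) {
    stop("need at least 2 groups to estimate a set-level variance",
         call. = FALSE)
  }
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    stop("response must contain both 0s (immature) and 1s (mature)",
         call. = FALSE)
  }

  g0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta0 <- g0$coefficients
  beta0[!is.finite(beta0)] <- 0
  check_separation(X, y, beta0)

  p <- ncol(X)
  if (!is.null(fix_sigma) && fix_sigma < 1e-10) {
    # plain logistic regression; still reports n_params with the variance slot
    eta <- drop(X %*% beta0)
    ll <- sum(bernoulli_ll(y, eta))
    mu <- logistic(eta)
    info <- crossprod(X * (mu * (1 - mu)), X)
    fit <- list(beta = beta0, cov_beta = solve(info), sigma_set = 0,
                loglik = ll, n_obs = length(y), n_params = p + 1L,
                converged = g0$converged, design = dsg,
                se_sigma = NA_real_)
    class(fit) <- "glmm_fit"
    return(fit)
  }

  nll <- if (is.null(fix_sigma)) {
    function(par) -laplace_loglik(par[1:p], par[p + 1], X, y, groups)
  } else {
    function(par) -laplace_loglik(par, fix_sigma, X, y, groups)
  }
  start <- if (is.null(fix_sigma)) c(beta0, sigma_start) else beta0
  lower <- if (is.null(fix_sigma)) c(rep(-Inf, p), 0) else rep(-Inf, p)
  opt <- stats::nlminb(start, nll, lower = lower,
                       control = list(iter.max = 500, eval.max = 1000))
  beta <- opt$par[1:p]
  names(beta) <- colnames(X)
  sigma <- if (is.null(fix_sigma)) unname(opt$par[p + 1]) else fix_sigma
  check_separation(X, y, beta)

  # observed information; at a sigma boundary differentiate over beta only
  at_boundary <- is.null(fix_sigma) && sigma < 1e-6
  if (is.null(fix_sigma) && !at_boundary) {
    H <- stats::optimHess(opt$par, nll)
    cov_all <- tryCatch(solve(H), error = function(e) {
      solve(H + diag(1e-8, nrow(H)))
    })
    cov_beta <- cov_all[1:p, 1:p, drop = FALSE]
    se_sigma <- sqrt(max(cov_all[p + 1, p + 1], 0))
  } else {
    nll_b <- function(b) -laplace_loglik(b, sigma, X, y, groups)
    H <- stats::optimHess(beta, nll_b)
    cov_beta <- tryCatch(solve(H), error = function(e) {
      solve(H + diag(1e-8, nrow(H)))
    })
    se_sigma <- NA_real_
  }
  cov_beta <- (cov_beta + t(cov_beta)) / 2
  dimnames(cov_beta) <- list(colnames(X), colnames(X))

  fit <- list(beta = beta, cov_beta = cov_beta, sigma_set = sigma,
              loglik = -opt$objective, n_obs = length(y),
              n_params = p + 1L, converged = opt$convergence == 0,
              design = dsg, se_sigma = se_sigma)
  class(fit) <- "glmm_fit"
  fit
}

check_separation <- function(X, y, beta) {
  beta[!is.finite(beta)] <- 0
  eta <- drop(X %*% beta)
  if (all(y == as.numeric(eta > 0)) && min(abs(eta)) > 8) {
    scale <- apply(X, 2, stats::sd)
    cand <- which(scale > 0)          # a constant column cannot separate
    if (!length(cand)) cand <- seq_len(ncol(X))
    worst <- colnames(X)[cand][which.max((abs(beta) * scale)[cand])]
    stop("complete separation detected: covariate '", worst,
         "' perfectly predicts maturity", call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial logit mixed model (Laplace)\n")
  cat("  observations:", x$n_obs, "  parameters:", x$n_params,
      " (", length(x$beta), "fixed + set-level SD )\n")
  cat("  set-level SD:", format(x$sigma_set, digits = 4),
      "  logLik:", format(x$loglik, digits = 8),
      "  converged:", x$converged, "\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Marginal log-likelihood by adaptive Gauss--Hermite quadrature
#'
#' Independent evaluation of the marginal likelihood used to validate the
#' Laplace approximation on small problems. Each group's integral is centred
#' and scaled at its posterior mode and evaluated with `n_nodes` Hermite
#' nodes via a log-sum-exp.
#'
#' @inheritParams laplace_loglik
#' @param n_nodes Number of quadrature nodes (default 21).
#' @return Scalar log-likelihood.
#' @export
loglik_quadrature <- function(beta, sigma, X, y, groups, n_nodes = 21) {
  eta0 <- drop(X %*% beta)
  if (sigma < 1e-10) return(sum(bernoulli_ll(y, eta0)))
  gf <- factor(groups)
  gidx <- as.integer(gf)
  G <- nlevels(gf)
  if (G > 30) warning("quadrature oracle intended for <= 30 groups (got ",
                      G, ")")
  m <- group_modes(eta0, y, gidx, G, sigma)
  s <- 1 / sqrt(m$W + 1 / sigma^2)
  gh <- gauss_hermite(n_nodes)
  ll <- 0
  for (g in seq_len(G)) {
    bk <- m$b[g] + sqrt(2) * s[g] * gh$nodes
    rows <- which(gidx == g)
    lk <- vapply(seq_along(bk), function(k) {
      sum(bernoulli_ll(y[rows], eta0[rows] + bk[k])) +
        stats::dnorm(bk[k], 0, sigma, log = TRUE)
    }, numeric(1))
    lw <- log(gh$weights) + gh$nodes^2 + log(sqrt(2) * s[g]) + lk
    M <- max(lw)
    ll <- ll + M + log(sum(exp(lw - M)))
  }
  ll
}

#' Predict the proportion mature
#'
#' Predictions are for a typical fishing set (random effect = 0) by default.
#' Standard errors come from the quadratic form of the fixed-effect
#' covariance on the logit scale; confidence intervals are Wald intervals on
#' the logit scale back-transformed to proportions, so they always lie in
#' [0, 1] and bracket the point estimate. Rows whose spline covariates fall
#' outside the training span are flagged as extrapolation. With
#' `population_averaged = TRUE` the set-level random effect is integrated out
#' by Gauss--Hermite quadrature.
#'
#' @param fit A `glmm_fit` whose design was built by [build_design()].
#' @param newdata data.frame of covariates (same fields as the fit).
#' @param level Confidence level (default 0.95).
#' @param population_averaged Integrate over the set effect instead of
#'   conditioning on a typical set.
#' @param n_quad Nodes for the population-averaged integral.
#' @return data.frame with `proportion`, `se_logit`, `lower`, `upper`,
#'   `extrapolated`.
#' @export
predict_proportion <- function(fit, newdata, level = 0.95,
                               population_averaged = FALSE, n_quad = 21) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (is.null(fit$design)) {
    stop("fit carries no design metadata; refit via build_design()",
         call. = FALSE)
  }
  X <- design_rows(fit$design, newdata)
  eta <- drop(X %*% fit$beta)
  if (any(!is.finite(eta))) stop("non-finite predictions", call. = FALSE)
  se <- sqrt(pmax(rowSums((X %*% fit$cov_beta) * X), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)

  extrap <- rep(FALSE, nrow(X))
  spec <- fit$design$spec
  xv <- if (spec$predictor == "length") newdata$fork_length_cm else
    newdata$age_years
  rng <- fit$design$bases$predictor$range
  extrap <- extrap | xv < rng[1] | xv > rng[2]
  if (!is.null(fit$design$bases$lat) && "latitude_degS" %in% names(newdata)) {
    rng <- fit$design$bases$lat$range
    extrap <- extrap | newdata$latitude_degS < rng[1] |
      newdata$latitude_degS > rng[2]
  }

  if (population_averaged && fit$sigma_set > 0) {
    gh <- gauss_hermite(n_quad)
    b <- sqrt(2) * fit$sigma_set * gh$nodes
    w <- gh$weights / sqrt(pi)
    prop <- drop(logistic(outer(eta, b, `+`)) %*% w)
    lower <- drop(logistic(outer(eta - z * se, b, `+`)) %*% w)
    upper <- drop(logistic(outer(eta + z * se, b, `+`)) %*% w)
  } else {
    prop <- logistic(eta)
    lower <- logistic(eta - z * se)
    upper <- logistic(eta + z * se)
  }
  data.frame(proportion = prop, se_logit = se, lower = lower, upper = upper,
             extrapolated = extrap)
}
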