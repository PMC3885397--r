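#' Parameters for the synthetic albacore-like population
#'
#' Defines the generating process for a size-structured, migratory,
#' cluster-sampled population with the statistical features the maturity
#' analysis assumes: a latitudinal size gradient (larger fish at lower
#' latitudes), a length-driven maturity process, a set-level random effect on
#' the logit scale, a spawning migration that moves mature fish north during
#' October--March, a length-dependent sex ratio, and fishing effort that
#' concentrates toward the spawning ground in season 1.
#'
#' @param n_sets Number of fishing sets.
#' @param fish_per_set_mean Mean fish per set (sizes are `1 + Poisson(mean-1)`).
#' @param latitude_range_degS Latitude span as positive degrees south,
#'   `c(lo, hi)` with `lo < hi` (10 means 10 degrees S).
#' @param month_weights 12 non-negative sampling weights for months Jan--Dec.
#' @param length_by_latitude `c(intercept_cm, slope_cm_per_degS, sd_cm)`:
#'   mean fork length at latitude x degrees S is
#'   `intercept_cm - slope_cm_per_degS * x`.
#' @param true_ogive `c(L50_base_cm, L50_lat_slope_cm_per_degS,
#'   L50_season1_shift_cm, logit_slope_per_cm)`. The true length at 50\%
#'   maturity at home latitude x in season s is
#'   `L50_base_cm + L50_lat_slope_cm_per_degS * (x - 25) +
#'   L50_season1_shift_cm * (s == 1)`; `logit_slope_per_cm` must be positive.
#' @param set_re_sd Standard deviation of the set-level random intercept
#'   (logit scale), `>= 0`.
#' @param migration_enabled Logical; if `TRUE`, a fraction of mature fish in
#'   October--March are displaced north before set assignment.
#' @param migration_north_shift_degS Northward displacement in degrees.
#' @param migration_fraction Proportion of mature fish that undertake the
#'   spawning migration in season 1 (the remainder stay at their home
#'   latitude).
#' @param sex_ratio `c(intercept, slope_per_cm)`:
#'   `P(female) = plogis(intercept + slope_per_cm * FL)`.
#' @param effort_north_bias_season1 Non-negative; 0 gives uniform effort.
#'   Season-1 clusters are sampled with probability proportional to a
#'   `Beta(1, 1 + bias)` density over the scaled latitude, skewing effort
#'   toward the northern spawning latitudes as fishing fleets follow the
#'   fish.
#' @param population_multiplier The latent population holds
#'   `n_sets * population_multiplier` clusters, of which `n_sets` are
#'   sampled; the rest exist only in the census attached to the output.
#' @param longitude_range_degE Longitude span, degrees east.
#' @param include_ages Logical; attach ages by inverting a von Bertalanffy
#'   growth curve with noise.
#' @param growth `c(Linf_cm, K_per_yr, t0_yr, age_sd_yr)` for age generation.
#' @param seed Optional integer seed.
#' @return A `population_params` list.
#' @export
population_params <- function(n_sets = 150,
                              fish_per_set_mean = 10,
                              latitude_range_degS = c(10, 40),
                              month_weights = rep(1, 12),
                              length_by_latitude = c(intercept_cm = 105,
                                                     slope_cm_per_degS = 0.9,
                                                     sd_cm = 8),
                              true_ogive = c(L50_base_cm = 87,
                                             L50_lat_slope_cm_per_degS = 0,
                                             L50_season1_shift_cm = 0,
                                             logit_slope_per_cm = 0.25),
                              set_re_sd = 0.5,
                              migration_enabled = TRUE,
                              migration_north_shift_degS = 8,
                              migration_fraction = 0.75,
                              sex_ratio = c(intercept = 2.5,
                                            slope_per_cm = -0.03),
                              effort_north_bias_season1 = 2,
                              population_multiplier = 4,
                              longitude_range_degE = c(150, 190),
                              include_ages = FALSE,
                              growth = c(Linf_cm = 104, K_per_yr = 0.4,
                                         t0_yr = -0.5, age_sd_yr = 0.5),
                              seed = NULL) {
  p <- list(n_sets = n_sets, fish_per_set_mean = fish_per_set_mean,
            latitude_range_degS = latitude_range_degS,
            month_weights = month_weights,
            length_by_latitude = length_by_latitude,
            true_ogive = true_ogive, set_re_sd = set_re_sd,
            migration_enabled = migration_enabled,
            migration_north_shift_degS = migration_north_shift_degS,
            migration_fraction = migration_fraction,
            sex_ratio = sex_ratio,
            effort_north_bias_season1 = effort_north_bias_season1,
            population_multiplier = population_multiplier,
            longitude_range_degE = longitude_range_degE,
            include_ages = include_ages, growth = growth, seed = seed)
  validate_population_params(p)
  class(p) <- "population_params"
  p
}

validate_population_params <- function(p) {
  lr <- p$latitude_range_degS
  if (length(lr) != 2 || !is.finite(lr[1]) || !is.finite(lr[2]) ||
      lr[1] >= lr[2]) {
    stop("latitude_range_degS must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  if (p$n_sets < 1) stop("n_sets must be positive", call. = FALSE)
  if (length(p$month_weights) != 12 || any(p$month_weights < 0) ||
      sum(p$month_weights) <= 0) {
    stop("month_weights must be 12 non-negative values, not all zero",
         call. = FALSE)
  }
  if (p$true_ogive[[4]] <= 0) {
    stop("logit_slope_per_cm must be positive", call. = FALSE)
  }
  if (p$set_re_sd < 0) stop("set_re_sd must be >= 0", call. = FALSE)
  if (p$effort_north_bias_season1 < 0) {
    stop("effort_north_bias_season1 must be >= 0", call. = FALSE)
  }
  if (p$population_multiplier < 1) {
    stop("population_multiplier must be >= 1", call. = FALSE)
  }
  if (p$migration_fraction < 0 || p$migration_fraction > 1) {
    stop("migration_fraction must be in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

# True L50 (cm) at a home latitude and season under the generator's ogive.
true_l50 <- function(params, latitude_degS, season) {
  og <- params$true_ogive
  og[[1]] + og[[2]] * (latitude_degS - 25) + og[[3]] * (season == 1)
}

#' Simulate a cluster-sampled fish population
#'
#' The generator separates the population from the sample, which is what
#' allows sampling bias to exist at all:
#' \enumerate{
#'   \item A latent population of fish clusters (schools) is drawn:
#'     each cluster has a month, a home latitude (uniform over the range), a
#'     longitude, a Gaussian random intercept on the logit scale, and a
#'     Poisson number of fish. Fish lengths follow the latitudinal size
#'     gradient at the cluster's home latitude; true maturity is Bernoulli
#'     with logit equal to `logit_slope * (FL - L50(home lat, season)) +
#'     b_cluster`; sex follows the length-dependent sex-ratio model.
#'   \item If migration is enabled, a fraction `migration_fraction` of
#'     mature fish in October--March (season 1) leave their cluster and move
#'     north by `migration_north_shift_degS` degrees (clamped to the latitude
#'     range), joining a randomly chosen existing season-1 cluster within 2
#'     degrees of their destination (same month), so spawning-ground schools
#'     mix residents and migrants.
#'   \item Fishing sets are a sample of `n_sets` clusters drawn without
#'     replacement with probability proportional to fishing effort: uniform
#'     in season 2, skewed toward the northern spawning latitudes in season 1
#'     by `effort_north_bias_season1` (fleets follow the fish).
#' }
#' The returned sample carries the latent true maturity state (`mature`),
#' standing in for a perfect histological classification. The full
#' post-migration population is attached as `attr(, "population")` and plays
#' the role of the fishery-independent census from which relative abundance
#' can be tabulated.
#'
#' @param params A [population_params()] object.
#' @return A data.frame with one row per sampled fish: `fish_id`, `set_id`,
#'   `month`, `latitude_degS` (capture latitude), `longitude_degE`,
#'   `fork_length_cm`, `sex`, `mature` (logical), `home_latitude_degS`, and
#'   `age_years` when ages are requested; the full population in
#'   `attr(, "population")`.
#' @export
simulate_population <- function(params) {
  validate_population_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  lo <- params$latitude_range_degS[1]
  hi <- params$latitude_range_degS[2]
  n_clusters <- params$n_sets * params$population_multiplier

  month_c <- sample.int(12, n_clusters, replace = TRUE,
                        prob = params$month_weights)
  season_c <- season_of_month(month_c, levels = 2)
  lat_c <- stats::runif(n_clusters, lo, hi)
  lon_c <- stats::runif(n_clusters, params$longitude_range_degE[1],
                        params$longitude_range_degE[2])
  b_c <- stats::rnorm(n_clusters, 0, params$set_re_sd)
  size_c <- 1L + stats::rpois(n_clusters,
                              max(params$fish_per_set_mean - 1, 0))

  cl <- rep(seq_len(n_clusters), size_c)
  n <- length(cl)
  lb <- params$length_by_latitude
  home_lat <- lat_c[cl]
  len <- pmax(stats::rnorm(n, lb[[1]] - lb[[2]] * home_lat, lb[[3]]), 30)
  l50 <- true_l50(params, home_lat, season_c[cl])
  eta <- params$true_ogive[[4]] * (len - l50) + b_c[cl]
  mature <- stats::runif(n) < logistic(eta)
  sex <- ifelse(
    stats::runif(n) < logistic(params$sex_ratio[[1]] +
                                 params$sex_ratio[[2]] * len), "F", "M")

  fish <- data.frame(
    fish_id = seq_len(n), cluster = cl, month = month_c[cl],
    latitude_degS = lat_c[cl], longitude_degE = lon_c[cl],
    fork_length_cm = len, sex = sex, mature = mature,
    home_latitude_degS = home_lat, stringsAsFactors = FALSE)

  cluster_lat <- lat_c
  cluster_month <- month_c
  cluster_lon <- lon_c
  if (params$migration_enabled) {
    mig <- fish$mature & season_c[fish$cluster] == 1 &
      stats::runif(n) < params$migration_fraction
    if (any(mig)) {
      idx <- which(mig)
      dest <- pmin(pmax(fish$home_latitude_degS[idx] -
                          params$migration_north_shift_degS, lo), hi)
      # migrants join an existing season-1 cluster near their destination
      # (within +/- 2 degrees; nearest cluster if none), mixing spawners
      # into resident schools
      s1_cl <- which(season_c == 1)
      for (mth in unique(fish$month[idx])) {
        rows <- idx[fish$month[idx] == mth]
        d <- dest[match(rows, idx)]
        cand <- s1_cl[month_c[s1_cl] == mth]
        if (!length(cand)) cand <- s1_cl
        newc <- vapply(d, function(tl) {
          near <- cand[abs(lat_c[cand] - tl) <= 2]
          if (!length(near)) near <- cand[which.min(abs(lat_c[cand] - tl))]
          if (length(near) == 1) near else sample(near, 1)
        }, integer(1))
        fish$cluster[rows] <- newc
        fish$month[rows] <- month_c[newc]
        fish$latitude_degS[rows] <- lat_c[newc]
        fish$longitude_degE[rows] <- lon_c[newc]
      }
    }
  }

  if (params$include_ages) {
    g <- params$growth
    ratio <- pmin(fish$fork_length_cm / g[[1]], 0.97)
    fish$age_years <- pmax(g[[3]] - log(1 - ratio) / g[[2]] +
                             stats::rnorm(n, 0, g[[4]]), 0.5)
  }

  # effort-weighted sampling of clusters
  n_cl_total <- length(cluster_lat)
  season_cl <- season_of_month(cluster_month, 2)
  w <- rep(1, n_cl_total)
  if (params$effort_north_bias_season1 > 0) {
    u <- (cluster_lat - lo) / (hi - lo)
    w1 <- stats::dbeta(pmin(pmax(u, 1e-6), 1 - 1e-6), 1,
                       1 + params$effort_north_bias_season1)
    w[season_cl == 1] <- w1[season_cl == 1]
  }
  take <- sample.int(n_cl_total, min(params$n_sets, n_cl_total), prob = w)
  sampled <- fish[fish$cluster %in% take, , drop = FALSE]
  sampled$set_id <- match(sampled$cluster, sort(unique(sampled$cluster)))
  sampled$cluster <- NULL
  rownames(sampled) <- NULL

  fish$set_id <- fish$cluster
  fish$cluster <- NULL
  out <- sampled[, c("fish_id", "set_id", "month", "latitude_degS",
                     "longitude_degE", "fork_length_cm", "sex", "mature",
                     "home_latitude_degS",
                     if (params$include_ages) "age_years")]
  attr(out, "population") <- fish
  out
}

#' Tabulate abundance, length composition and sex ratio
#'
#' Cross-tabulates a fish table into the three inputs of the weighted-ogive
#' estimator: total abundance by latitudinal area and season (`N_as`, both
#' sexes), the within-(area, season) length composition over 5-cm classes
#' (`p_las`, summing to 1 within occupied strata), and the proportion female
#' per (length class, area, season) cell (`f_las`). When these come from a
#' census-scale simulation they play the role of the fishery-independent
#' abundance index; empty cells are returned as `NA`, never as zeros.
#'
#' @param population Fish table as returned by [simulate_population()], or any
#'   data.frame with `latitude_degS`, `month`, `fork_length_cm`, `sex`.
#' @param band_edges_degS Interior latitude band edges (degrees south).
#' @param class_width_cm Length class width (cm).
#' @return List with `abundance` (area, season, N) and `composition`
#'   (length_class, midpoint, area, season, p, f, n).
#' @export
derive_abundance_inputs <- function(population, band_edges_degS = c(23, 29),
                                    class_width_cm = 5) {
  if (!nrow(population)) stop("population is empty", call. = FALSE)
  area <- latitude_band(population$latitude_degS, band_edges_degS)
  season <- season_of_month(population$month, levels = 2)
  lc <- length_class(population$fork_length_cm, class_width_cm)

  ab <- as.data.frame(table(area = area, season = season))
  names(ab)[3] <- "N"
  ab$area <- as.integer(as.character(ab$area))
  ab$season <- as.integer(as.character(ab$season))

  classes <- sort(unique(lc$lower))
  grid <- expand.grid(lower = classes, area = sort(unique(area)),
                      season = 1:2)
  key <- function(lw, a, s) paste(lw, a, s, sep = "|")
  tab_all <- table(key(lc$lower, area, season))
  tab_f <- table(key(lc$lower, area, season)[population$sex == "F"])
  grid$n <- as.vector(tab_all[key(grid$lower, grid$area, grid$season)])
  grid$n[is.na(grid$n)] <- 0L
  nf <- as.vector(tab_f[key(grid$lower, grid$area, grid$season)])
  nf[is.na(nf)] <- 0L
  tot_as <- stats::ave(grid$n, grid$area, grid$season, FUN = sum)
  grid$p <- ifelse(tot_as > 0 & grid$n > 0, grid$n / tot_as,
                   ifelse(tot_as > 0, 0, NA_real_))
  grid$f <- ifelse(grid$n > 0, nf / grid$n, NA_real_)
  grid$length_class <- paste0(grid$lower, "-", grid$lower + class_width_cm - 1)
  grid$midpoint <- grid$lower + (class_width_cm - 1) / 2
  comp <- grid[order(grid$season, grid$area, grid$lower),
               c("length_class", "midpoint", "area", "season", "p", "f", "n")]
  rownames(comp) <- NULL
  list(abundance = ab[order(ab$season, ab$area), ],
       composition = comp)
}

#' True population maturity ogive
#'
#' The exact population proportion mature at length for a given season,
#' marginalised over the (uniform) home-latitude distribution and the
#' set-level random effect. The latitude integral uses a fine trapezoid grid;
#' the random-effect integral uses Gauss--Hermite quadrature. This is the
#' recovery target for the weighted estimator: migration moves fish around
#' but does not change who is mature at a given length.
#'
#' @param params A [population_params()] object.
#' @param lengths Numeric vector of fork lengths (cm).
#' @param season Season (1 = Oct--Mar, 2 = Apr--Sep).
#' @param n_lat Latitude grid size.
#' @param n_quad Gauss--Hermite nodes for the random-effect integral.
#' @return data.frame with `fork_length_cm` and `p_mature`.
#' @export
true_weighted_ogive <- function(params, lengths, season = 1,
                                n_lat = 201, n_quad = 40) {
  validate_population_params(params)
  lo <- params$latitude_range_degS[1]
  hi <- params$latitude_range_degS[2]
  lat <- seq(lo, hi, length.out = n_lat)
  w_lat <- rep(1, n_lat)
  w_lat[c(1, n_lat)] <- 0.5          # trapezoid weights, uniform density
  w_lat <- w_lat / sum(w_lat)
  k <- params$true_ogive[[4]]
  if (params$set_re_sd > 0) {
    gh <- gauss_hermite(n_quad)
    b <- sqrt(2) * params$set_re_sd * gh$nodes
    w_b <- gh$weights / sqrt(pi)
  } else {
    b <- 0
    w_b <- 1
  }
  p <- vapply(lengths, function(L) {
    l50 <- true_l50(params, lat, season)
    # p(L) = sum_lat w_lat * sum_b w_b * plogis(k (L - l50) + b)
    m <- outer(k * (L - l50), b, `+`)
    sum(w_lat * (logistic(m) %*% w_b))
  }, numeric(1))
  data.frame(fork_length_cm = lengths, p_mature = p)
}

#' True length at a maturity quantile
#'
#' Root-finds the generator's exact population ogive for the length at which
#' the proportion mature equals `q`.
#'
#' @inheritParams true_weighted_ogive
#' @param q Target proportion in (0, 1).
#' @return Length in cm.
#' @export
true_length_at <- function(params, q = 0.5, season = 1) {
  f <- function(L) true_weighted_ogive(params, L, season)$p_mature - q
  stats::uniroot(f, c(30, 150), tol = 1e-4)$root
}
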