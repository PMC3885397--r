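make_weight_tables <- function(N, p, f, midpoint = 88, season = 1) {
  list(abundance = data.frame(area = seq_along(N), season = season, N = N),
       composition = data.frame(midpoint = midpoint, area = seq_along(N),
                                season = season, p = p, f = f))
}

test_that("abundance weights reproduce the N*p*f hand calculation", {
  tb <- make_weight_tables(N = c(3, 1), p = c(0.2, 0.4), f = c(0.5, 0.25))
  w <- compute_weights(tb$abundance, tb$composition)
  expect_equal(w$W[order(w$area)], c(0.75, 0.25), tolerance = 1e-12)

  tb2 <- make_weight_tables(N = c(1, 1), p = c(0.3, 0.3), f = c(0.5, 0.5))
  w2 <- compute_weights(tb2$abundance, tb2$composition)
  expect_equal(w2$W, c(0.5, 0.5))

  bad <- tb
  bad$abundance$N[1] <- -1
  expect_error(compute_weights(bad$abundance, bad$composition),
               "non-negative")
})

test_that("weights normalise over areas for random positive tables", {
  set.seed(11)
  for (i in 1:20) {
    ab <- expand.grid(area = 1:3, season = 1:2)
    ab$N <- runif(6, 0.1, 10)
    comp <- expand.grid(midpoint = c(48, 53, 58), area = 1:3, season = 1:2)
    comp$p <- runif(nrow(comp))
    comp$f <- runif(nrow(comp))
    w <- compute_weights(ab, comp)
    tot <- tapply(w$W, paste(w$midpoint, w$season), sum)
    expect_true(all(abs(tot - 1) < 1e-12))
  }
})

test_that("missing cells drop their area and renormalise, or propagate NA", {
  comp <- expand.grid(midpoint = 48, area = 1:3, season = 1)
  comp$p <- c(0.5, NA, 0.5)
  comp$f <- c(0.5, NA, 0.5)
  ab <- data.frame(area = 1:3, season = 1, N = 1)
  w <- compute_weights(ab, comp)
  expect_equal(w$W[!is.na(w$W)], c(0.5, 0.5))
  comp$p <- NA_real_
  w2 <- compute_weights(ab, comp)
  expect_true(all(is.na(w2$W)))
})

test_that("the weighted combination equals brute-force summation", {
  set.seed(3)
  preds <- expand.grid(midpoint = seq(48, 108, by = 5), area = 1:3,
                       season = 1:2)
  preds$p <- plogis(0.3 * (preds$midpoint - 85) + 0.3 * preds$area)
  preds$var <- runif(nrow(preds), 1e-5, 4e-3)
  wts <- preds[, c("midpoint", "area", "season")]
  raw <- runif(nrow(wts))
  tot <- ave(raw, paste(wts$midpoint, wts$season), FUN = sum)
  wts$W <- raw / tot
  og <- combine_weighted(preds, wts)
  for (i in sample(nrow(og), 8)) {
    sel <- preds$midpoint == og$midpoint[i] & preds$season == og$season[i]
    wsel <- wts$W[match(paste(preds$midpoint[sel], preds$area[sel],
                              preds$season[sel]),
                        paste(wts$midpoint, wts$area, wts$season))]
    expect_equal(og$estimate[i], sum(wsel * preds$p[sel]), tolerance = 1e-12)
    expect_equal(og$variance[i], sum(wsel^2 * preds$var[sel]),
                 tolerance = 1e-12)
    # convex-hull bound of the weighted average
    expect_gte(og$estimate[i], min(preds$p[sel]) - 1e-12)
    expect_lte(og$estimate[i], max(preds$p[sel]) + 1e-12)
  }
  expect_true(all(og$ci_low >= 0 & og$ci_high <= 1))
  expect_match(attr(og, "note"), "weight")

  # degenerate weight reduces to the selected area exactly
  w10 <- wts
  w10$W <- as.numeric(w10$area == 1)
  og10 <- combine_weighted(preds, w10)
  a1 <- preds[preds$area == 1, ]
  key <- paste(og10$midpoint, og10$season)
  expect_equal(og10$estimate, a1$p[match(key, paste(a1$midpoint, a1$season))],
               tolerance = 1e-12)

  # simple mean example
  tb <- make_weight_tables(N = c(1, 1), p = c(0.5, 0.5), f = c(1, 1))
  pr <- data.frame(midpoint = 88, area = 1:2, season = 1, p = c(0.2, 0.8),
                   var = c(1e-4, 1e-4))
  og2 <- combine_weighted(pr, compute_weights(tb$abundance, tb$composition))
  expect_equal(og2$estimate, 0.5)

  # positive weight with missing variance is an error
  pr$var[1] <- NA
  expect_error(combine_weighted(pr, compute_weights(tb$abundance,
                                                    tb$composition)),
               "variance")
})

test_that("the reduced variance formula matches a Monte-Carlo oracle", {
  set.seed(21)
  p_hat <- c(0.25, 0.55, 0.8)
  v_hat <- c(4e-4, 9e-4, 2.5e-4)
  W <- c(0.5, 0.3, 0.2)
  preds <- data.frame(midpoint = 88, area = 1:3, season = 1, p = p_hat,
                      var = v_hat)
  wts <- data.frame(midpoint = 88, area = 1:3, season = 1, W = W)
  og <- combine_weighted(preds, wts)
  draws <- replicate(10000, sum(W * rnorm(3, p_hat, sqrt(v_hat))))
  expect_lt(abs(og$variance - var(draws)) / var(draws), 0.10)
})

test_that("area ogives require full stratum coverage and order the spawning ground on top", {
  rec <- toy_records(200)
  rec$latitude_degS <- runif(200, 10, 22)   # only band 1
  expect_error(area_season_ogives(rec), "stratum")

  pop <- simulate_population(small_params(seed = 31, n_sets = 400,
                                          fish_per_set_mean = 15))
  fem <- pop[pop$sex == "F", ]
  ao <- area_season_ogives(fem)
  expect_true(all(ao$predictions$p >= 0 & ao$predictions$p <= 1))
  expect_true(all(ao$predictions$var >= 0))
  at85 <- ao$predictions[ao$predictions$midpoint == 83 &
                           ao$predictions$season == 1, ]
  expect_gt(at85$p[at85$area == 1], at85$p[at85$area == 3])
})

test_that("the unweighted seasonal ogive is monotone and guards separation", {
  pop <- simulate_population(small_params(seed = 17, n_sets = 200))
  uw <- fit_unweighted(pop, 2)
  lens <- seq(60, 110, by = 5)
  expect_true(all(diff(uw$curve(lens)) > 0))
  expect_gt(uw$fit$beta[2], 0)
  one_state <- pop
  one_state$mature <- TRUE
  expect_error(fit_unweighted(one_state, 2), "single maturity state")
})

test_that("lengths at maturity quantiles interpolate the ogive table", {
  og <- data.frame(midpoint = c(78, 83, 88, 93, 98), season = 1,
                   estimate = c(0, 0, 1, 1, 1))
  expect_equal(length_at_quantile(og, 0.5, 1), 85.5)  # first upward crossing
  og$estimate <- c(0.1, 0.4, 0.6, 0.95, 0.995)
  expect_equal(length_at_quantile(og, 0.5, 1), 85.5)
  og2 <- data.frame(midpoint = c(85, 90), season = 1, estimate = c(0.4, 0.6))
  expect_equal(length_at_quantile(og2, 0.5, 1), 87.5)
  expect_equal(length_at_quantile(og, 1, 1), 98)
  out <- length_at_quantile(og2, 1, 1)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "threshold")
  out2 <- length_at_quantile(og2, 0.99, 1)
  expect_true(is.na(out2))
})
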