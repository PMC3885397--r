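test_that("AICc evaluates its closed form and limits", {
  expect_equal(aicc(-100, 3, 100), 206.25)
  expect_lt(abs(aicc(-100, 3, 1e9) - (-2 * -100 + 2 * 3)), 1e-6)
  expect_error(aicc(-100, 8, 10), "exceed")
  expect_error(aicc(-100, 9, 10), "exceed")
})

test_that("Akaike weights renormalise exp(-delta/2) stably", {
  expect_equal(akaike_weights(c(5, 5)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 0.66, 2.62, 5.29, 6.07, 7.19))
  expect_equal(w[1], 0.468322, tolerance = 1e-5)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # invariance to a constant shift, including huge offsets
  set.seed(4)
  for (i in 1:5) {
    a <- runif(6, 0, 30)
    expect_equal(akaike_weights(a), akaike_weights(a + 12345.6),
                 tolerance = 1e-9)
    expect_equal(sum(akaike_weights(a)), 1, tolerance = 1e-12)
  }
  expect_error(akaike_weights(numeric(0)), "non-empty")
  expect_error(akaike_weights(c(1, NA)), "finite")
})

test_that("the default candidate grid covers the comparison axes", {
  grid <- candidate_grid()
  expect_gte(length(grid), 24)
  ids <- vapply(grid, `[[`, character(1), "model_id")
  expect_equal(anyDuplicated(ids), 0)
  # the best-supported structure (2-df length, 2-df latitude, 2 seasons,
  # latitude-by-season interaction) is among the candidates
  has <- vapply(grid, function(s) {
    s$predictor_df == 2 && s$lat == "spline" && s$lat_df == 2 &&
      s$lon_df == 0 && s$season_levels == 2 && s$lat_x_season
  }, logical(1))
  expect_true(any(has))
})

test_that("model comparison ranks, weights and deduplicates consistently", {
  rec <- toy_records(600, n_sets = 60, seed = 9)
  specs <- list(model_spec(predictor_df = 1), model_spec(predictor_df = 2),
                model_spec(predictor_df = 1))
  cmp <- compare_models(rec, specs, keep_fits = FALSE)
  expect_equal(nrow(cmp$table), 3)
  expect_true(!is.unsorted(cmp$table$aicc))
  expect_equal(cmp$table$delta_aicc, cmp$table$aicc - min(cmp$table$aicc))
  expect_equal(sum(cmp$table$akaike_weight), 1, tolerance = 1e-12)
  dup <- cmp$table$aicc[cmp$table$predictor_df == 1]
  expect_lt(abs(dup[1] - dup[2]), 1e-8)
  # order invariance of the sorted table
  cmp2 <- compare_models(rec, specs[c(2, 3, 1)], keep_fits = FALSE)
  expect_equal(cmp2$table$aicc, cmp$table$aicc, tolerance = 1e-6)
})

test_that("the generating model is selected when latitude truly matters", {
  wins <- 0
  for (r in 1:10) {
    p <- small_params(seed = 300 + r, n_sets = 150, fish_per_set_mean = 10,
                      true_ogive = c(87, 0.8, 0, 0.25),
                      migration_enabled = FALSE,
                      effort_north_bias_season1 = 0)
    pop <- simulate_population(p)
    specs <- list(model_spec(predictor_df = 1, lat = "spline", lat_df = 1),
                  model_spec(predictor_df = 1))
    cmp <- suppressWarnings(compare_models(pop, specs, keep_fits = FALSE))
    wins <- wins + (cmp$table$lat[1] == "spline")
  }
  expect_gte(wins, 9)
})

test_that("length-vs-age comparison favours the true driver and is symmetric", {
  p <- small_params(seed = 55, n_sets = 120, include_ages = TRUE,
                    migration_enabled = FALSE,
                    effort_north_bias_season1 = 0)
  pop <- simulate_population(p)

  # identical predictor columns give a dead heat
  same <- pop
  same$age_years <- same$fork_length_cm
  hh0 <- head_to_head(same, predictor_df = 2, season_levels = 2)
  expect_lt(abs(diff(hh0$table$aicc)), 1e-4)
  expect_equal(sum(hh0$table$akaike_weight), 1, tolerance = 1e-12)

  # maturity is driven by length; age is a noisy proxy, so length wins
  wins <- 0
  for (r in 1:6) {
    pr <- small_params(seed = 600 + r, n_sets = 120, include_ages = TRUE,
                       migration_enabled = FALSE,
                       effort_north_bias_season1 = 0)
    d <- simulate_population(pr)
    hh <- suppressWarnings(head_to_head(d, predictor_df = 2,
                                        season_levels = 2))
    wins <- wins + (hh$table$predictor[1] == "length")
  }
  expect_gte(wins, 5)
  pop$age_years <- NULL
  expect_error(head_to_head(pop), "age")
})

test_that("L50-by-latitude inverts a known logistic exactly and orders its CI", {
  rec <- toy_records(400, n_sets = 40, seed = 2)
  fit <- fit_logistic_glmm(build_design(rec, model_spec(predictor_df = 1,
                                                        lat = "spline",
                                                        lat_df = 1)))
  # overwrite with a known plain logistic: logit p = -17.4 + 0.2 L
  ctr <- fit$design$bases$predictor$center
  fit$beta[] <- 0
  fit$beta["length_lin"] <- 0.2
  fit$beta["(Intercept)"] <- -17.4 + 0.2 * ctr
  fit$cov_beta[] <- 0
  diag(fit$cov_beta) <- 1e-10
  out <- l50_by_latitude(fit, latitudes = c(15, 25, 35), season = 2)
  expect_equal(out$l50, rep(87, 3), tolerance = 0.01)

  refit <- fit_logistic_glmm(build_design(rec, model_spec(predictor_df = 1,
                                                          lat = "spline",
                                                          lat_df = 1)))
  out2 <- l50_by_latitude(refit, latitudes = c(15, 25, 35), season = 2)
  ok <- !is.na(out2$l50)
  expect_true(all(out2$ci_low[ok] <= out2$l50[ok] + 1e-9, na.rm = TRUE))
  expect_true(all(out2$l50[ok] <= out2$ci_high[ok] + 1e-9, na.rm = TRUE))
})

test_that("the latitude profile of L50 is recovered from simulated data", {
  p <- small_params(seed = 505, n_sets = 500, fish_per_set_mean = 20,
                    true_ogive = c(87, 0.5, 0, 0.25),
                    migration_enabled = FALSE,
                    effort_north_bias_season1 = 0)
  pop <- simulate_population(p)
  fit <- fit_logistic_glmm(build_design(pop, model_spec(predictor_df = 1,
                                                        lat = "spline",
                                                        lat_df = 1)))
  lats <- c(14, 22, 30, 38)
  out <- l50_by_latitude(fit, lats, season = 2)
  truth <- 87 + 0.5 * (lats - 25)
  expect_true(all(abs(out$l50 - truth) < 2))
})
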