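test_that("spline bases have quantile knots and re-evaluate exactly from stored knots", {
  set.seed(1)
  x <- runif(200, 40, 110)
  sb1 <- spline_basis(x, 1)
  expect_equal(ncol(sb1$matrix), 1)
  expect_equal(drop(sb1$matrix), x - mean(x))

  for (df in c(2, 3, 6)) {
    sb <- spline_basis(x, df)
    expect_equal(ncol(sb$matrix), df)
    expect_equal(length(sb$knots), df - 1)
    expect_equal(sb$knots,
                 unname(quantile(x, seq_len(df - 1) / df)), tolerance = 1e-12)
    # df + 1 nodes in total: df - 1 interior plus 2 boundary
    expect_equal(length(sb$knots) + 2, df + 1)
    expect_equal(eval_basis(sb, x), sb$matrix, tolerance = 1e-12)
    # out-of-order evaluation is row-consistent
    ord <- sample(length(x))
    expect_equal(eval_basis(sb, x[ord]), sb$matrix[ord, ], tolerance = 1e-12)
  }
  expect_error(spline_basis(rep(1, 50), 2), "distinct")
  expect_error(spline_basis(c(0, 1), 3), "few")
})

test_that("design matrices have the documented column layout", {
  rec <- toy_records(300)
  d0 <- build_design(rec, model_spec(predictor_df = 2))
  expect_equal(ncol(d0$X), 1 + 2 + 1)  # intercept + spline + season1

  d1 <- build_design(rec, model_spec(predictor_df = 2, lat = "discrete3",
                                     lat_x_season = TRUE))
  expect_equal(ncol(d1$X), 1 + 2 + 2 + 1 + 2)
  expect_true(all(c("band2", "band3", "ssn1") %in% colnames(d1$X)))

  d2 <- build_design(rec, model_spec(predictor_df = 6, lat = "spline",
                                     lat_df = 2, lon_df = 1,
                                     season_levels = 4, lat_x_season = TRUE,
                                     lon_x_season = TRUE))
  expect_equal(ncol(d2$X), 1 + 6 + 2 + 1 + 3 + 6 + 3)

  rec2 <- rec[, setdiff(names(rec), "longitude_degE")]
  expect_error(build_design(rec2, model_spec(lon_df = 1)), "longitude_degE")
  expect_error(build_design(rec, model_spec(predictor = "age")), "age_years")

  # all-immature data build fine; failure surfaces at fit time
  rec3 <- rec
  rec3$mature <- FALSE
  d3 <- build_design(rec3, model_spec())
  expect_error(fit_logistic_glmm(d3), "both 0s")

  expect_error(model_spec(lat = "none", lat_x_season = TRUE), "main effect")
})

test_that("the fit collapses to plain logistic regression when sigma is zero", {
  set.seed(42)
  d <- sim_glmm_data(80, 10, sigma = 0)
  fit0 <- fit_logistic_glmm(d$X, y = d$y, groups = d$groups, fix_sigma = 0)
  gref <- glm(d$y ~ d$len, family = binomial)
  expect_equal(unname(fit0$beta), unname(coef(gref)), tolerance = 1e-6)
  expect_equal(fit0$loglik, as.numeric(logLik(gref)), tolerance = 1e-8)

  # freely estimated fit on no-clustering data stays near the GLM answer
  fit <- fit_logistic_glmm(d$X, y = d$y, groups = d$groups)
  se <- sqrt(diag(vcov(gref)))
  expect_lt(max(abs(fit$beta - coef(gref)) / se), 2)
  expect_lt(fit$sigma_set, 0.3)
  expect_true(fit$converged)
  expect_equal(fit$n_params, 3)
})

test_that("Laplace agrees with adaptive Gauss-Hermite quadrature", {
  set.seed(7)
  d <- sim_glmm_data(5, 8, sigma = 0.8)
  fit <- fit_logistic_glmm(d$X, y = d$y, groups = d$groups)
  la <- laplace_loglik(fit$beta, fit$sigma_set, d$X, d$y, d$groups)
  qu21 <- loglik_quadrature(fit$beta, fit$sigma_set, d$X, d$y, d$groups, 21)
  qu41 <- loglik_quadrature(fit$beta, fit$sigma_set, d$X, d$y, d$groups, 41)
  expect_lt(abs(la - qu21) / abs(qu21), 1e-2)
  expect_lt(abs(qu21 - qu41), 1e-8)
  # no integral at sigma = 0
  eta <- drop(d$X %*% fit$beta)
  expect_equal(loglik_quadrature(fit$beta, 0, d$X, d$y, d$groups),
               sum(d$y * eta - log1p(exp(eta))), tolerance = 1e-12)
})

test_that("the Laplace optimum matches an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  set.seed(12)
  d <- sim_glmm_data(100, 12, sigma = 0.6)
  fit <- fit_logistic_glmm(d$X, y = d$y, groups = d$groups)
  df <- data.frame(y = d$y, len = d$len, g = d$groups)
  ref <- suppressWarnings(
    lme4::glmer(y ~ len + (1 | g), data = df, family = binomial))
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(fit$sigma_set, sqrt(unname(unlist(lme4::VarCorr(ref)))),
               tolerance = 1e-2)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("the marginal likelihood at the optimum dominates the starting values", {
  set.seed(30)
  d <- sim_glmm_data(40, 10, sigma = 0.5)
  fit <- fit_logistic_glmm(d$X, y = d$y, groups = d$groups)
  g0 <- glm.fit(d$X, d$y, family = binomial())
  expect_gte(fit$loglik + 1e-8,
             laplace_loglik(g0$coefficients, 0.5, d$X, d$y, d$groups))
})

test_that("complete separation is detected and named", {
  X <- cbind(`(Intercept)` = 1, len = c(1:5, 11:15))
  y <- rep(c(0, 1), each = 5)
  g <- rep(c("a", "b"), 5)
  expect_error(fit_logistic_glmm(X, y = y, groups = g), "separation.*len")
})

test_that("predictions are well-formed, bracketed and order-invariant", {
  rec <- toy_records(500, n_sets = 50)
  fit <- fit_logistic_glmm(build_design(rec, model_spec(predictor_df = 2)))
  nd <- data.frame(fork_length_cm = seq(55, 105, by = 5),
                   season = rep(1:2, length.out = 11))
  pr <- predict_proportion(fit, nd)
  expect_true(all(pr$proportion >= 0 & pr$proportion <= 1))
  expect_true(all(pr$lower <= pr$proportion & pr$proportion <= pr$upper))
  expect_true(all(pr$lower >= 0 & pr$upper <= 1))
  # row order invariance
  ord <- sample(nrow(nd))
  pr2 <- predict_proportion(fit, nd[ord, , drop = FALSE])
  expect_equal(pr2$proportion, pr$proportion[ord], tolerance = 1e-12)
  # zero coefficients give exactly one half
  fit0 <- fit
  fit0$beta[] <- 0
  expect_equal(predict_proportion(fit0, nd)$proportion, rep(0.5, nrow(nd)))
  # extrapolation is flagged
  prx <- predict_proportion(fit, data.frame(fork_length_cm = 300, season = 1))
  expect_true(prx$extrapolated)
  expect_error(predict_proportion(fit, data.frame(fork_length_cm = 80,
                                                  season = 7)),
               "season")
})

test_that("logit-scale standard errors agree with a set-level bootstrap", {
  set.seed(77)
  rec <- toy_records(240, n_sets = 20, seed = 77)
  spec <- model_spec(predictor_df = 1)
  fit <- fit_logistic_glmm(build_design(rec, spec))
  nd <- data.frame(fork_length_cm = 85, season = 2)
  se_model <- predict_proportion(fit, nd)$se_logit

  sets <- unique(rec$set_id)
  boot <- replicate(200, {
    take <- sample(sets, length(sets), replace = TRUE)
    d <- do.call(rbind, lapply(seq_along(take), function(i) {
      di <- rec[rec$set_id == take[i], ]
      di$set_id <- i
      di
    }))
    f <- tryCatch(fit_logistic_glmm(build_design(d, spec)),
                  error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    Xn <- cbind(1, 85 - f$design$bases$predictor$center,
                as.numeric(1 == 1) * 0)
    drop(Xn %*% f$beta)
  })
  se_boot <- sd(boot, na.rm = TRUE)
  expect_lt(abs(se_model - se_boot) / se_boot, 0.25)
})
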