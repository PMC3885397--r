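# Small scenario builders shared across test files.

# Compact cluster-sampled scenario; defaults small enough for unit tests.
small_params <- function(seed = 101, n_sets = 150, fish_per_set_mean = 10,
                         ...) {
  population_params(n_sets = n_sets, fish_per_set_mean = fish_per_set_mean,
                    seed = seed, ...)
}

# Direct simulation of the plain random-intercept logistic model
# logit P(mature) = b0 + b1 * FL + b_set, outside the population generator,
# for estimator-level checks.
sim_glmm_data <- function(n_sets, fish_per_set, b0 = -17.4, b1 = 0.2,
                          sigma = 0.5, len_mean = 87, len_sd = 12) {
  set_id <- rep(seq_len(n_sets), each = fish_per_set)
  b <- rnorm(n_sets, 0, sigma)
  len <- rnorm(n_sets * fish_per_set, len_mean, len_sd)
  y <- as.numeric(runif(length(len)) < plogis(b0 + b1 * len + b[set_id]))
  list(X = cbind(`(Intercept)` = 1, len = len), y = y,
       groups = as.character(set_id), len = len, set_id = set_id)
}

# Fish records with covariates suitable for build_design(), drawn i.i.d.
# (no clustering structure beyond the set labels themselves).
toy_records <- function(n = 400, n_sets = 40, seed = 5, both_seasons = TRUE) {
  set.seed(seed)
  months <- if (both_seasons) 1:12 else 4:9
  len <- runif(n, 50, 110)
  data.frame(
    set_id = sample(n_sets, n, replace = TRUE),
    month = sample(months, n, replace = TRUE),
    latitude_degS = runif(n, 10, 40),
    longitude_degE = runif(n, 150, 190),
    fork_length_cm = len,
    sex = "F",
    mature = runif(n) < plogis(0.25 * (len - 87)))
}
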