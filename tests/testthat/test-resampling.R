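test_that("subset draws are uniform-without-replacement, reproducible, and pool-preserving", {
  comm <- generate_community(pool_size = 6, seed = 3)

  exh <- draw_subsets(comm, n_sub = 3, exhaustive = TRUE)
  expect_length(exh, choose(6, 3))
  keys <- vapply(exh, function(s) paste(sort(s$species_id), collapse = "|"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0)
  expect_true(all(vapply(exh, attr, numeric(1), "pool_size") == 6))

  a <- draw_subsets(comm, n_sub = 4, n_draws = 8, seed = 99)
  b <- draw_subsets(comm, n_sub = 4, n_draws = 8, seed = 99)
  expect_identical(a, b)
  expect_true(all(vapply(a, nrow, integer(1)) == 4))

  full <- draw_subsets(comm, n_sub = 6, n_draws = 3, seed = 1)
  expect_true(all(vapply(full, function(s)
    setequal(s$species_id, comm$data$species_id), logical(1))))

  expect_error(draw_subsets(comm, n_sub = 7, n_draws = 1), "available")
})

test_that("predicted bias follows the finite-pool formula", {
  expect_equal(predicted_bias(10, n_sub = 5, pool_size = 10), 0.1)
  expect_equal(predicted_bias(123, n_sub = 20, pool_size = 20), 0)
  expect_equal(predicted_bias(0, n_sub = c(2, 5, 9), pool_size = 10),
               c(0, 0, 0))
  # decays like 1/N at fixed pool
  pb <- predicted_bias(50, n_sub = c(2, 4, 8), pool_size = 100)
  expect_true(all(diff(pb) < 0))
  expect_error(predicted_bias(1, n_sub = 1, pool_size = 10))
})

test_that("the design object validates its fields", {
  d <- subsampling_design(n_grid = c(5, 2, 5), n_draws = 10)
  expect_equal(d$n_grid, c(2L, 5L))
  expect_error(subsampling_design(n_grid = 1), ">= 2")
  expect_error(subsampling_design(n_grid = 4, n_draws = 0), ">= 1")
})

test_that("subsampling experiment is exact in exhaustive mode and tidy in shape", {
  comm <- generate_community(pool_size = 8, seed = 21)
  des <- subsampling_design(n_grid = c(3, 8), n_draws = 50,
                            n_het_reps = c(1, 5), seed = 4,
                            exhaustive_threshold = 100)
  curve <- subsampling_experiment(comm, des)

  expect_true(all(c("N", "variant", "n_het", "mean_bias", "sd",
                    "predicted_bias") %in% names(curve)))
  expect_setequal(unique(curve$variant),
                  c("ce_uncorrected", "se_uncorrected",
                    "ce_corrected", "se_corrected"))

  # C(8,3) = 56 <= threshold: exhaustive, so corrected means are exactly
  # unbiased and the uncorrected CE bias equals the analytic value
  at3 <- dplyr::filter(curve, N == 3, n_het == 1)
  expect_true(all(at3$exhaustive))
  expect_lt(abs(at3$mean_bias[at3$variant == "ce_corrected"]), 1e-8)
  expect_lt(abs(at3$mean_bias[at3$variant == "se_corrected"]), 1e-8)
  expect_close(at3$mean_bias[at3$variant == "ce_uncorrected"],
               at3$predicted_bias[at3$variant == "ce_uncorrected"],
               rel_tol = 1e-8)

  # the complete sample has no sampling error at all
  at8 <- dplyr::filter(curve, N == 8, n_het == 1)
  expect_equal(at8$sd, rep(0, 4))
  expect_equal(at8$mean_bias[at8$variant == "ce_corrected"], 0)
})

test_that("Monte-Carlo draws converge to the exhaustive mean", {
  comm <- generate_community(pool_size = 7, seed = 8)
  des_mc <- subsampling_design(n_grid = 4, n_draws = 4000, seed = 13,
                               exhaustive_threshold = 0)
  des_ex <- subsampling_design(n_grid = 4, n_draws = 1, seed = 13,
                               exhaustive_threshold = 1e5)
  mc <- subsampling_experiment(comm, des_mc) |>
    dplyr::filter(variant == "ce_corrected", n_het == 1)
  ex <- subsampling_experiment(comm, des_ex) |>
    dplyr::filter(variant == "ce_corrected", n_het == 1)
  expect_false(mc$exhaustive)
  expect_true(ex$exhaustive)
  expect_lt(abs(mc$mean_bias - ex$mean_bias), 3 * mc$sem)
})

test_that("experiment runs are reproducible and refuse partial communities", {
  comm <- generate_community(pool_size = 10, seed = 2)
  des <- subsampling_design(n_grid = c(3, 5), n_draws = 30, seed = 6)
  expect_identical(subsampling_experiment(comm, des),
                   subsampling_experiment(comm, des))

  partial <- comm$data[1:6, ]
  expect_error(subsampling_experiment(partial, des, pool_size = 10),
               "fully observed")
})

test_that("sampling-error intervals scale correctly and hit exact zeros", {
  # no between-species variation: every subset gives the same estimate
  flat <- toy_community(rep(4, 6), rep(4 * (0.1 + 1 / 6), 6), q = 6)
  sei <- sampling_error_interval(flat, n_resamples = 50, seed = 1)
  expect_equal(sei$sd_ce, 0)
  expect_equal(sei$sd_se, 0)

  # complete sample: the design factor zeroes the interval
  comm <- generate_community(pool_size = 12, seed = 31)
  sei_full <- sampling_error_interval(comm$data, n_resamples = 50, seed = 2)
  expect_equal(sei_full$sd_ce, 0)
  expect_equal(sei_full$sd_se, 0)

  # incomplete sample: deterministic given seed, stable in n_resamples
  obs <- draw_subsets(comm, n_sub = 8, n_draws = 1, seed = 3)[[1]]
  s1 <- sampling_error_interval(obs, n_resamples = 400, seed = 7)
  s1b <- sampling_error_interval(obs, n_resamples = 400, seed = 7)
  expect_identical(s1, s1b)
  expect_gt(s1$sd_ce, 0)
  s2 <- sampling_error_interval(obs, n_resamples = 800, seed = 8)
  # doubling the resamples moves the estimate by less than its own MC error
  expect_lt(abs(s2$sd_ce - s1$sd_ce) / s1$sd_ce, 0.25)

  expect_error(
    sampling_error_interval(toy_community(c(1, 2), c(1, 2), q = 5)),
    "at least 3")
})

test_that("sampling-error intervals are calibrated against true sampling spread", {
  # the interval from one observed subset should approximate the true SD
  # of the estimator across independent subsets of the same size
  comm <- generate_community(pool_size = 40, seed = 55)
  n_obs <- 20
  draws <- draw_subsets(comm, n_sub = n_obs, n_draws = 300, seed = 5)
  true_sd <- stats::sd(vapply(draws, function(s)
    estimate_population(s, pool_size = 40)$ce_pop_hat, numeric(1)))
  seis <- vapply(draws[1:40], function(s)
    sampling_error_interval(s, n_resamples = 200, seed = 11)$sd_ce,
    numeric(1))
  # right order of magnitude: median interval within a factor 2 of truth
  expect_gt(stats::median(seis), true_sd / 2)
  expect_lt(stats::median(seis), true_sd * 2)
})

test_that("relative SD profile normalises to the smallest subsample size", {
  comm <- generate_community(pool_size = 15, seed = 12)
  des <- subsampling_design(n_grid = c(3, 8, 15), n_draws = 300, seed = 2,
                            exhaustive_threshold = 0)
  prof <- relative_sd_profile(subsampling_experiment(comm, des))
  expect_equal(nrow(prof), 6)
  expect_equal(prof$rel_sd[prof$N == 3],
               c(1, 1))
  expect_true(all(prof$rel_sd[prof$N == 15] == 0))
})

test_that("observation-error study: homogeneous replication shrinks spread", {
  comm <- generate_community(pool_size = 25, seed = 19)
  study <- observation_error_study(comm, cv = 0.4, m_reps_grid = c(1, 8),
                                   n_sub = 18, n_iter = 150, seed = 23)
  expect_equal(study$m_reps, c(1, 8))
  expect_lt(study$sd_ce[2], study$sd_ce[1])
  expect_lt(study$sd_se[2], study$sd_se[1])
})
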