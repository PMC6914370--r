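# Exhaustive-enumeration oracle: averages the corrected estimators over
# every subset of size n, computing each piece with direct formulas
# (stats::cov / means), independent of the package's vectorised paths.
enumerate_mean_estimates <- function(m, y, q, n) {
  dry <- y / m - 1 / q
  subsets <- utils::combn(length(m), n)
  ests <- apply(subsets, 2, function(idx) {
    ce_s <- n * mean(dry[idx]) * mean(m[idx])
    se_s <- n * stats::cov(dry[idx], m[idx])
    c(ce_finite = q / n * (ce_s - (q - n) / q * se_s / n),
      ce_large = q / n * (ce_s - se_s / n),
      se_hat = q * se_s / n,
      ce_s_scaled = ce_s / n)
  })
  rowMeans(ests)
}

test_that("sample-level statistics match hand evaluation with pool-referenced dRY", {
  sub <- toy_community(c(4, 2), c(3, 0.5), q = 10)
  st <- sample_statistics(sub)
  # dRY = [0.65, 0.15]; CE^S = 2 * 0.4 * 3; SE^S = 2 * cov_{N-1} = 2 * 0.5
  expect_equal(st$ce_sample, 2.4)
  expect_equal(st$se_sample, 1.0)
  expect_equal(st$n_sampled, 2)
  expect_equal(st$pool_size, 10)
})

test_that("sample SE vanishes when dRY is constant and matches the full-pool bookkeeping", {
  m <- c(1, 3, 8)
  y <- m * (0.2 + 1 / 3)  # dRY = 0.2 for everyone
  expect_equal(sample_statistics(toy_community(m, y, q = 3))$se_sample, 0)

  # a sample containing all Q species: SE^S = Q/(Q-1) x partition SE
  comm <- random_community(9, seed = 11)
  st <- sample_statistics(comm)
  pp <- partition(comm)
  expect_close(st$se_sample, pp$se * 9 / 8)
  expect_close(st$ce_sample, pp$ce)
})

test_that("population estimates follow the correction formulas", {
  # build a 2-species sample with known ce_sample, se_sample, then check
  # the arithmetic of both corrections on top of it
  sub <- toy_community(c(4, 2), c(3, 0.5), q = 10)
  st <- sample_statistics(sub)
  est_f <- estimate_population(sub, correction = "finite_Q")
  est_l <- estimate_population(sub, correction = "large_Q")
  q <- 10; n <- 2
  expect_equal(est_f$se_pop_hat, q * st$se_sample / n)
  expect_equal(est_f$ce_pop_hat,
               q / n * (st$ce_sample - (q - n) / q * st$se_sample / n))
  expect_equal(est_l$ce_pop_hat,
               q / n * (st$ce_sample - st$se_sample / n))
  expect_equal(est_f$correction, "finite_Q")

  # the documented worked numbers: ce_s = 2.4, se_s = 1.0
  expect_equal(est_f$se_pop_hat, 5)
  expect_equal(est_f$ce_pop_hat, 10 / 2 * (2.4 - 0.8 * 0.5))
})

test_that("a complete sample collapses the finite-pool correction", {
  comm <- random_community(12, seed = 5)
  est <- estimate_population(comm, correction = "finite_Q")
  st <- sample_statistics(comm)
  pp <- partition(comm)
  expect_equal(est$ce_pop_hat, st$ce_sample)
  expect_equal(est$se_pop_hat, st$se_sample)
  expect_close(est$ce_pop_hat, pp$ce)
})

test_that("finite-pool CE estimator is exactly unbiased over all subsets", {
  for (seed in 1:6) {
    q <- sample(5:9, 1)
    comm <- random_community(q, seed = 100 + seed)
    m <- comm$monoculture
    y <- comm$mixture
    dry <- y / m - 1 / q
    ce_pop <- q * mean(dry) * mean(m)
    se_pop_bessel <- q * stats::cov(dry, m)

    for (n in 2:q) {
      means <- enumerate_mean_estimates(m, y, q, n)
      # package path agrees with the oracle subset-by-subset mean
      pkg_means <- rowMeans(vapply(
        draw_subsets(comm, n, exhaustive = TRUE),
        function(s) {
          e <- estimate_population(s, pool_size = q)
          c(e$ce_pop_hat, e$se_pop_hat)
        }, numeric(2)))
      expect_close(pkg_means, means[c("ce_finite", "se_hat")])
      # unbiasedness: CE recovered exactly, SE targets the Bessel form
      expect_close(means[["ce_finite"]], ce_pop)
      expect_close(means[["se_hat"]], se_pop_bessel)
    }
  }
})

test_that("uncorrected CE bias over all subsets matches the analytic structure", {
  q <- 8
  comm <- random_community(q, seed = 42)
  m <- comm$monoculture
  dry <- comm$mixture / m - 1 / q
  ce_pop <- q * mean(dry) * mean(m)
  s_xz <- stats::cov(dry, m)
  for (n in c(2, 4, 6)) {
    means <- enumerate_mean_estimates(m, comm$mixture, q, n)
    expect_close(means[["ce_s_scaled"]] - ce_pop / q,
                 (q - n) / q * s_xz / n)
    # the large-pool correction leaves a deficit of exactly -S_xz
    expect_close(means[["ce_large"]] - ce_pop, -s_xz, rel_tol = 1e-8)
  }
})

test_that("large-pool and finite-pool corrections converge as Q grows", {
  ratios <- vapply(c(20, 200, 2000), function(q) {
    sub <- toy_community(c(40, 20, 10), c(30, 5, 3), q = q)
    f <- estimate_population(sub, correction = "finite_Q")$ce_pop_hat
    l <- estimate_population(sub, correction = "large_Q")$ce_pop_hat
    l / f
  }, numeric(1))
  expect_true(all(abs(ratios - 1) < c(0.2, 0.02, 0.002)))
  expect_lt(abs(ratios[3] - 1), abs(ratios[1] - 1))
})

test_that("estimators reject invalid sampling setups", {
  expect_error(estimate_population(toy_community(4, 3, q = 5)), "at least 2")
  expect_error(
    estimate_population(toy_community(c(4, 2), c(3, 1), q = 1)))
})

test_that("heterogeneous aggregation summarises draws correctly", {
  comm <- random_community(10, seed = 9)
  e <- estimate_population(draw_subsets(comm, 5, 1, seed = 1)[[1]],
                           pool_size = 10)
  same <- aggregate_heterogeneous(list(e, e, e))
  ce_row <- dplyr::filter(same, quantity == "ce_pop_hat")
  expect_equal(ce_row$mean, e$ce_pop_hat)
  expect_equal(ce_row$sd, 0)
  expect_equal(ce_row$n_replicates, 3)

  two <- aggregate_heterogeneous(
    tibble::tibble(ce_pop_hat = c(3, 5), se_pop_hat = c(1, 1),
                   pool_size = 10))
  ce2 <- dplyr::filter(two, quantity == "ce_pop_hat")
  expect_equal(ce2$mean, 4)
  expect_equal(ce2$sd, sqrt(2))
  expect_equal(ce2$sem, 1)

  single <- aggregate_heterogeneous(e)
  expect_true(all(is.na(single$sd)))

  expect_error(aggregate_heterogeneous(
    tibble::tibble(ce_pop_hat = 1:2, se_pop_hat = 1:2,
                   pool_size = c(5, 6))), "pool sizes")
})

test_that("more heterogeneous replicates mean tighter aggregated means", {
  comm <- generate_community(pool_size = 30, seed = 77)
  sd_of_means <- function(n_rep, seed) {
    batches <- withr::with_seed(seed, replicate(40, {
      draws <- draw_subsets(comm$data, n_sub = 10, n_draws = n_rep)
      ests <- purrr::map(draws, estimate_population, pool_size = 30)
      aggregate_heterogeneous(ests) |>
        dplyr::filter(quantity == "ce_pop_hat") |>
        dplyr::pull(mean)
    }))
    stats::sd(batches)
  }
  expect_lt(sd_of_means(30, seed = 1), sd_of_means(10, seed = 2))
  expect_lt(sd_of_means(10, seed = 3), sd_of_means(1, seed = 4))
})
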