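# Small in-code fixtures shared across test files.

# Community table from bare vectors; pool defaults to the species count.
toy_community <- function(m, y, q = length(m)) {
  out <- tibble::tibble(
    species_id = paste0("sp", seq_along(m)),
    monoculture = m,
    mixture = y)
  attr(out, "pool_size") <- q
  out
}

# Random fully observed community independent of the package's generator:
# used where the generator itself is under test or where an arbitrary
# valid input is all that is needed.
random_community <- function(q, seed) {
  withr::with_seed(seed, {
    m <- exp(stats::rnorm(q, log(50), 1))
    y <- pmax(m * (stats::rnorm(q, 0.1, 0.2) + 1 / q), 0)
    toy_community(m, y, q)
  })
}

rel_err <- function(actual, expected) {
  abs(actual - expected) / pmax(abs(expected), 1e-12)
}

expect_close <- function(actual, expected, rel_tol = 1e-9,
                         abs_tol = 1e-12) {
  ok <- abs(actual - expected) <= pmax(abs_tol, rel_tol * abs(expected))
  expect_true(all(ok),
              info = sprintf("max deviation %.3e from %s",
                             max(abs(actual - expected)),
                             paste(signif(expected, 6), collapse = ", ")))
}
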