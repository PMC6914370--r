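#' Sample-level complementarity and selection statistics
#'
#' Computes the uncorrected sample-level statistics \eqn{CE^S} and
#' \eqn{SE^S} from an incomplete random subsample of `N` species drawn
#' from a pool of `Q`:
#' \eqn{CE^S = N \overline{\Delta RY}^S \overline{M}^S} and
#' \eqn{SE^S = N\,\mathrm{Cov}_{N-1}(\Delta RY, M)}, where moments are
#' over the sampled species only. Two bookkeeping rules are load-bearing:
#' the \eqn{1/Q} term inside \eqn{\Delta RY} uses the *pool* size, never
#' the number of sampled species, and the covariance always uses the
#' Bessel \eqn{N-1} denominator — the correction formulas in
#' [estimate_population()] are only unbiased for that form.
#'
#' @inheritParams partition
#' @returns one-row tibble with columns `ce_sample`, `se_sample`,
#'   `n_sampled`, `pool_size`.
#' @examples
#' sub <- tibble::tibble(monoculture = c(4, 2), mixture = c(3, 0.5))
#' sample_statistics(sub, pool_size = 10)
#' @export
sample_statistics <- function(data, pool_size = NULL, expected_ry = NULL) {
  chk <- check_community(data, pool_size, min_n = 2L)
  dry <- compute_delta_ry(data, chk$pool_size, expected_ry)
  n <- nrow(dry)
  tibble::tibble(
    ce_sample = n * mean(dry$delta_ry) * mean(dry$monoculture),
    se_sample = n * stats::cov(dry$delta_ry, dry$monoculture),
    n_sampled = n,
    pool_size = chk$pool_size)
}

#' Estimate population-level effects from an incomplete species sample
#'
#' Bias-corrected estimators of the population-level complementarity and
#' selection effects of the full `Q`-species community, from monoculture
#' and mixture biomass of a simple random subsample of `N` species.
#' With sample statistics from [sample_statistics()],
#' \deqn{\widehat{SE}^P = \frac{Q}{N} SE^S,}
#' and for the complementarity effect either the large-pool form
#' \deqn{\widehat{CE}^P = \frac{Q}{N}\left(CE^S - \frac{SE^S}{N}\right)
#'   \quad (\code{correction = "large_Q"})}
#' or the finite-pool form, exactly unbiased for any \eqn{N \le Q} under
#' sampling without replacement and therefore the default,
#' \deqn{\widehat{CE}^P = \frac{Q}{N}\left(CE^S -
#'   \frac{Q-N}{Q}\,\frac{SE^S}{N}\right)
#'   \quad (\code{correction = "finite_Q"}).}
#'
#' The uncorrected \eqn{CE^S/N} overshoots \eqn{CE^P/Q} whenever the
#' selection effect is nonzero, because under a positive
#' \eqn{M}–\eqn{\Delta RY} covariance a subsample with high mean
#' monoculture biomass also has a high mean deviation in relative yield;
#' the correction removes exactly that sampling covariance. \eqn{SE^S}
#' needs no such correction. When `N = Q` the finite-pool factor
#' \eqn{(Q-N)/Q} vanishes and the estimate collapses to the sample value.
#'
#' Averaged over all subsets of size `N`, `ce_pop_hat` (finite form)
#' equals the population \eqn{CE} exactly, and `se_pop_hat` equals
#' \eqn{Q} times the Bessel-form (\eqn{Q-1} denominator) population
#' covariance of \eqn{(\Delta RY, M)} — i.e. \eqn{Q/(Q-1)} times the
#' count-denominator population \eqn{SE}.
#'
#' The method assumes the sampled species are a *random* subset of the
#' pool; it does not correct for biased species selection.
#'
#' @inheritParams partition
#' @param correction `"finite_Q"` (default, recommended for all pool
#'   sizes) or `"large_Q"`.
#' @returns object of class `bef_estimate`: list with `ce_pop_hat`,
#'   `se_pop_hat`, `ce_sample`, `se_sample`, `n_sampled`, `pool_size`,
#'   `correction`. Has [tidy()][generics::tidy],
#'   [glance()][generics::glance] and `print` methods.
#' @examples
#' sub <- tibble::tibble(monoculture = c(4, 2), mixture = c(3, 0.5))
#' estimate_population(sub, pool_size = 10)
#' @export
estimate_population <- function(data, pool_size = NULL,
                                correction = c("finite_Q", "large_Q"),
                                expected_ry = NULL) {
  correction <- match.arg(correction)
  st <- sample_statistics(data, pool_size, expected_ry)
  n <- st$n_sampled
  q <- st$pool_size

  shrink <- if (correction == "finite_Q") (q - n) / q else 1
  structure(
    list(
      ce_pop_hat = q / n * (st$ce_sample - shrink * st$se_sample / n),
      se_pop_hat = q * st$se_sample / n,
      ce_sample = st$ce_sample,
      se_sample = st$se_sample,
      n_sampled = n,
      pool_size = q,
      correction = correction),
    class = "bef_estimate")
}

#' Summarise estimates across heterogeneous replicates
#'
#' Heterogeneous replication means repeated independent random draws of
#' species subsets from the same pool (as opposed to homogeneous
#' replication, repeated measurement of one fixed community). This
#' summarises a set of such per-draw estimates into a mean, an SD across
#' draws and a standard error of the mean, per quantity.
#'
#' @param estimates a list of `bef_estimate` objects, or a tibble with
#'   (at least) columns `ce_pop_hat`, `se_pop_hat`, `pool_size` — one row
#'   per replicate draw. All replicates must share the same pool size.
#' @returns tibble with one row per quantity (`ce_pop_hat`, `se_pop_hat`,
#'   and the sample-level statistics when present) and columns `quantity`,
#'   `mean`, `sd`, `sem`, `n_replicates`. With a single replicate `sd` and
#'   `sem` are `NA`.
#' @examples
#' comm <- generate_community(pool_size = 12, seed = 1)
#' draws <- draw_subsets(comm$data, n_sub = 6, n_draws = 20, seed = 2)
#' ests <- purrr::map(draws, estimate_population, pool_size = 12)
#' aggregate_heterogeneous(ests)
#' @export
aggregate_heterogeneous <- function(estimates) {
  if (inherits(estimates, "bef_estimate")) estimates <- list(estimates)
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- purrr::map_dfr(estimates, function(e) {
      tibble::as_tibble(unclass(e)[c("ce_pop_hat", "se_pop_hat",
                                     "ce_sample", "se_sample",
                                     "n_sampled", "pool_size")])
    })
  }
  if (nrow(estimates) < 1) {
    rlang::abort("Need at least one estimate to aggregate.")
  }
  if (dplyr::n_distinct(estimates$pool_size) > 1) {
    rlang::abort(paste0(
      "Estimates mix different pool sizes (Q = ",
      paste(sort(unique(estimates$pool_size)), collapse = ", "),
      "); population-level effects are only comparable at a common Q."))
  }
  qty <- intersect(c("ce_pop_hat", "se_pop_hat", "ce_sample", "se_sample"),
                   names(estimates))
  n <- nrow(estimates)
  estimates |>
    dplyr::select(dplyr::all_of(qty)) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "quantity", values_to = "value") |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (n > 1) stats::sd(.data$value) else NA_real_,
      sem = if (n > 1) stats::sd(.data$value) / sqrt(n) else NA_real_,
      n_replicates = n,
      .groups = "drop") |>
    dplyr::arrange(match(.data$quantity, qty))
}
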