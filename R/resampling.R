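#' Describe a subsampling experiment
#'
#' Bundles the design choices of a subsampling experiment: which subsample
#' sizes to probe, how many Monte-Carlo draws per size, which
#' heterogeneous replicate counts to summarise, the seed, and the subset
#' count below which exact enumeration of all subsets replaces
#' Monte-Carlo.
#'
#' @param n_grid integer vector of subsample sizes N (each >= 2).
#' @param n_draws Monte-Carlo draws per N (default 20000, the scale at
#'   which the estimators were originally validated; scale down for quick
#'   runs).
#' @param n_het_reps heterogeneous replicate counts to summarise
#'   (default `c(1, 10, 30)`): the draws are cut into consecutive blocks
#'   of this size and the spread of block means is reported.
#' @param seed integer seed for the whole experiment; per-size substreams
#'   are derived from it deterministically.
#' @param exhaustive_threshold when `choose(N_available, N)` is at or
#'   below this, every subset is enumerated exactly once instead of
#'   sampling (making unbiasedness checks exact). Set to 0 to force pure
#'   Monte-Carlo everywhere.
#' @returns list of class `subsampling_design`.
#' @export
subsampling_design <- function(n_grid, n_draws = 20000,
                               n_het_reps = c(1, 10, 30),
                               seed = 1L, exhaustive_threshold = 1e5) {
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid < 2)) {
    rlang::abort("Every subsample size in `n_grid` must be >= 2.")
  }
  if (n_draws < 1) rlang::abort("`n_draws` must be >= 1.")
  if (any(n_het_reps < 1)) rlang::abort("`n_het_reps` must all be >= 1.")
  structure(
    list(n_grid = n_grid, n_draws = as.integer(n_draws),
         n_het_reps = sort(unique(as.integer(n_het_reps))),
         seed = as.integer(seed),
         exhaustive_threshold = exhaustive_threshold),
    class = "subsampling_design")
}

# Index matrix (n_sub x draws) of species subsets; exhaustive enumerates
# every combination exactly once, Monte-Carlo samples uniformly without
# replacement within a draw, independently across draws.
draw_index_matrix <- function(n_avail, n_sub, n_draws, seed = NULL,
                              exhaustive = FALSE) {
  if (n_sub > n_avail) {
    rlang::abort(paste0("Cannot draw ", n_sub, " species from ", n_avail,
                        " available."))
  }
  if (exhaustive) {
    return(utils::combn(n_avail, n_sub))
  }
  mc <- function() {
    vapply(seq_len(n_draws),
           function(i) sample.int(n_avail, n_sub),
           integer(n_sub))
  }
  idx <- if (is.null(seed)) mc() else withr::with_seed(seed, mc())
  if (n_sub == 1L) idx <- matrix(idx, nrow = 1L)
  idx
}

#' Draw random species subsets from a fully observed community
#'
#' Simulates incomplete sampling: each draw is a uniform random subset of
#' `n_sub` species taken without replacement (duplicate subsets may recur
#' across draws). Every subset keeps the full community's pool size, so
#' downstream statistics stay referenced to the complete pool.
#'
#' @param data fully observed community table (all pool species with
#'   monoculture biomass present), or a `bef_community`.
#' @param n_sub subset size, `2 <= n_sub <= nrow(data)`.
#' @param n_draws number of subsets (ignored when `exhaustive = TRUE`).
#' @param seed integer seed for reproducible draws.
#' @param exhaustive return every `choose(nrow(data), n_sub)` subset
#'   exactly once.
#' @returns list of tibbles, each a subset of `data`'s rows with the
#'   `pool_size` attribute carried over.
#' @examples
#' comm <- generate_community(pool_size = 6, seed = 1)
#' length(draw_subsets(comm, n_sub = 3, exhaustive = TRUE))  # choose(6,3)
#' @export
draw_subsets <- function(data, n_sub, n_draws = 1L, seed = NULL,
                         exhaustive = FALSE) {
  if (inherits(data, "bef_community")) data <- data$data
  pool <- attr(data, "pool_size")
  idx <- draw_index_matrix(nrow(data), n_sub, n_draws, seed, exhaustive)
  lapply(seq_len(ncol(idx)), function(j) {
    out <- data[idx[, j], , drop = FALSE]
    attr(out, "pool_size") <- pool
    out
  })
}

#' Predicted bias of the uncorrected sample-level complementarity effect
#'
#' Expected value of \eqn{CE^S/N - CE^P/Q} under simple random sampling
#' without replacement of `n_sub` species from a pool of `pool_size`:
#' \deqn{\frac{Q-N}{Q}\,\frac{S_{xz}}{N},} where
#' \eqn{S_{xz} = } `se_pop_bessel` \eqn{/Q} is the Bessel-form population
#' covariance between deviation in relative yield and monoculture
#' biomass. The bias is proportional to the selection effect and decays
#' as \eqn{1/N}, vanishing at \eqn{N = Q}.
#'
#' @param se_pop_bessel population selection effect in Bessel form
#'   (`Q * cov(delta_ry, M)` with the Q-1 denominator), g/m^2.
#' @param n_sub,pool_size subsample and pool sizes.
#' @returns predicted bias on the per-pool-species (\eqn{CE/Q}) scale.
#' @examples
#' predicted_bias(se_pop_bessel = 10, n_sub = 5, pool_size = 10)  # 0.1
#' @export
predicted_bias <- function(se_pop_bessel, n_sub, pool_size) {
  if (any(n_sub < 2) || any(n_sub > pool_size)) {
    rlang::abort("`n_sub` must satisfy 2 <= n_sub <= pool_size.")
  }
  (pool_size - n_sub) / pool_size * (se_pop_bessel / pool_size) / n_sub
}

# SD of consecutive-block means of x for one block size; NA when fewer
# than 2 complete blocks exist.
block_sd <- function(x, block) {
  n_blocks <- length(x) %/% block
  if (n_blocks < 2) return(NA_real_)
  xb <- x[seq_len(n_blocks * block)]
  stats::sd(colMeans(matrix(xb, nrow = block)))
}

#' Subsampling experiment: bias and sampling error across subsample sizes
#'
#' For each subsample size N in the design, repeatedly draws N species
#' from a fully observed community, computes uncorrected sample-level and
#' corrected (finite-pool) population-level complementarity/selection
#' statistics per draw, and summarises their bias against the known
#' population values and their spread across draws and across
#' heterogeneous replicate blocks.
#'
#' Uncorrected variants are reported on the per-pool-species scale
#' (\eqn{CE^S/N - CE^P/Q}, \eqn{SE^S/N - SE^P_{Bessel}/Q}) so that the
#' analytic curve from [predicted_bias()] applies directly; corrected
#' variants are on the full population scale. The SE reference is the
#' Bessel-form population value, the quantity the SE estimator is
#' unbiased for.
#'
#' When `choose(N_available, N)` is at or below the design's
#' `exhaustive_threshold`, all subsets are enumerated exactly once, so
#' mean biases are exact expectations rather than Monte-Carlo estimates.
#'
#' @param community a `bef_community` from [generate_community()], or a
#'   fully observed community table (then `pool_size` is required).
#' @param design a [subsampling_design()].
#' @param pool_size pool size Q, only needed when `community` is a bare
#'   table without a `pool_size` attribute.
#' @returns tibble of class `bef_bias_curve` with columns `N`, `variant`
#'   (`ce_uncorrected`, `se_uncorrected`, `ce_corrected`, `se_corrected`),
#'   `n_het`, `mean_bias`, `sd` (spread of block means of size `n_het`;
#'   at `n_het = 1`, across draws), `sem` (Monte-Carlo standard error of
#'   `mean_bias`), `predicted_bias` (analytic, nonzero only for
#'   `ce_uncorrected`), `n_draws`, `exhaustive`. The realized population
#'   truth is attached as attribute `truth`.
#' @examples
#' comm <- generate_community(pool_size = 12, seed = 1)
#' des <- subsampling_design(n_grid = c(3, 6, 12), n_draws = 200,
#'                           n_het_reps = c(1, 10), seed = 2)
#' subsampling_experiment(comm, des)
#' @export
subsampling_experiment <- function(community, design, pool_size = NULL) {
  if (inherits(community, "bef_community")) community <- community$data
  chk <- check_community(community, pool_size, min_n = 2L)
  if (chk$n < chk$pool_size) {
    rlang::abort(paste0(
      "The experiment needs a fully observed community: ", chk$n,
      " species with monoculture data but pool_size = ", chk$pool_size, "."))
  }
  q <- chk$pool_size
  dry <- compute_delta_ry(community, q)
  m <- dry$monoculture
  x <- dry$delta_ry

  truth <- tibble::tibble(
    ce = q * mean(x) * mean(m),
    se = q * cov_n(x, m),
    net = sum(x * m),
    se_bessel = q * stats::cov(x, m))

  if (any(design$n_grid > chk$n)) {
    rlang::abort("`n_grid` contains sizes larger than the community.")
  }
  sub_seeds <- withr::with_seed(
    design$seed,
    sample.int(.Machine$integer.max - 1L, length(design$n_grid)))

  per_n <- purrr::map2(design$n_grid, sub_seeds, function(n, sd_n) {
    n_subsets <- choose(chk$n, n)
    exhaustive <- n_subsets <= design$exhaustive_threshold
    idx <- draw_index_matrix(chk$n, n, design$n_draws, sd_n, exhaustive)
    nd <- ncol(idx)

    xm <- matrix(x[idx], nrow = n)
    mm <- matrix(m[idx], nrow = n)
    mean_x <- colMeans(xm)
    mean_m <- colMeans(mm)
    # Bessel-form sample covariance per draw
    cov_s <- (colMeans(xm * mm) - mean_x * mean_m) * n / (n - 1)

    ce_s <- n * mean_x * mean_m
    se_s <- n * cov_s
    ce_hat <- q / n * (ce_s - (q - n) / q * se_s / n)
    se_hat <- q * se_s / n

    per_draw <- list(
      ce_uncorrected = ce_s / n - truth$ce / q,
      se_uncorrected = se_s / n - truth$se_bessel / q,
      ce_corrected = ce_hat - truth$ce,
      se_corrected = se_hat - truth$se_bessel)
    pred <- c(ce_uncorrected = predicted_bias(truth$se_bessel, n, q),
              se_uncorrected = 0, ce_corrected = 0, se_corrected = 0)

    purrr::imap_dfr(per_draw, function(b, variant) {
      sd1 <- if (nd > 1) stats::sd(b) else 0
      pred_v <- pred[[variant]]
      sd_het <- vapply(design$n_het_reps,
                       function(h) if (h == 1) sd1 else block_sd(b, h),
                       numeric(1))
      tibble::tibble(
        N = n, variant = variant, n_het = design$n_het_reps,
        mean_bias = mean(b), sd = sd_het, sem = sd1 / sqrt(nd),
        predicted_bias = pred_v, n_draws = nd, exhaustive = exhaustive)
    })
  })

  out <- dplyr::bind_rows(per_n)
  attr(out, "truth") <- truth
  attr(out, "pool_size") <- q
  class(out) <- c("bef_bias_curve", class(out))
  out
}

#' Sampling-error interval for an incomplete sample
#'
#' Estimates how much of the uncertainty in the corrected
#' complementarity/selection estimates is attributable to incomplete
#' sampling of the species pool, given only the N observed species. The
#' procedure draws `n_resamples` sub-subsamples of size `n_prime < N`
#' from the observed species, re-applies the finite-pool correction to
#' each (still referenced to the full pool Q), measures the spread of the
#' resulting estimates, and rescales that spread by the design-based
#' variance factor \eqn{(1/N - 1/Q)\,/\,(1/N' - 1/N)} linking the
#' sub-subsample size to the actual sample size. This is a documented
#' approximation: the dispersion of size-\eqn{N'} estimates around the
#' size-\eqn{N} estimate carries variance \eqn{\propto 1/N' - 1/N},
#' whereas the target sampling variance at size \eqn{N} from a pool of
#' \eqn{Q} is \eqn{\propto 1/N - 1/Q} (exact for mean-like statistics
#' under sampling without replacement, approximate for the product and
#' covariance terms here). At \eqn{N = Q} the factor is 0: a complete
#' sample has no sampling error.
#'
#' @inheritParams partition
#' @param n_resamples number of sub-subsamples (default 1000).
#' @param seed integer seed.
#' @param n_prime sub-subsample size, `2 <= n_prime < N`; default
#'   `max(2, floor(N / 2))`.
#' @returns one-row tibble with `sd_ce`, `sd_se` (g/m^2), `n_observed`,
#'   `pool_size`, `n_prime`, `n_resamples`.
#' @examples
#' comm <- generate_community(pool_size = 30, seed = 1)
#' obs <- draw_subsets(comm, n_sub = 15, n_draws = 1, seed = 2)[[1]]
#' sampling_error_interval(obs, n_resamples = 200, seed = 3)
#' @export
sampling_error_interval <- function(data, pool_size = NULL,
                                    n_resamples = 1000, seed = NULL,
                                    n_prime = NULL) {
  chk <- check_community(data, pool_size, min_n = 3L)
  n <- chk$n
  q <- chk$pool_size
  if (is.null(n_prime)) n_prime <- max(2L, n %/% 2L)
  if (n_prime < 2 || n_prime >= n) {
    rlang::abort("`n_prime` must satisfy 2 <= n_prime < N.")
  }

  dry <- compute_delta_ry(data, q)
  x <- dry$delta_ry
  m <- dry$monoculture
  idx <- draw_index_matrix(n, n_prime, n_resamples, seed)

  xm <- matrix(x[idx], nrow = n_prime)
  mm <- matrix(m[idx], nrow = n_prime)
  mean_x <- colMeans(xm)
  mean_m <- colMeans(mm)
  cov_s <- (colMeans(xm * mm) - mean_x * mean_m) * n_prime / (n_prime - 1)
  ce_s <- n_prime * mean_x * mean_m
  se_s <- n_prime * cov_s
  ce_hat <- q / n_prime * (ce_s - (q - n_prime) / q * se_s / n_prime)
  se_hat <- q * se_s / n_prime

  scale <- (1 / n - 1 / q) / (1 / n_prime - 1 / n)
  tibble::tibble(
    sd_ce = stats::sd(ce_hat) * sqrt(scale),
    sd_se = stats::sd(se_hat) * sqrt(scale),
    n_observed = n, pool_size = q,
    n_prime = n_prime, n_resamples = as.integer(n_resamples))
}

#' Observation-error study with homogeneous replication
#'
#' Quantifies how measurement noise propagates into the corrected
#' estimators and how much homogeneous replication (repeated measurement
#' of the same community, averaged per species) suppresses it. Each
#' iteration injects fresh multiplicative observation error at the given
#' CV (averaged over `m_reps` replicate measurements), draws one random
#' subset of `n_sub` species, and applies [estimate_population()]; the
#' spread across iterations mixes observation error and sampling error,
#' as it does in real studies.
#'
#' @param community `bef_community` or fully observed community table.
#' @param cv observation-error coefficient of variation (see
#'   [calibrate_cv()]).
#' @param m_reps_grid homogeneous replicate counts to compare.
#' @param n_sub subset size drawn per iteration.
#' @param n_iter iterations per `m_reps` value.
#' @param seed integer seed.
#' @param pool_size required when `community` is a bare table without a
#'   `pool_size` attribute.
#' @returns tibble with one row per `m_reps`: `m_reps`, `mean_ce`,
#'   `sd_ce`, `mean_se`, `sd_se`, `n_sub`, `n_iter`, `cv`.
#' @examples
#' comm <- generate_community(pool_size = 20, seed = 1)
#' observation_error_study(comm, cv = 0.2, m_reps_grid = c(1, 4),
#'                         n_sub = 15, n_iter = 50, seed = 2)
#' @export
observation_error_study <- function(community, cv, m_reps_grid = c(1, 4),
                                    n_sub, n_iter = 200, seed = 1L,
                                    pool_size = NULL) {
  if (inherits(community, "bef_community")) community <- community$data
  chk <- check_community(community, pool_size, min_n = 2L)
  q <- chk$pool_size
  data <- chk$part

  purrr::map_dfr(m_reps_grid, function(mr) {
    ests <- withr::with_seed(seed, {
      purrr::map_dfr(seq_len(n_iter), function(i) {
        noisy <- add_observation_error(data, cv = cv, m_reps = mr)
        sub <- noisy[sample.int(nrow(noisy), n_sub), , drop = FALSE]
        e <- estimate_population(sub, pool_size = q)
        tibble::tibble(ce = e$ce_pop_hat, se = e$se_pop_hat)
      })
    })
    tibble::tibble(
      m_reps = mr,
      mean_ce = mean(ests$ce), sd_ce = stats::sd(ests$ce),
      mean_se = mean(ests$se), sd_se = stats::sd(ests$se),
      n_sub = n_sub, n_iter = n_iter, cv = cv)
  })
}

#' Relative sampling-error profile across subsample sizes
#'
#' Condenses a bias curve into the "how many monocultures are enough"
#' question: the SD of the corrected estimates as a function of N,
#' normalised by the SD at the smallest N in the grid. Useful for
#' checking the rule of thumb that estimates stabilise once at least half
#' of the community has been sampled in monoculture (N > Q/2).
#'
#' @param bias_curve output of [subsampling_experiment()].
#' @returns tibble with columns `N`, `variant` (`ce_corrected`,
#'   `se_corrected`), `sd`, `rel_sd` (`sd` divided by the SD at the
#'   smallest N for that variant).
#' @export
relative_sd_profile <- function(bias_curve) {
  bias_curve |>
    dplyr::filter(.data$variant %in% c("ce_corrected", "se_corrected"),
                  .data$n_het == 1) |>
    dplyr::group_by(.data$variant) |>
    dplyr::mutate(rel_sd = .data$sd / .data$sd[which.min(.data$N)]) |>
    dplyr::ungroup() |>
    dplyr::select("N", "variant", "sd", "rel_sd")
}
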