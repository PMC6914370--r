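#' Deviation in relative yield
#'
#' Adds the per-species deviation in relative yield,
#' \eqn{\Delta RY_i = Y_i / M_i - 1/Q}, to a community table. \eqn{Y_i} is
#' species \eqn{i}'s biomass in the mixture, \eqn{M_i} its monoculture
#' biomass, and \eqn{1/Q} the expected relative yield under proportional
#' sowing from a pool of \eqn{Q} species. Note that \eqn{Q} is the full
#' pool size, not the number of rows: when the table covers only a sampled
#' subset of species the \eqn{1/Q} term must still use the pool, which is
#' what keeps subsample statistics commensurate with the full community.
#'
#' @inheritParams partition
#' @param expected_ry optional numeric vector of per-species expected
#'   relative yields replacing the default \eqn{1/Q} (one value per row of
#'   `data`, in row order), supporting alternative null models. The default
#'   `NULL` uses \eqn{1/Q} for every species.
#' @returns the participating rows of `data` (monoculture > 0) as a tibble
#'   with an added `delta_ry` column, in the original row order.
#' @examples
#' comm <- tibble::tibble(species_id = c("a", "b"),
#'                        monoculture = c(4, 2), mixture = c(3, 0.5))
#' compute_delta_ry(comm, pool_size = 2)
#' @export
compute_delta_ry <- function(data, pool_size = NULL, expected_ry = NULL) {
  chk <- check_community(data, pool_size, min_n = 1L)
  part <- chk$part

  zero_m <- !is.na(data$monoculture) & data$monoculture == 0 &
    !is.na(data$mixture) & data$mixture > 0
  if (any(zero_m)) {
    ids <- if ("species_id" %in% names(data)) data$species_id[zero_m]
           else which(zero_m)
    rlang::abort(paste0(
      "Deviation in relative yield is undefined for species with zero ",
      "monoculture biomass but positive mixture biomass: ",
      paste(ids, collapse = ", "),
      ". Treat them as pool-only species (monoculture = NA)."))
  }

  if (is.null(expected_ry)) {
    ery <- rep(1 / chk$pool_size, chk$n)
  } else {
    if (length(expected_ry) != nrow(data)) {
      rlang::abort("`expected_ry` must have one value per row of `data`.")
    }
    keep <- !is.na(data$monoculture) & data$monoculture > 0 &
      !is.na(data$mixture)
    ery <- expected_ry[keep]
  }
  dplyr::mutate(part, delta_ry = .data$mixture / .data$monoculture - ery)
}

#' Partition the net biodiversity effect into complementarity and selection
#'
#' The additive partition of the net biodiversity effect. For a community
#' of \eqn{N} participating species from a pool of \eqn{Q},
#' \deqn{\Delta Y = \sum_i \Delta RY_i M_i
#'       = N \overline{\Delta RY}\,\overline{M}
#'       + N \,\mathrm{Cov}(\Delta RY, M),}
#' so the total deviation in yield splits into a complementarity effect
#' \eqn{CE = N \overline{\Delta RY}\,\overline{M}} and a selection effect
#' \eqn{SE = N\,\mathrm{Cov}(\Delta RY, M)}.
#'
#' The covariance denominator matters and is recorded explicitly:
#' `"partition"` uses the count denominator \eqn{N}, under which
#' \eqn{CE + SE = \Delta Y} holds exactly for any community;
#' `"estimator"` uses the Bessel denominator \eqn{N - 1} (as `stats::cov`
#' and most software), which is what the finite-pool correction formulas
#' in [estimate_population()] require. The two differ by a factor
#' \eqn{N/(N-1)} in SE only.
#'
#' Species with missing or zero monoculture biomass are excluded from the
#' \eqn{N} participating records but remain counted in the pool `Q`
#' (their deviation in relative yield is undefined).
#'
#' @param data data frame with columns `monoculture` and `mixture` (biomass
#'   per unit area, conventionally g/m^2) and optionally `species_id`.
#' @param pool_size total species pool size `Q` of the mixture community
#'   (>= number of rows). Defaults to `attr(data, "pool_size")` when present.
#' @param convention covariance denominator: `"partition"` (denominator N;
#'   additivity exact) or `"estimator"` (denominator N - 1).
#' @param expected_ry optional alternative null expectation, see
#'   [compute_delta_ry()].
#' @returns object of class `bef_partition`: list with elements `ce`, `se`,
#'   `net` (g/m^2), `n_species`, `pool_size`, `convention`. Has
#'   [tidy()][generics::tidy], [glance()][generics::glance] and `print`
#'   methods.
#' @examples
#' comm <- tibble::tibble(monoculture = c(4, 2), mixture = c(3, 0.5))
#' partition(comm, pool_size = 2)
#' @seealso [partition_via_ols()] for the regression form,
#'   [estimate_population()] for incomplete samples.
#' @export
partition <- function(data, pool_size = NULL,
                      convention = c("partition", "estimator"),
                      expected_ry = NULL) {
  convention <- match.arg(convention)
  chk <- check_community(data, pool_size, min_n = 2L)
  dry <- compute_delta_ry(data, chk$pool_size, expected_ry)

  n <- nrow(dry)
  m <- dry$monoculture
  x <- dry$delta_ry
  cv <- if (convention == "partition") cov_n(x, m) else stats::cov(x, m)

  new_bef_partition(
    ce = n * mean(x) * mean(m),
    se = n * cv,
    net = sum(x * m),
    n_species = n,
    pool_size = chk$pool_size,
    convention = convention)
}

new_bef_partition <- function(ce, se, net, n_species, pool_size, convention) {
  structure(
    list(ce = ce, se = se, net = net, n_species = n_species,
         pool_size = pool_size, convention = convention),
    class = "bef_partition")
}

#' Partition via ordinary least squares regression
#'
#' Recomputes the complementarity/selection partition from the point-slope
#' regression of the deviation in relative yield on monoculture biomass,
#' \eqn{\widehat{\Delta RY}_i = \beta_0 + \beta_1 M_i}. Then
#' \eqn{CE = N \overline{M} (\beta_0 + \beta_1 \overline{M})} and
#' \eqn{SE = N \beta_1 \mathrm{Var}(M)}, with `Var` taken under the same
#' denominator convention as [partition()]. The result is algebraically
#' identical to [partition()]; the regression form is useful for
#' visualising how sample-level statistics drift when only part of the
#' pool is observed (the fitted slope is stable under subsampling, the
#' sample means are not).
#'
#' @inheritParams partition
#' @returns a `bef_partition`, identical to `partition(data, ...)` up to
#'   floating-point error.
#' @examples
#' comm <- tibble::tibble(monoculture = c(4, 2), mixture = c(3, 0.5))
#' partition_via_ols(comm, pool_size = 2)
#' @export
partition_via_ols <- function(data, pool_size = NULL,
                              convention = c("partition", "estimator"),
                              expected_ry = NULL) {
  convention <- match.arg(convention)
  chk <- check_community(data, pool_size, min_n = 2L)
  dry <- compute_delta_ry(data, chk$pool_size, expected_ry)

  m <- dry$monoculture
  if (var_n(m) <= 0) {
    rlang::abort(paste0(
      "All monoculture biomasses are equal: the regression slope is ",
      "undefined. Use `partition()` instead (its selection effect is ",
      "exactly 0 here)."))
  }
  n <- nrow(dry)
  fit <- stats::lm(delta_ry ~ monoculture, data = dry)
  beta <- stats::coef(fit)
  v <- if (convention == "partition") var_n(m) else stats::var(m)

  new_bef_partition(
    ce = n * mean(m) * (beta[[1]] + beta[[2]] * mean(m)),
    se = n * beta[[2]] * v,
    net = sum(dry$delta_ry * m),
    n_species = n,
    pool_size = chk$pool_size,
    convention = convention)
}

#' Net biodiversity effect
#'
#' Total deviation in yield
#' \eqn{\Delta Y = \sum_i (Y_i - M_i/Q) = \sum_i \Delta RY_i M_i}: observed
#' mixture yield minus the yield expected if every species produced its
#' monoculture biomass scaled by its expected share \eqn{1/Q}.
#'
#' @inheritParams partition
#' @returns a single number (g/m^2).
#' @examples
#' net_biodiversity_effect(
#'   tibble::tibble(monoculture = c(4, 2), mixture = c(3, 0.5)),
#'   pool_size = 2)
#' @export
net_biodiversity_effect <- function(data, pool_size = NULL,
                                    expected_ry = NULL) {
  chk <- check_community(data, pool_size, min_n = 1L)
  dry <- compute_delta_ry(data, chk$pool_size, expected_ry)
  sum(dry$delta_ry * dry$monoculture)
}

#' Exponentiated Shannon diversity
#'
#' Effective number of equally abundant species,
#' \eqn{e^H = \exp(-\sum_i p_i \ln p_i)} with \eqn{p_i} the biomass share
#' of species \eqn{i}. Species with zero biomass contribute nothing.
#'
#' @param biomasses numeric vector of non-negative biomasses, at least one
#'   positive.
#' @returns a single number in `[1, length(biomasses)]`.
#' @examples
#' exp_shannon_diversity(c(1, 1, 1))   # 3: maximum evenness
#' exp_shannon_diversity(c(10, 0, 0))  # 1: a single species
#' @export
exp_shannon_diversity <- function(biomasses) {
  if (!is.numeric(biomasses) || any(is.na(biomasses)) || any(biomasses < 0)) {
    rlang::abort("`biomasses` must be non-negative numbers without NA.")
  }
  pos <- biomasses[biomasses > 0]
  if (length(pos) == 0) {
    rlang::abort("All biomasses are zero: diversity is undefined.")
  }
  p <- pos / sum(pos)
  exp(-sum(p * log(p)))
}
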