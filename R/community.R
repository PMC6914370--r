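#' Validate a community biomass table
#'
#' Internal gatekeeper used by every statistic in the package. A community
#' table pairs each species' monoculture biomass with its biomass in a
#' multi-species mixture. Species without usable monoculture data
#' (missing, or measured zero) cannot contribute a deviation in relative
#' yield and are set aside: they stay in the species pool `Q` but drop out
#' of the `N` participating records.
#'
#' @param data data frame with columns `monoculture` and `mixture`
#'   (biomass, conventionally g/m^2) and optionally `species_id`.
#' @param pool_size total number of species `Q` in the mixture community,
#'   including species without monoculture data. Falls back to
#'   `attr(data, "pool_size")` (set by [read_community()] and
#'   [generate_community()]).
#' @param min_n minimum number of participating species required.
#' @returns list with `part` (tibble of participating rows, `delta_ry`-ready),
#'   `n` (N), `pool_size` (Q), `dropped` (species_ids excluded from N).
#' @noRd
check_community <- function(data, pool_size = NULL, min_n = 1L,
                            call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame of species biomasses.",
                 call = call)
  }
  missing_cols <- setdiff(c("monoculture", "mixture"), names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("`data` is missing column(s): ",
             paste0("`", missing_cols, "`", collapse = ", "), "."),
      call = call)
  }
  data <- tibble::as_tibble(data)
  if (!"species_id" %in% names(data)) {
    data$species_id <- paste0("sp", seq_len(nrow(data)))
  }

  if (is.null(pool_size)) pool_size <- attr(data, "pool_size")
  if (is.null(pool_size)) {
    rlang::abort(
      paste0("`pool_size` (Q) must be supplied: it is the total number of ",
             "species in the mixture community and cannot be inferred from ",
             "the number of rows, which may cover only sampled species."),
      call = call)
  }
  pool_size <- as.integer(pool_size)
  if (length(pool_size) != 1L || is.na(pool_size) || pool_size < 1L) {
    rlang::abort("`pool_size` must be a single integer >= 1.", call = call)
  }

  bad <- !is.na(data$mixture) & data$mixture < 0 |
    !is.na(data$monoculture) & data$monoculture < 0
  if (any(bad)) {
    rlang::abort(
      paste0("Negative biomass for species: ",
             paste(data$species_id[bad], collapse = ", "), "."),
      call = call)
  }

  usable <- !is.na(data$monoculture) & data$monoculture > 0 &
    !is.na(data$mixture)
  part <- data[usable, , drop = FALSE]
  dropped <- data$species_id[!usable]

  if (nrow(data) > pool_size) {
    rlang::abort(
      paste0("`pool_size` (", pool_size, ") is smaller than the number of ",
             "species rows (", nrow(data), ")."),
      call = call)
  }
  if (nrow(part) < min_n) {
    rlang::abort(
      paste0("Need at least ", min_n, " species with monoculture biomass ",
             "> 0; got ", nrow(part), "."),
      call = call)
  }
  list(part = part, n = nrow(part), pool_size = pool_size, dropped = dropped)
}

# Count-denominator covariance/variance (population convention). stats::cov
# carries the Bessel N-1 denominator used by the estimator convention.
cov_n <- function(x, z) mean(x * z) - mean(x) * mean(z)
var_n <- function(x) cov_n(x, x)
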