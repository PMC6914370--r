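#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a partition result
#'
#' @param x a `bef_partition` from [partition()] or [partition_via_ols()].
#' @param ... unused.
#' @returns tibble with columns `term` (`complementarity`, `selection`,
#'   `net`) and `estimate` (g/m^2).
#' @method tidy bef_partition
#' @export
tidy.bef_partition <- function(x, ...) {
  tibble::tibble(
    term = c("complementarity", "selection", "net"),
    estimate = c(x$ce, x$se, x$net))
}

#' @rdname tidy.bef_partition
#' @returns for `glance()`: a one-row tibble with `ce`, `se`, `net`,
#'   `n_species`, `pool_size`, `convention`.
#' @method glance bef_partition
#' @export
glance.bef_partition <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
print.bef_partition <- function(x, ...) {
  cat("Net biodiversity effect partition (", x$convention,
      " convention)\n", sep = "")
  cat(sprintf("  N = %d species sampled, pool Q = %d\n",
              x$n_species, x$pool_size))
  cat(sprintf("  complementarity effect: %10.4g g/m^2\n", x$ce))
  cat(sprintf("  selection effect:       %10.4g g/m^2\n", x$se))
  cat(sprintf("  net effect:             %10.4g g/m^2\n", x$net))
  invisible(x)
}

#' Tidy a population-level estimate
#'
#' @param x a `bef_estimate` from [estimate_population()].
#' @param ... unused.
#' @returns tibble with columns `term` (`ce_pop_hat`, `se_pop_hat`,
#'   `ce_sample`, `se_sample`) and `estimate` (g/m^2).
#' @method tidy bef_estimate
#' @export
tidy.bef_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("ce_pop_hat", "se_pop_hat", "ce_sample", "se_sample"),
    estimate = c(x$ce_pop_hat, x$se_pop_hat, x$ce_sample, x$se_sample))
}

#' @rdname tidy.bef_estimate
#' @returns for `glance()`: a one-row tibble with every estimate field
#'   plus `n_sampled`, `pool_size`, `correction`.
#' @method glance bef_estimate
#' @export
glance.bef_estimate <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
print.bef_estimate <- function(x, ...) {
  cat("Population-level effects estimated from an incomplete sample\n")
  cat(sprintf("  N = %d of Q = %d species; correction: %s\n",
              x$n_sampled, x$pool_size, x$correction))
  cat(sprintf("  complementarity (pop.): %10.4g g/m^2  (sample: %.4g)\n",
              x$ce_pop_hat, x$ce_sample))
  cat(sprintf("  selection (pop.):       %10.4g g/m^2  (sample: %.4g)\n",
              x$se_pop_hat, x$se_sample))
  invisible(x)
}
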