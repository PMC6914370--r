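#' Read a community biomass table
#'
#' Reads a delimited text file with columns `species_id`,
#' `monoculture_biomass`, `mixture_biomass` and an optional
#' `replicate_id`. A missing monoculture field (empty or `NA`) marks a
#' species that is in the pool but was never grown in monoculture — it
#' stays in the bookkeeping for `Q` but cannot enter the `N` participating
#' records — whereas the string `"0"` means a measured zero. When
#' `replicate_id` is present, replicates are homogeneous repeated
#' measurements of the same community: biomasses are averaged per species
#' before analysis and the raw replicate matrix is kept (attribute
#' `replicates`) for [calibrate_cv()].
#'
#' @param path file path.
#' @param pool_size total pool size `Q` (>= number of distinct species in
#'   the file), or `"infer_with_warning"` to fall back on the species
#'   count — a warning is issued because files commonly cover only the
#'   sampled species, in which case the inferred `Q` is too small.
#' @param delim field delimiter (default comma).
#' @returns tibble with columns `species_id`, `monoculture`, `mixture`,
#'   with attributes `pool_size` and (when applicable) `replicates`, a
#'   long tibble of the raw replicate measurements.
#' @export
read_community <- function(path, pool_size, delim = ",") {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path))
  }
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      species_id = readr::col_character(),
      monoculture_biomass = readr::col_double(),
      mixture_biomass = readr::col_double(),
      .default = readr::col_guess()))
  needed <- c("species_id", "monoculture_biomass", "mixture_biomass")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Missing column(s): ",
                        paste(missing_cols, collapse = ", "), "."))
  }

  for (col in c("monoculture_biomass", "mixture_biomass")) {
    bad <- which(!is.na(raw[[col]]) &
                   (raw[[col]] < 0 | !is.finite(raw[[col]])))
    if (length(bad) > 0) {
      rlang::abort(paste0(
        "Negative or non-finite ", col, " in row(s) ",
        paste(bad, collapse = ", "), " (species ",
        paste(raw$species_id[bad], collapse = ", "), ")."))
    }
  }

  has_reps <- "replicate_id" %in% names(raw)
  key <- if (has_reps) paste(raw$species_id, raw$replicate_id, sep = "\r")
         else raw$species_id
  if (anyDuplicated(key)) {
    dup <- unique(raw$species_id[duplicated(key)])
    rlang::abort(paste0("Duplicate species within a replicate: ",
                        paste(dup, collapse = ", "), "."))
  }

  replicates <- NULL
  if (has_reps) {
    replicates <- raw |>
      dplyr::select("species_id", "replicate_id",
                    "monoculture_biomass", "mixture_biomass") |>
      tidyr::pivot_longer(c("monoculture_biomass", "mixture_biomass"),
                          names_to = "measure", values_to = "biomass")
    raw <- raw |>
      dplyr::group_by(.data$species_id) |>
      dplyr::summarise(
        monoculture_biomass =
          mean_or_na(.data$monoculture_biomass),
        mixture_biomass = mean_or_na(.data$mixture_biomass),
        .groups = "drop")
  }

  n_species <- nrow(raw)
  if (identical(pool_size, "infer_with_warning")) {
    pool_size <- n_species
    rlang::warn(paste0(
      "Pool size Q inferred from the table's ", n_species, " species. ",
      "If the file covers only a sampled subset, supply the true Q."))
  }
  pool_size <- as.integer(pool_size)
  if (pool_size < n_species) {
    rlang::abort(paste0("pool_size (", pool_size, ") < number of species ",
                        "in the file (", n_species, ")."))
  }

  out <- tibble::tibble(
    species_id = raw$species_id,
    monoculture = raw$monoculture_biomass,
    mixture = raw$mixture_biomass)
  attr(out, "pool_size") <- pool_size
  attr(out, "replicates") <- replicates

  n_part <- sum(!is.na(out$monoculture) & out$monoculture > 0 &
                  !is.na(out$mixture))
  rlang::inform(paste0(
    "Read ", n_species, " species (pool Q = ", pool_size, "): ",
    n_part, " participate in the partition, ",
    n_species - n_part, " excluded (missing or zero monoculture)."))
  out
}

mean_or_na <- function(x) {
  if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
}

#' Write a community biomass table
#'
#' Inverse of [read_community()]: writes `species_id`,
#' `monoculture_biomass`, `mixture_biomass` as delimited text. Reading
#' the file back yields a value-identical table.
#'
#' @param data community tibble (columns `species_id`, `monoculture`,
#'   `mixture`).
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @returns `path`, invisibly.
#' @export
write_community <- function(data, path, delim = ",") {
  if (inherits(data, "bef_community")) data <- data$data
  out <- tibble::tibble(
    species_id = if ("species_id" %in% names(data)) data$species_id
                 else paste0("sp", seq_len(nrow(data))),
    monoculture_biomass = data$monoculture,
    mixture_biomass = data$mixture)
  readr::write_delim(out, path, delim = delim, na = "NA")
  invisible(path)
}

# Flat key=value sidecar recording the realized truth of a generated
# community alongside its CSV.
write_truth_sidecar <- function(community, path) {
  stopifnot(inherits(community, "bef_community"))
  p <- community$params
  t <- community$truth
  kv <- c(
    purrr::imap_chr(p, function(v, k) {
      paste0(k, "=", if (is.null(v)) "NA" else format(v, digits = 17))
    }),
    paste0("n_truncated=", community$n_truncated),
    paste0("realized_ce=", format(t$ce, digits = 17)),
    paste0("realized_se=", format(t$se, digits = 17)),
    paste0("realized_net=", format(t$net, digits = 17)),
    paste0("realized_se_bessel=", format(t$se_bessel, digits = 17)))
  writeLines(kv, path)
  invisible(path)
}

read_truth_sidecar <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- vapply(kv, `[`, character(1), 2)
  names(vals) <- vapply(kv, `[`, character(1), 1)
  suppressWarnings(num <- as.numeric(vals))
  out <- lapply(seq_along(vals), function(i) {
    if (!is.na(num[[i]])) num[[i]]
    else if (vals[[i]] == "NA") NA
    else vals[[i]]
  })
  names(out) <- names(vals)
  out
}
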