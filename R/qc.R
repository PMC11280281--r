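#' Screen trait records for outliers
#'
#' Retains observations within `mean +/- k * SD`, with mean and SD computed
#' once on the full input per trait (single pass; statistics are not
#' re-estimated after removal). With `within_cells = TRUE` the screen is
#' applied inside each generation-by-hatch cell instead of across the whole
#' trait.
#'
#' @param records A data frame of trait records with a numeric `value`
#'   column; if a `trait_name` column is present the screen is applied per
#'   trait.
#' @param k Number of standard deviations retained (default 3).
#' @param within_cells Apply the screen within `generation x hatch` cells.
#' @return A list with tibbles `retained` and `removed`; `removed` carries a
#'   `reason` column of the form `"value outside mean +/- 3 SD"`.
#' @export
filter_outliers <- function(records, k = 3, within_cells = FALSE) {
  stopifnot(is.data.frame(records), "value" %in% names(records))
  grp <- intersect("trait_name", names(records))
  if (within_cells) grp <- c(grp, intersect(c("generation", "hatch"), names(records)))
  records <- as_tibble(records)
  flagged <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(.n = dplyr::n(), .mu = mean(.data$value), .sd = sd(.data$value)) |>
    dplyr::ungroup()
  if (any(flagged$.n < 2)) stop("outlier screen needs at least 2 records per group")
  zero_var <- !is.na(flagged$.sd) & flagged$.sd == 0
  if (any(zero_var)) {
    warning("zero variance in ", sum(zero_var), " record group(s); all retained")
  }
  out <- abs(flagged$value - flagged$.mu) > k * flagged$.sd & !zero_var
  removed <- flagged[out, setdiff(names(records), character(0)), drop = FALSE]
  if (nrow(removed)) {
    removed$reason <- sprintf("value outside mean +/- %g SD", k)
  } else {
    removed$reason <- character(0)
  }
  list(
    retained = flagged[!out, names(records), drop = FALSE],
    removed = removed
  )
}

#' Descriptive statistics per trait
#'
#' Sample size, mean, standard error, standard deviation (n - 1 denominator)
#' and coefficient of variation per trait: `SE = SD / sqrt(n)`,
#' `CV% = 100 * SD / mean`. CV is reported missing when the mean is zero;
#' all statistics except the mean are missing for single-record traits,
#' which are flagged.
#'
#' @param records A data frame with `value` and optionally `trait_name`.
#' @return A tibble with columns `trait_name`, `n`, `mean`, `se`, `sd`,
#'   `cv`, `flag`.
#' @export
describe_traits <- function(records) {
  stopifnot(is.data.frame(records), "value" %in% names(records))
  records <- as_tibble(records)
  if (!"trait_name" %in% names(records)) records$trait_name <- "trait"
  records |>
    dplyr::group_by(.data$trait_name) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() >= 2) sd(.data$value) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se = .data$sd / sqrt(.data$n),
      cv = dplyr::if_else(.data$mean == 0, NA_real_, 100 * .data$sd / abs(.data$mean)),
      flag = dplyr::case_when(
        .data$n < 2 ~ "single record",
        .data$mean == 0 ~ "zero mean: CV undefined",
        .default = ""
      )
    ) |>
    dplyr::select("trait_name", "n", "mean", "se", "sd", "cv", "flag")
}
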