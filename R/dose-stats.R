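# Light-dose arithmetic and per-group summary statistics.

#' Energy density of a light treatment
#'
#' `irradiance (mW/cm^2) * duration (s) / 1000`, in J/cm². The standard
#' photobiomodulation dose, e.g. 25 mW/cm² for 180 s = 4.5 J/cm².
#'
#' @param irradiance mW/cm², > 0.
#' @param duration s, > 0.
#' @return energy density, J/cm² (vectorised).
#' @export
energy_density <- function(irradiance, duration) {
  if (any(irradiance <= 0) || any(duration <= 0)) {
    rdx_input_error("irradiance and duration must be > 0")
  }
  irradiance * duration / 1000
}

#' Per-group mean and standard error, with optional comparison
#'
#' Summarises a measurement per group as mean ± SE (`sd / sqrt(n)`).
#' When `comparison` names two groups, a Welch (unequal-variance)
#' two-sample t-test between them is attached.
#'
#' @param data data frame with the measurement and grouping columns.
#' @param value name of the measurement column.
#' @param group name of the grouping column.
#' @param comparison optional character vector of two group labels,
#'   compared as `comparison[1] - comparison[2]`.
#' @return tibble with columns `group`, `n`, `mean`, `se`; if a comparison
#'   was requested, the test is attached as attribute `"comparison"`
#'   (tibble `difference`, `statistic`, `df`, `p_value`).
#' @export
group_summary <- function(data, value, group = "group", comparison = NULL) {
  if (!value %in% names(data) || !group %in% names(data)) {
    rdx_input_error("value/group columns not found in `data`")
  }
  v <- data[[value]]
  g <- as.character(data[[group]])
  if (anyNA(v) || anyNA(g)) rdx_input_error("missing values not allowed")
  out <- tibble(group = g, value = v) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     se = ifelse(dplyr::n() > 1,
                                 sd(.data$value) / sqrt(dplyr::n()), 0),
                     .groups = "drop")
  if (!is.null(comparison)) {
    if (length(comparison) != 2L || !all(comparison %in% g)) {
      rdx_input_error("`comparison` must name two groups present in the data")
    }
    x <- v[g == comparison[1]]
    y <- v[g == comparison[2]]
    cmp <- if (length(x) > 1 && length(y) > 1 && (sd(x) > 0 || sd(y) > 0)) {
      tt <- t.test(x, y)
      tibble(difference = mean(x) - mean(y),
             statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value)
    } else {
      tibble(difference = mean(x) - mean(y), statistic = NA_real_,
             df = NA_real_, p_value = NA_real_)
    }
    attr(out, "comparison") <- cmp
  }
  out
}
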