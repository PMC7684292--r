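# broom-style tidiers for the result objects.

#' Tidy a redox summary into its histogram
#'
#' @param x a [mean_redox()] result.
#' @param ... unused.
#' @return tibble with `bin_lo`, `bin_hi`, `count`.
#' @method tidy redox_summary
#' @export
tidy.redox_summary <- function(x, ...) x$histogram

#' One-row summary of a redox result
#' @inheritParams tidy.redox_summary
#' @return tibble with `mean_rr`, `se`, `n_foreground`, `scope`.
#' @method glance redox_summary
#' @export
glance.redox_summary <- function(x, ...) {
  tibble(mean_rr = x$mean_rr, se = x$se,
         n_foreground = x$n_foreground, scope = x$scope)
}

#' Tidy layer boundaries
#' @param x a [detect_boundaries()] result.
#' @param ... unused.
#' @return tibble with `boundary`, `depth_um`.
#' @method tidy layer_boundaries
#' @export
tidy.layer_boundaries <- function(x, ...) {
  tibble(boundary = c("ilm", "opl_onl", "onl_isos", "bm"),
         depth_um = c(x$ilm, x$opl_onl, x$onl_isos, x$bm))
}

#' Tidy a thickness profile into its ONL table
#' @param x an [onl_thickness_profile()] result.
#' @param ... unused.
#' @return tibble with `offset_um`, `side`, `onl_um`.
#' @method tidy thickness_profile
#' @export
tidy.thickness_profile <- function(x, ...) x$onl

#' One-row summary of a thickness profile
#' @inheritParams tidy.thickness_profile
#' @return tibble with `total_um`, `mean_onl_um`, `age_days`.
#' @method glance thickness_profile
#' @export
glance.thickness_profile <- function(x, ...) {
  tibble(total_um = x$total_um, mean_onl_um = mean(x$onl$onl_um),
         age_days = x$age_days %||% NA_real_)
}

#' Tidy ERG amplitudes
#' @param x a [measure_amplitudes()] result.
#' @param ... unused.
#' @return one-row tibble with `a_amp`, `b_amp`, `a_time`, `b_time`,
#'   `baseline`.
#' @method tidy erg_amplitudes
#' @export
tidy.erg_amplitudes <- function(x, ...) {
  tibble(a_amp = x$a_amp, b_amp = x$b_amp,
         a_time = x$a_time, b_time = x$b_time, baseline = x$baseline)
}
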