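# Photoreceptor-row histomorphometry: count rows of ONL nuclei in a binary
# mask and assemble the superior-inferior "spider" profile.

#' Count photoreceptor nuclei rows in a mask window
#'
#' The vertical occupancy profile of the window (fraction of
#' nuclei-positive pixels per image row) is thresholded at 50% of the
#' window width; the number of maximal runs of occupied rows is the row
#' count. This operationalizes counting rows of nuclei so that phantom
#' ground truth is exactly recoverable.
#'
#' @param mask logical matrix (rows = depth), `TRUE` = nucleus.
#' @param column_window integer vector of column indices, or `NULL` for the
#'   whole width.
#' @param min_occupancy occupancy fraction for a row to count as filled.
#' @return integer row count.
#' @export
count_rows <- function(mask, column_window = NULL, min_occupancy = 0.5) {
  if (!is.matrix(mask)) rdx_input_error("`mask` must be a matrix")
  column_window <- column_window %||% seq_len(ncol(mask))
  if (length(column_window) == 0L) rdx_input_error("empty column window")
  if (min(column_window) < 1L || max(column_window) > ncol(mask)) {
    rdx_input_error("column window outside the mask")
  }
  occ <- rowMeans(mask[, column_window, drop = FALSE])
  runs <- rle(occ >= min_occupancy)
  sum(runs$values)
}

#' Superior-inferior spider profile of nuclei-row counts
#'
#' Row counts at fixed signed distances from the optic nerve head
#' (+ superior, − inferior), ordered from the superior edge to the
#' inferior edge. With replicate masks per location, per-location mean ±
#' SE is reported.
#'
#' @param masks list of logical masks, one per entry of `locations`, or —
#'   with replicates — a list of such lists.
#' @param locations signed distances from the ONH, µm (default
#'   ±100, ±200, ±300); must be unique and match `masks` in length.
#' @param group optional group label.
#' @param ... passed to [count_rows()].
#' @return object of class `spider_profile`: tibble with columns
#'   `location_um`, `n_rows` (mean over replicates), `se`, `n`, ordered
#'   superior to inferior; `group` attribute.
#' @export
build_spider <- function(masks, locations = c(300, 200, 100,
                                              -100, -200, -300),
                         group = NULL, ...) {
  if (length(masks) == 0L) rdx_input_error("need at least one location")
  if (length(masks) != length(locations)) {
    rdx_input_error("one mask (or replicate list) per location required")
  }
  if (anyDuplicated(locations)) rdx_input_error("duplicate locations")
  dots <- list(...)
  counts <- purrr::map(masks, function(m) {
    reps <- if (is.list(m)) m else list(m)
    purrr::map_int(reps, function(r) {
      as.integer(do.call(count_rows, c(list(r), dots)))
    })
  })
  out <- tibble(
    location_um = locations,
    n_rows = purrr::map_dbl(counts, mean),
    se = purrr::map_dbl(counts, ~ if (length(.x) > 1)
      sd(.x) / sqrt(length(.x)) else 0),
    n = purrr::map_int(counts, length)
  ) |>
    dplyr::arrange(dplyr::desc(.data$location_um))
  structure(out, class = c("spider_profile", class(out)), group = group)
}
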