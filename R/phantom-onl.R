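# Synthetic outer-nuclear-layer nuclei mask: stacked rows of ellipses
# emulating photoreceptor nuclei, with the row count as ground truth.

#' Generate an ONL nuclei mask
#'
#' `n_rows` horizontal rows of disjoint ellipses ("nuclei") of vertical
#' extent `nucleus_diameter`, stacked with touching row pitch, so the ONL
#' band height is exactly `n_rows * nucleus_diameter`. Nuclei within a row
#' are spaced 1.4 diameters apart, leaving the inter-nucleus gaps that row
#' counting relies on.
#'
#' @param n_rows number of nuclei rows (>= 0).
#' @param nucleus_diameter nucleus diameter, µm.
#' @param width mask width, µm.
#' @param pixel_size µm per pixel (isotropic).
#' @param margin blank border above and below the band, µm.
#' @return list with `mask` (logical matrix, rows = depth) and `truth`
#'   (a `phantom_truth` list with `n_nuclei_rows`).
#' @export
make_onl_mask <- function(n_rows, nucleus_diameter = 5, width = 100,
                          pixel_size = 1, margin = 10) {
  if (n_rows < 0) rdx_input_error("n_rows must be >= 0")
  d_px <- nucleus_diameter / pixel_size
  w_px <- max(1L, round(width / pixel_size))
  m_px <- round(margin / pixel_size)
  h_px <- as.integer(round(n_rows * d_px) + 2L * m_px)
  mask <- matrix(FALSE, max(h_px, 1L), w_px)
  if (n_rows > 0) {
    spacing <- 1.4 * d_px
    centres_x <- seq(spacing / 2, w_px, by = spacing)
    rows_y <- m_px + (seq_len(n_rows) - 0.5) * d_px
    # pixel-centre coordinates so the band extent is exactly n_rows * d
    xg <- matrix(seq_len(w_px) - 0.5, nrow(mask), w_px, byrow = TRUE)
    yg <- matrix(seq_len(nrow(mask)) - 0.5, nrow(mask), w_px)
    for (cy in rows_y) {
      for (cx in centres_x) {
        mask <- mask | ((xg - cx)^2 + (yg - cy)^2 <= (d_px / 2)^2)
      }
    }
  }
  truth <- structure(list(n_nuclei_rows = as.integer(n_rows),
                          band_height_um = n_rows * nucleus_diameter,
                          pixel_size = pixel_size),
                     class = "phantom_truth")
  list(mask = mask, truth = truth)
}
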