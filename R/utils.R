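# Shared numerical helpers.

#' Otsu threshold of an intensity array
#'
#' Histogram-based two-class threshold on the raw intensity scale. The
#' array is rescaled to `[0, 1]` by its maximum, thresholded with
#' [EBImage::otsu()] at 256 levels, and the cut mapped back, so the
#' returned threshold scales exactly with the data.
#'
#' @param x numeric array (any dimensionality), all values finite.
#' @param levels histogram resolution passed to [EBImage::otsu()].
#' @return threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  if (!all(is.finite(v))) rdx_input_error("intensities must be finite")
  hi <- max(v)
  lo <- min(v)
  if (hi <= lo) rdx_analysis_error("constant image: no threshold exists")
  img <- EBImage::Image(matrix((v - lo) / (hi - lo), ncol = 1L))
  lo + EBImage::otsu(img, range = c(0, 1), levels = levels) * (hi - lo)
}

# Largest connected component of a 3D logical array (6-connectivity).
# Slices are labelled in 2D with EBImage::bwlabel and labels merged across
# adjacent slices with union-find; pure-R flood fill would not scale to the
# ~10^7-voxel volumes a cryo stack produces.
largest_component_3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  nz <- dim(mask)[3]
  labs <- vector("list", nz)
  offset <- 0L
  n_per <- integer(0)
  for (z in seq_len(nz)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask[, , z] * 1))
    lab <- EBImage::imageData(lab)
    k <- max(lab)
    lab[lab > 0] <- lab[lab > 0] + offset
    labs[[z]] <- lab
    offset <- offset + as.integer(k)
  }
  if (offset == 0L) return(array(FALSE, dim(mask)))
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (z in seq_len(nz - 1L)) {
    a <- labs[[z]]
    b <- labs[[z + 1L]]
    touch <- a > 0 & b > 0
    if (!any(touch)) next
    pairs <- unique(cbind(a[touch], b[touch]))
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  sizes <- numeric(offset)
  for (z in seq_len(nz)) {
    lab <- labs[[z]]
    pos <- lab > 0
    tab <- tabulate(roots[lab[pos]], nbins = offset)
    sizes <- sizes + tab
  }
  keep <- which.max(sizes)
  out <- array(FALSE, dim(mask))
  for (z in seq_len(nz)) {
    lab <- labs[[z]]
    pos <- lab > 0
    sl <- array(FALSE, dim(lab))
    sl[pos] <- roots[lab[pos]] == keep
    out[, , z] <- sl
  }
  out
}

# Morphological closing applied slice-wise with a disc brush.
close_slices <- function(mask, brush_size = 3L) {
  out <- mask
  kern <- EBImage::makeBrush(brush_size, shape = "disc")
  for (z in seq_len(dim(mask)[3])) {
    sl <- EBImage::closing(EBImage::Image(mask[, , z] * 1), kern)
    out[, , z] <- EBImage::imageData(sl) > 0.5
  }
  out
}

# Dice overlap of two logical masks of identical shape.
#' Dice similarity coefficient between two masks
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) rdx_input_error("mask shapes differ")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
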