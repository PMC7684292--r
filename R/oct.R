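# SD-OCT analysis: B-scan registration/averaging, longitudinal reflectivity
# profiles (LRP), reflectivity-based layer boundaries, and retinal thickness
# at the standard sampling scheme around the optic nerve head (ONH).

#' Construct a B-scan
#'
#' @param image nonnegative numeric matrix, rows = axial pixels (row 1 =
#'   vitreous side), columns = A-scans.
#' @param axial_scale µm per axial pixel.
#' @param lateral_scale µm per A-scan.
#' @param onh_column A-scan index of the optic nerve head, or `NULL`.
#' @return object of class `bscan`.
#' @export
bscan <- function(image, axial_scale = 1, lateral_scale = 1.76,
                  onh_column = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) {
    rdx_input_error("`image` must be a numeric matrix")
  }
  if (any(image < 0)) rdx_input_error("reflectivity must be >= 0")
  if (axial_scale <= 0 || lateral_scale <= 0) {
    rdx_input_error("scales must be > 0")
  }
  structure(list(image = image, axial_scale = axial_scale,
                 lateral_scale = lateral_scale, onh_column = onh_column),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d axial px x %d A-scans @ %g um/px axial, %g um/px lateral\n",
              nrow(x$image), ncol(x$image), x$axial_scale, x$lateral_scale))
  invisible(x)
}

#' Read a grayscale TIFF or PNG as a B-scan
#' @param path image file.
#' @inheritParams bscan
#' @return a [bscan()].
#' @export
read_bscan <- function(path, axial_scale = 1, lateral_scale = 1.76,
                       onh_column = NULL) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  bscan(img, axial_scale, lateral_scale, onh_column)
}

# Integer-pixel shift between two same-size images maximising circular
# cross-correlation of the demeaned images (FFT-based).
estimate_shift <- function(ref, img) {
  a <- ref - mean(ref)
  b <- img - mean(img)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  idx <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(k, n) as.integer(if (k - 1 > n / 2) k - 1 - n else k - 1)
  c(drow = wrap(idx[1], nrow(a)), dcol = wrap(idx[2], ncol(a)))
}

# Shift an image by integer (drow, dcol), exposing NA where no data moved in.
shift_image <- function(img, drow, dcol) {
  out <- matrix(NA_real_, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - drow
  src_c <- seq_len(ncol(img)) - dcol
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Register and average repeated B-scans
#'
#' Each scan is aligned to the first by the integer axial/lateral shift that
#' maximises cross-correlation, then the aligned stack is averaged pixelwise
#' (pixels a shift moved out of frame are dropped from that scan's
#' contribution). A single scan is returned unchanged.
#'
#' @param bscans list of [bscan()]s with identical shapes and scales.
#' @return a [bscan()]; the estimated per-scan shifts are attached as the
#'   `"shifts"` attribute (tibble with `scan`, `drow`, `dcol`).
#' @export
register_and_average <- function(bscans) {
  if (length(bscans) == 0L) rdx_input_error("need at least one B-scan")
  imgs <- lapply(bscans, function(b) {
    if (!inherits(b, "bscan")) rdx_input_error("inputs must be bscan objects")
    b$image
  })
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    rdx_input_error("all B-scans must share the same shape")
  }
  ref <- imgs[[1]]
  shifts <- tibble(scan = seq_along(imgs), drow = 0L, dcol = 0L)
  total <- ref
  count <- matrix(1, nrow(ref), ncol(ref))
  for (i in seq_along(imgs)[-1]) {
    s <- estimate_shift(ref, imgs[[i]])
    shifts$drow[i] <- s[["drow"]]
    shifts$dcol[i] <- s[["dcol"]]
    aligned <- shift_image(imgs[[i]], s[["drow"]], s[["dcol"]])
    got <- !is.na(aligned)
    total[got] <- total[got] + aligned[got]
    count <- count + got
  }
  out <- bscans[[1]]
  out$image <- total / count
  attr(out, "shifts") <- shifts
  out
}

#' Longitudinal reflectivity profile of a B-scan
#'
#' Mean reflectivity across a lateral window at every axial depth. The
#' window of `width_px` A-scans is centred on `center_column`; 100 px is
#' the standard width for thickness measurement.
#'
#' @param b a [bscan()].
#' @param center_column A-scan index at the window centre.
#' @param width_px window width in A-scans.
#' @return object of class `lrp`: tibble-backed profile with columns
#'   `depth_um` (axial pixel centres) and `reflectivity`, plus
#'   `center_column` / `width_px` / `axial_scale` attributes.
#' @export
compute_lrp <- function(b, center_column, width_px = 100L) {
  stopifnot(inherits(b, "bscan"))
  cols <- center_column - floor(width_px / 2) + seq_len(width_px) - 1L
  if (min(cols) < 1L || max(cols) > ncol(b$image)) {
    rdx_input_error(sprintf(
      "LRP window [%d, %d] out of bounds (1..%d)",
      min(cols), max(cols), ncol(b$image)))
  }
  refl <- rowMeans(b$image[, cols, drop = FALSE])
  out <- tibble(
    depth_um = (seq_len(nrow(b$image)) - 0.5) * b$axial_scale,
    reflectivity = refl
  )
  structure(out, class = c("lrp", class(out)),
            center_column = center_column, width_px = width_px,
            axial_scale = b$axial_scale)
}

# Linear interpolation of the depth at which the profile crosses `level`
# between samples i and i+1.
cross_depth <- function(depth, refl, i, level) {
  depth[i] + (level - refl[i]) / (refl[i + 1] - refl[i]) *
    (depth[i + 1] - depth[i])
}

#' Detect retinal layer boundaries on an LRP
#'
#' Bright (synaptic / plexiform and photoreceptor-segment) bands are the
#' maximal runs of the profile above its half-height (midpoint of profile
#' min and max); nuclear layers are the troughs between them. An LRP
#' through retina shows three bright bands: the inner retinal complex, the
#' OPL, and the IS/OS-to-RPE complex. Boundaries are placed at half-height
#' crossings, linearly interpolated to sub-pixel depth:
#' * `ilm` — rising edge into the first bright band;
#' * `opl_onl` — falling edge out of the OPL band into the ONL trough;
#' * `onl_isos` — rising edge out of the ONL trough;
#' * `bm` — falling edge out of the outermost bright band.
#'
#' @param lrp an [compute_lrp()] profile.
#' @return object of class `layer_boundaries`: named list with `ilm`,
#'   `opl_onl`, `onl_isos`, `bm` in µm.
#' @export
detect_boundaries <- function(lrp) {
  refl <- lrp$reflectivity
  depth <- lrp$depth_um
  if (max(refl) <= min(refl)) {
    rdx_analysis_error("constant profile: no reflectivity extrema")
  }
  half <- (max(refl) + min(refl)) / 2
  above <- refl > half
  runs <- rle(above)
  bright <- which(runs$values)
  if (length(bright) < 3L) {
    missing <- c("inner retinal complex", "OPL", "outer retinal band")
    rdx_analysis_error(sprintf(
      "expected 3 bright reflectivity bands, found %d (missing landmark: %s)",
      length(bright), missing[min(length(bright) + 1L, 3L)]))
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rise <- function(run) cross_depth(depth, refl, starts[run] - 1L, half)
  fall <- function(run) cross_depth(depth, refl, ends[run], half)
  first_b <- bright[1]
  outer_b <- bright[length(bright)]
  opl_b <- bright[length(bright) - 1L]
  if (starts[first_b] == 1L || ends[outer_b] == length(refl)) {
    rdx_analysis_error("bright band touches the profile edge; cannot localise ILM/BM")
  }
  out <- list(ilm = rise(first_b), opl_onl = fall(opl_b),
              onl_isos = rise(outer_b), bm = fall(outer_b))
  if (!(out$ilm < out$opl_onl && out$opl_onl < out$onl_isos &&
        out$onl_isos < out$bm)) {
    rdx_analysis_error("boundary ordering violated (ilm < opl_onl < onl_isos < bm)")
  }
  structure(out, class = "layer_boundaries")
}

#' @export
print.layer_boundaries <- function(x, ...) {
  cat(sprintf("<layer_boundaries> ILM %.2f | OPL/ONL %.2f | ONL/IS-OS %.2f | BM %.2f um\n",
              x$ilm, x$opl_onl, x$onl_isos, x$bm))
  invisible(x)
}

#' Total retinal thickness by the 10-location LRP protocol
#'
#' Thickness (BM − ILM) is measured from 100 px-wide LRPs at 5 locations,
#' 50 pixels apart, on either side of the ONH, and the 10 values averaged.
#'
#' @param b a [bscan()].
#' @param onh_column ONH A-scan index; defaults to the scan's `onh_column`.
#' @param spacing_px lateral spacing between locations, pixels.
#' @param n_locations locations per side.
#' @param width_px LRP window width.
#' @return mean total thickness in µm, with the per-location tibble
#'   (`location_px`, `side`, `total_um`) as attribute `"locations"`.
#' @export
total_retinal_thickness <- function(b, onh_column = NULL, spacing_px = 50L,
                                    n_locations = 5L, width_px = 100L) {
  onh_column <- onh_column %||% b$onh_column
  if (is.null(onh_column)) rdx_input_error("ONH column not given")
  offsets <- c(-rev(seq_len(n_locations)), seq_len(n_locations)) * spacing_px
  res <- purrr::map(offsets, function(off) {
    col <- onh_column + off
    bnd <- tryCatch(detect_boundaries(compute_lrp(b, col, width_px)),
                    retinodex_error = function(e) e)
    list(off = off, bnd = bnd)
  })
  failed <- purrr::keep(res, ~ inherits(.x$bnd, "condition"))
  if (length(failed) > 0) {
    rdx_analysis_error(sprintf(
      "boundary detection failed at offsets: %s",
      paste(purrr::map_dbl(failed, "off"), collapse = ", ")))
  }
  locs <- tibble(
    location_px = onh_column + offsets,
    side = ifelse(offsets < 0, "inferior", "superior"),
    total_um = purrr::map_dbl(res, ~ .x$bnd$bm - .x$bnd$ilm)
  )
  structure(mean(locs$total_um), locations = locs)
}

#' ONL thickness profile at fixed distances from the ONH
#'
#' Outer nuclear layer thickness (`onl_isos - opl_onl` from the local LRP)
#' at ±88, ±176, ±264, ±352 and ±440 µm from the optic nerve head. Offsets
#' in µm are mapped to A-scan columns by rounding through the lateral scale.
#'
#' @param b a [bscan()].
#' @param onh_column ONH A-scan index; defaults to the scan's own.
#' @param offsets_um unsigned sampling distances from the ONH, µm.
#' @param width_px LRP window width.
#' @param age_days optional postnatal day label carried into the result.
#' @return object of class `thickness_profile`: list with `total_um`
#'   (mean 10-location total thickness), `onl` (tibble `offset_um`, `side`,
#'   `onl_um`), and `age_days`.
#' @export
onl_thickness_profile <- function(b, onh_column = NULL,
                                  offsets_um = c(88, 176, 264, 352, 440),
                                  width_px = 100L, age_days = NULL) {
  onh_column <- onh_column %||% b$onh_column
  if (is.null(onh_column)) rdx_input_error("ONH column not given")
  signed <- c(-rev(offsets_um), offsets_um)
  onl <- purrr::map_dfr(signed, function(off) {
    col <- onh_column + round(off / b$lateral_scale)
    bnd <- detect_boundaries(compute_lrp(b, col, width_px))
    tibble(offset_um = off,
           side = ifelse(off < 0, "inferior", "superior"),
           onl_um = bnd$onl_isos - bnd$opl_onl)
  })
  structure(
    list(total_um = as.numeric(total_retinal_thickness(b, onh_column,
                                                       width_px = width_px)),
         onl = onl, age_days = age_days),
    class = "thickness_profile")
}

#' Longitudinal thickness summary across ages
#'
#' Per-age (and, when present, per-group) mean ± SE of total retinal
#' thickness, the between-group Welch comparison at each age when exactly
#' two groups are present, and a flag for strictly decreasing mean
#' thickness with age.
#'
#' @param data tibble with columns `age_days`, `total_um` and optionally
#'   `group` (one row per eye), e.g. assembled from
#'   [onl_thickness_profile()] results.
#' @return list with `by_age` (tibble `age_days`, `group`, `n`, `mean_um`,
#'   `se_um`), `comparisons` (per-age group difference, Welch t and p, or
#'   `NULL`), and `monotone_decrease` (logical, per group).
#' @export
longitudinal_summary <- function(data) {
  if (!all(c("age_days", "total_um") %in% names(data))) {
    rdx_input_error("`data` needs columns age_days and total_um")
  }
  if (any(is.na(data$age_days))) rdx_input_error("missing age labels")
  if (length(unique(data$age_days)) < 2L) {
    rdx_input_error("need measurements at >= 2 ages")
  }
  if (!"group" %in% names(data)) data$group <- "all"
  by_age <- data |>
    dplyr::group_by(.data$age_days, .data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_um = mean(.data$total_um),
                     se_um = ifelse(dplyr::n() > 1,
                                    sd(.data$total_um) / sqrt(dplyr::n()), 0),
                     .groups = "drop") |>
    dplyr::arrange(.data$age_days)
  groups <- unique(data$group)
  comparisons <- NULL
  if (length(groups) == 2L) {
    comparisons <- purrr::map_dfr(sort(unique(data$age_days)), function(a) {
      d <- data[data$age_days == a, ]
      x <- d$total_um[d$group == groups[1]]
      y <- d$total_um[d$group == groups[2]]
      diff <- mean(x) - mean(y)
      if (length(x) > 1 && length(y) > 1 && (sd(x) > 0 || sd(y) > 0)) {
        tt <- t.test(x, y)
        tibble(age_days = a, difference_um = diff,
               statistic = unname(tt$statistic), p_value = tt$p.value)
      } else {
        tibble(age_days = a, difference_um = diff,
               statistic = NA_real_, p_value = NA_real_)
      }
    })
  }
  mono <- by_age |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      monotone_decrease = all(diff(.data$mean_um[order(.data$age_days)]) < 0),
      .groups = "drop")
  list(by_age = by_age, comparisons = comparisons, monotone_decrease = mono)
}
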