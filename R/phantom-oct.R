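# Synthetic OCT B-scan phantom: alternating hypo-/hyper-reflective bands
# with multiplicative speckle and an optic-nerve-head excavation.

#' Configuration for the layered B-scan phantom
#'
#' The retina is modelled as piecewise-constant reflectivity bands separated
#' by the interfaces a longitudinal reflectivity profile resolves: ILM, the
#' inner retinal complex / INL, INL / OPL, OPL / ONL, ONL / IS-OS, and
#' Bruch's membrane. Pixels straddling an interface take the
#' partial-volume mixture of the two band reflectivities. Within
#' `onh_halfwidth` A-scans of `onh_center` the bands collapse to the
#' vitreous level (ONH excavation). Speckle is multiplicative
#' `Normal(1, speckle_cv)`.
#'
#' @param n_ascans A-scans (columns) per B-scan.
#' @param axial_pixels axial samples (rows) per A-scan.
#' @param axial_scale µm per axial pixel.
#' @param lateral_scale µm per A-scan. The default 1.76 makes the
#'   standard 50-pixel lateral sampling interval equal 88 µm, so the
#'   pixel- and µm-denominated sampling schemes coincide.
#' @param layer_depths strictly increasing interface depths in µm:
#'   `ilm`, `ipl_inl`, `inl_opl`, `opl_onl`, `onl_isos`, `bm`.
#' @param layer_reflectivities AU per band, length
#'   `length(layer_depths) + 1` (vitreous, the bands between successive
#'   interfaces, then below-BM).
#' @param onh_center A-scan index of the optic nerve head.
#' @param onh_halfwidth half-width of the excavation, A-scans.
#' @param speckle_cv coefficient of variation of the multiplicative speckle.
#' @param seed integer seed.
#' @return a list of class `oct_phantom_config`.
#' @export
oct_phantom_config <- function(n_ascans = 1000L,
                               axial_pixels = 300L,
                               axial_scale = 1,
                               lateral_scale = 1.76,
                               layer_depths = c(ilm = 20, ipl_inl = 80,
                                                inl_opl = 105, opl_onl = 125,
                                                onl_isos = 165, bm = 198.1),
                               layer_reflectivities = c(10, 180, 60, 200,
                                                        40, 220, 15),
                               onh_center = 500L,
                               onh_halfwidth = 30L,
                               speckle_cv = 0.1,
                               seed = 1L) {
  cfg <- list(n_ascans = as.integer(n_ascans),
              axial_pixels = as.integer(axial_pixels),
              axial_scale = axial_scale, lateral_scale = lateral_scale,
              layer_depths = layer_depths,
              layer_reflectivities = layer_reflectivities,
              onh_center = as.integer(onh_center),
              onh_halfwidth = as.integer(onh_halfwidth),
              speckle_cv = speckle_cv, seed = as.integer(seed))
  if (is.unsorted(cfg$layer_depths, strictly = TRUE)) {
    rdx_config_error("layer_depths must be strictly increasing")
  }
  if (max(cfg$layer_depths) >= cfg$axial_pixels * cfg$axial_scale) {
    rdx_config_error("deepest interface exceeds the imaged depth")
  }
  if (length(cfg$layer_reflectivities) != length(cfg$layer_depths) + 1L) {
    rdx_config_error("need one reflectivity per band (n interfaces + 1)")
  }
  if (cfg$speckle_cv < 0) rdx_config_error("speckle_cv must be >= 0")
  structure(cfg, class = "oct_phantom_config")
}

#' Packaged OCT phantom profiles
#'
#' Two p30 study-group profiles whose configured ILM-to-BM span matches the
#' group total retinal thickness: `"PBM-p30"` (178.1 µm) and `"sham-p30"`
#' (169.2 µm). The outer-retinal interfaces are shifted, emulating thinning
#' of the photoreceptor layers.
#'
#' @param name `"PBM-p30"` or `"sham-p30"`.
#' @param seed integer seed.
#' @return an [oct_phantom_config()].
#' @export
oct_phantom_profile <- function(name = c("PBM-p30", "sham-p30"), seed = 1L) {
  name <- match.arg(name)
  depths <- switch(name,
    "PBM-p30" = c(ilm = 20, ipl_inl = 80, inl_opl = 105, opl_onl = 125,
                  onl_isos = 165, bm = 198.1),
    "sham-p30" = c(ilm = 20, ipl_inl = 80, inl_opl = 105, opl_onl = 125,
                   onl_isos = 158, bm = 189.2))
  oct_phantom_config(layer_depths = depths, speckle_cv = 0.1, seed = seed)
}

# Noiseless band profile for one A-scan: partial-volume integral of the
# piecewise-constant reflectivity over each axial pixel.
band_profile <- function(cfg) {
  edges_px <- c(0, cfg$layer_depths / cfg$axial_scale, cfg$axial_pixels)
  refl <- cfg$layer_reflectivities
  cum_at <- function(p) {
    # integral of reflectivity from depth 0 to pixel coordinate p
    seg <- pmin(pmax(p - head(edges_px, -1), 0),
                diff(edges_px))
    sum(seg * refl)
  }
  cum <- vapply(0:cfg$axial_pixels, cum_at, numeric(1))
  diff(cum)
}

#' Generate a layered B-scan phantom
#'
#' @param cfg an [oct_phantom_config()].
#' @return list with `bscan` (a [bscan()]) and `truth` (a `phantom_truth`
#'   list carrying `layer_depths`, `true_total_thickness = bm - ilm`, and
#'   `true_onl_thickness = onl_isos - opl_onl`).
#' @export
make_oct_bscan <- function(cfg) {
  if (!inherits(cfg, "oct_phantom_config")) {
    cfg <- do.call(oct_phantom_config, as.list(cfg))
  }
  prof <- band_profile(cfg)
  img <- matrix(prof, nrow = cfg$axial_pixels, ncol = cfg$n_ascans)
  onh_cols <- abs(seq_len(cfg$n_ascans) - cfg$onh_center) <= cfg$onh_halfwidth
  if (any(onh_cols)) {
    excav <- prof
    bm_px <- cfg$layer_depths[["bm"]] / cfg$axial_scale
    excav[seq_len(floor(bm_px))] <- cfg$layer_reflectivities[1]
    img[, onh_cols] <- excav
  }
  if (cfg$speckle_cv > 0) {
    withr::with_seed(cfg$seed, {
      img <- img * pmax(matrix(rnorm(length(img), 1, cfg$speckle_cv),
                               nrow = nrow(img)), 0)
    })
  }
  d <- cfg$layer_depths
  truth <- structure(
    list(layer_depths = d,
         true_total_thickness = unname(d[["bm"]] - d[["ilm"]]),
         true_onl_thickness = unname(d[["onl_isos"]] - d[["opl_onl"]]),
         config = cfg),
    class = "phantom_truth")
  list(bscan = bscan(img, axial_scale = cfg$axial_scale,
                     lateral_scale = cfg$lateral_scale,
                     onh_column = cfg$onh_center),
       truth = truth)
}

#' Generate a set of speckled replicate B-scans
#'
#' Repeated acquisitions of the same retina (identical structure,
#' independent speckle), ready for [register_and_average()].
#'
#' @param cfg an [oct_phantom_config()].
#' @param n_scans number of replicate B-scans.
#' @return list with `bscans` (list of [bscan()]) and `truth`.
#' @export
make_oct_scan_set <- function(cfg, n_scans = 40L) {
  if (!inherits(cfg, "oct_phantom_config")) {
    cfg <- do.call(oct_phantom_config, as.list(cfg))
  }
  seeds <- cfg$seed + seq_len(n_scans) - 1L
  out <- purrr::map(seeds, function(s) {
    ci <- cfg
    ci$seed <- s
    make_oct_bscan(ci)
  })
  list(bscans = purrr::map(out, "bscan"), truth = out[[1]]$truth)
}
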