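# 3D fluorescence volume container and TIFF stack I/O.

#' Construct a fluorescence volume
#'
#' One channel (NADH or FAD) of a 3D cryo-imaging stack. Voxels are stored
#' as a numeric array indexed `[y, x, z]` (z = slice index, vitreous-agnostic);
#' geometry is carried as the voxel edge length in µm per axis.
#'
#' @param voxels nonnegative 3D numeric array, `[y, x, z]`.
#' @param voxel_size voxel edge length in µm; length 1 (isotropic) or 3
#'   `(x, y, z)`.
#' @param channel `"NADH"` or `"FAD"`.
#' @param excitation_nm,emission_nm filter wavelengths carried as metadata.
#'   Defaults are the cryo-imager settings for the chosen channel
#'   (NADH 336/450 nm, FAD 470/520 nm).
#' @return object of class `fluorescence_volume`.
#' @export
fluorescence_volume <- function(voxels, voxel_size = 10,
                                channel = c("NADH", "FAD"),
                                excitation_nm = NULL, emission_nm = NULL) {
  channel <- match.arg(channel)
  if (length(dim(voxels)) != 3L) rdx_input_error("`voxels` must be a 3D array")
  if (any(voxels < 0)) rdx_input_error("fluorescence intensities must be >= 0")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    rdx_input_error("`voxel_size` must be 1 or 3 positive lengths (um)")
  }
  defaults <- if (channel == "NADH") c(336, 450) else c(470, 520)
  structure(
    list(
      voxels = voxels,
      voxel_size = voxel_size,
      channel = channel,
      excitation_nm = excitation_nm %||% defaults[1],
      emission_nm = emission_nm %||% defaults[2]
    ),
    class = "fluorescence_volume"
  )
}

#' @export
print.fluorescence_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<fluorescence_volume> %s, %d x %d x %d voxels @ %g/%g/%g um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Write a volume as a multi-page TIFF stack
#'
#' One 16-bit page per z-slice. Intensities are divided by `full_scale`
#' before writing. When two channels are destined for a ratio analysis
#' they must share one `full_scale` (as they would share one camera's
#' count range), otherwise the on-disk ratio is rescaled by the ratio of
#' the per-channel maxima.
#'
#' @param vol a [fluorescence_volume()].
#' @param path output `.tif` path.
#' @param full_scale intensity mapped to the 16-bit maximum; defaults to
#'   the volume maximum.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path, full_scale = NULL) {
  stopifnot(inherits(vol, "fluorescence_volume"))
  hi <- full_scale %||% max(vol$voxels)
  if (hi <= 0) hi <- 1
  if (max(vol$voxels) > hi) rdx_input_error("intensities exceed full_scale")
  pages <- lapply(seq_len(dim(vol$voxels)[3]),
                  function(z) vol$voxels[, , z] / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF stack as a fluorescence volume
#'
#' @param path TIFF file with one page per z-slice.
#' @inheritParams fluorescence_volume
#' @return a [fluorescence_volume()] with intensities in `[0, 1]` units of
#'   the on-disk full scale.
#' @export
read_volume_tiff <- function(path, voxel_size = 10, channel = c("NADH", "FAD")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  voxels <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  fluorescence_volume(voxels, voxel_size = voxel_size, channel = channel)
}
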