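# Synthetic cryo-imaging eye phantom: a spherical fluorescent retinal shell
# with configurable NADH:FAD expectation, used to validate the redox pipeline
# against known ground truth.

#' Configuration for the cryo-imaging eye phantom
#'
#' Geometry follows the cryo-imager: isotropic 10 µm voxels and one z-slice
#' per microtome cut, so the slice count is `ceiling(eye_diameter /
#' voxel_size)`. The retina is modelled as a centred spherical shell whose
#' voxels fluoresce at `nadh_mean` / `fad_mean` with multiplicative Gaussian
#' noise of coefficient of variation `noise_cv`, truncated at zero;
#' everything else is dim background.
#'
#' @param eye_diameter eye diameter, µm.
#' @param shell_outer_radius outer radius of the retinal shell, µm.
#' @param shell_thickness shell (retina) thickness, µm.
#' @param voxel_size isotropic voxel edge, µm.
#' @param nadh_mean,fad_mean expected shell intensity per channel, AU.
#' @param noise_cv coefficient of variation of voxel intensity (fraction).
#' @param background_mean expected intensity outside the shell, AU.
#' @param lateral_pixels optional x/y grid size; defaults to the z-slice
#'   count (cubic volume). Smaller values crop the field of view.
#' @param seed integer seed; all phantom randomness flows from it.
#' @return a list of class `eye_phantom_config`.
#' @export
eye_phantom_config <- function(eye_diameter = 2000,
                               shell_outer_radius = 900,
                               shell_thickness = 90,
                               voxel_size = 10,
                               nadh_mean = 92,
                               fad_mean = 100,
                               noise_cv = 0.02,
                               background_mean = 2,
                               lateral_pixels = NULL,
                               seed = 1L) {
  cfg <- list(eye_diameter = eye_diameter,
              shell_outer_radius = shell_outer_radius,
              shell_thickness = shell_thickness,
              voxel_size = voxel_size,
              nadh_mean = nadh_mean, fad_mean = fad_mean,
              noise_cv = noise_cv, background_mean = background_mean,
              lateral_pixels = lateral_pixels,
              seed = as.integer(seed))
  if (cfg$shell_thickness >= cfg$shell_outer_radius ||
      cfg$shell_outer_radius > cfg$eye_diameter / 2) {
    rdx_config_error(
      "need shell_thickness < shell_outer_radius <= eye_diameter / 2")
  }
  if (cfg$noise_cv < 0) rdx_config_error("noise_cv must be >= 0")
  if (cfg$fad_mean <= 0) rdx_config_error("fad_mean must be > 0")
  if (cfg$voxel_size <= 0) rdx_config_error("voxel_size must be > 0")
  structure(cfg, class = "eye_phantom_config")
}

#' Packaged cryo phantom profiles
#'
#' Three study-group profiles with shell NADH:FAD expectations matching the
#' representative group mean redox ratios: non-dystrophic control (`"SD"`,
#' true ratio 0.92), dystrophic transgenic (`"P23H"`, 0.66), and
#' 830 nm-treated (`"P23H-PBM"`, 0.97). All use a 200^3 desk-scale volume
#' (2 mm eye at 10 µm voxels) with `noise_cv` 0.02.
#'
#' @param name one of `"SD"`, `"P23H"`, `"P23H-PBM"`.
#' @param seed integer seed for the phantom draw.
#' @return an [eye_phantom_config()].
#' @export
cryo_phantom_profile <- function(name = c("SD", "P23H", "P23H-PBM"),
                                 seed = 1L) {
  name <- match.arg(name)
  nadh <- switch(name, "SD" = 92, "P23H" = 66, "P23H-PBM" = 97)
  eye_phantom_config(nadh_mean = nadh, fad_mean = 100, seed = seed)
}

#' Generate a two-channel cryo-imaging phantom
#'
#' Draws the NADH and FAD stacks plus ground truth. Shell voxels are
#' `Normal(mean, noise_cv * mean)` truncated at zero; background voxels
#' likewise around `background_mean`. Identical configurations (including
#' seed) give bit-identical volumes.
#'
#' @param cfg an [eye_phantom_config()].
#' @return list with elements `nadh`, `fad` (both
#'   [fluorescence_volume()]s) and `truth` (a `phantom_truth` list with
#'   `shell_mask` and `true_ratio = nadh_mean / fad_mean`).
#' @export
make_cryo_phantom <- function(cfg) {
  if (!inherits(cfg, "eye_phantom_config")) {
    cfg <- do.call(eye_phantom_config, as.list(cfg))
  }
  nz <- as.integer(ceiling(cfg$eye_diameter / cfg$voxel_size))
  nx <- as.integer(cfg$lateral_pixels %||% nz)
  ny <- nx
  centre <- function(n) (seq_len(n) - (n + 1) / 2) * cfg$voxel_size
  yy <- centre(ny); xx <- centre(nx); zz <- centre(nz)
  r2 <- outer(outer(yy^2, xx^2, `+`), zz^2, `+`)
  r_out2 <- cfg$shell_outer_radius^2
  r_in2 <- (cfg$shell_outer_radius - cfg$shell_thickness)^2
  shell <- r2 <= r_out2 & r2 > r_in2

  draw <- function(mean_fg) {
    v <- array(0, dim = c(ny, nx, nz))
    if (cfg$noise_cv == 0) {
      v[] <- cfg$background_mean
      v[shell] <- mean_fg
    } else {
      v[] <- rnorm(length(v), cfg$background_mean,
                   cfg$noise_cv * cfg$background_mean)
      n_fg <- sum(shell)
      v[shell] <- rnorm(n_fg, mean_fg, cfg$noise_cv * mean_fg)
      v[v < 0] <- 0
    }
    v
  }
  withr::with_seed(cfg$seed, {
    nadh <- draw(cfg$nadh_mean)
    fad <- draw(cfg$fad_mean)
  })
  truth <- structure(
    list(shell_mask = shell,
         true_ratio = cfg$nadh_mean / cfg$fad_mean,
         config = cfg),
    class = "phantom_truth")
  list(
    nadh = fluorescence_volume(nadh, cfg$voxel_size, "NADH"),
    fad = fluorescence_volume(fad, cfg$voxel_size, "FAD"),
    truth = truth
  )
}
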