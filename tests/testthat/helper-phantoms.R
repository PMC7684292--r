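# Small phantom configurations shared across tests: desk-scale geometries
# keep individual tests fast while exercising the same code paths as the
# full-size profiles.

small_cryo_cfg <- function(nadh_mean = 92, fad_mean = 100, noise_cv = 0.02,
                           seed = 7) {
  eye_phantom_config(eye_diameter = 600, shell_outer_radius = 270,
                     shell_thickness = 60, nadh_mean = nadh_mean,
                     fad_mean = fad_mean, noise_cv = noise_cv, seed = seed)
}

small_oct_cfg <- function(speckle_cv = 0, seed = 1,
                          layer_depths = c(ilm = 20, ipl_inl = 80,
                                           inl_opl = 105, opl_onl = 125,
                                           onl_isos = 165, bm = 198.1)) {
  oct_phantom_config(n_ascans = 320, axial_pixels = 260,
                     onh_center = 160L, onh_halfwidth = 10L,
                     layer_depths = layer_depths, speckle_cv = speckle_cv,
                     seed = seed)
}

# Brute-force frame mean: the literal double loop over all pixels,
# background counting as zero. Independent oracle for mean_redox().
brute_force_frame_mean <- function(mp) {
  total <- 0
  for (i in seq_len(mp$Ny)) {
    for (j in seq_len(mp$Nx)) {
      v <- mp$image[i, j]
      if (!is.na(v)) total <- total + v
    }
  }
  total / (mp$Nx * mp$Ny)
}

# Brute-force row counting: walk the occupancy profile and count entries
# into occupied runs. Independent oracle for count_rows().
brute_force_row_count <- function(mask, cols, min_occupancy = 0.5) {
  inside <- FALSE
  n <- 0L
  for (r in seq_len(nrow(mask))) {
    occ <- sum(mask[r, cols]) / length(cols)
    if (occ >= min_occupancy) {
      if (!inside) n <- n + 1L
      inside <- TRUE
    } else {
      inside <- FALSE
    }
  }
  n
}
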