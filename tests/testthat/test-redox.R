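test_that("redox ratio is the voxelwise quotient, with sub-floor FAD excluded", {
  n <- fluorescence_volume(array(92, c(2, 2, 2)), channel = "NADH")
  f <- fluorescence_volume(array(100, c(2, 2, 2)), channel = "FAD")
  rv <- compute_redox_volume(n, f, fad_floor = 1)
  expect_true(all(rv$ratio == 0.92))

  # identical channels give ratio 1 everywhere
  g <- fluorescence_volume(array(50, c(2, 2, 2)), channel = "FAD")
  n50 <- fluorescence_volume(array(50, c(2, 2, 2)), channel = "NADH")
  expect_true(all(compute_redox_volume(n50, g, fad_floor = 1)$ratio == 1))

  # zero FAD voxel: excluded from the valid mask, no error
  fz <- array(100, c(2, 2, 2)); fz[1, 1, 1] <- 0
  rv2 <- compute_redox_volume(
    n, fluorescence_volume(fz, channel = "FAD"), fad_floor = 1)
  expect_false(rv2$valid_mask[1, 1, 1])
  expect_true(is.na(rv2$ratio[1, 1, 1]))
  expect_equal(sum(rv2$valid_mask), 7)
})

test_that("shape or channel mismatches are input errors", {
  n <- fluorescence_volume(array(1, c(2, 2, 2)), channel = "NADH")
  f3 <- fluorescence_volume(array(1, c(2, 2, 3)), channel = "FAD")
  expect_error(compute_redox_volume(n, f3), class = "retinodex_input_error")
  expect_error(compute_redox_volume(n, n), class = "retinodex_input_error")
})

test_that("segmentation recovers the phantom shell: exact at zero noise, Dice >= 0.9 noisy", {
  ph0 <- make_cryo_phantom(small_cryo_cfg(noise_cv = 0))
  sm <- segment_shell(ph0$nadh, ph0$fad)
  expect_identical(sm$mask, ph0$truth$shell_mask)
  expect_equal(dice_coefficient(sm$mask, ph0$truth$shell_mask), 1.0)

  ph <- make_cryo_phantom(small_cryo_cfg(noise_cv = 0.05))
  smn <- segment_shell(ph$nadh, ph$fad)
  expect_gte(dice_coefficient(smn$mask, ph$truth$shell_mask), 0.9)
})

test_that("an all-background volume fails segmentation with an analysis error", {
  flat <- fluorescence_volume(array(5, c(8, 8, 8)), channel = "NADH")
  flatf <- fluorescence_volume(array(5, c(8, 8, 8)), channel = "FAD")
  expect_error(segment_shell(flat, flatf), class = "retinodex_analysis_error")
})

test_that("max projection takes the per-column maximum over shell-valid voxels", {
  ratio <- array(NA_real_, c(1, 1, 3))
  ratio[1, 1, ] <- c(0.5, 0.9, 0.7)
  rv <- structure(list(ratio = ratio,
                       valid_mask = array(TRUE, c(1, 1, 3))),
                  class = "redox_volume")
  mp <- max_project(rv, array(TRUE, c(1, 1, 3)))
  expect_equal(mp$image[1, 1], 0.9)

  # single-slice volume: projection is that slice
  rv1 <- structure(list(ratio = array(0.97, c(4, 4, 1)),
                        valid_mask = array(TRUE, c(4, 4, 1))),
                   class = "redox_volume")
  mp1 <- max_project(rv1, array(TRUE, c(4, 4, 1)))
  expect_true(all(mp1$image == 0.97))

  # columns with no shell voxel are excluded from the foreground
  shell <- array(TRUE, c(1, 2, 3)); shell[1, 2, ] <- FALSE
  rv2 <- structure(list(ratio = array(1, c(1, 2, 3)),
                        valid_mask = array(TRUE, c(1, 2, 3))),
                   class = "redox_volume")
  mp2 <- max_project(rv2, shell)
  expect_identical(as.vector(mp2$foreground), c(TRUE, FALSE))
  expect_true(is.na(mp2$image[1, 2]))
})

test_that("frame-mean and foreground-mean scopes follow their definitions", {
  img <- matrix(c(2, 0, 0, 0), 2, 2)
  fg <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  img[!fg] <- NA
  mp <- structure(list(image = img, foreground = fg, Nx = 2, Ny = 2),
                  class = "max_projection")
  expect_equal(mean_redox(mp, "full_frame")$mean_rr, 0.5)
  expect_equal(mean_redox(mp, "foreground")$mean_rr, 2.0)

  const <- structure(list(image = matrix(1, 2, 2),
                          foreground = matrix(TRUE, 2, 2), Nx = 2, Ny = 2),
                     class = "max_projection")
  expect_equal(mean_redox(const, "full_frame")$mean_rr, 1.0)

  # constant 0.66 foreground reproduces the group-mean identity
  img2 <- matrix(0.66, 3, 3); img2[1, 1] <- NA
  fg2 <- matrix(TRUE, 3, 3); fg2[1, 1] <- FALSE
  mp2 <- structure(list(image = img2, foreground = fg2, Nx = 3, Ny = 3),
                   class = "max_projection")
  expect_equal(mean_redox(mp2, "foreground")$mean_rr, 0.66)

  empty <- structure(list(image = matrix(NA_real_, 2, 2),
                          foreground = matrix(FALSE, 2, 2), Nx = 2, Ny = 2),
                     class = "max_projection")
  expect_error(mean_redox(empty, "foreground"),
               class = "retinodex_analysis_error")
})

test_that("frame mean equals the brute-force double-loop oracle", {
  ph <- make_cryo_phantom(small_cryo_cfg(seed = 3))
  res <- run_redox_pipeline(ph$nadh, ph$fad, scope = "full_frame",
                            keep_intermediates = TRUE)
  expect_equal(res$summary$mean_rr, brute_force_frame_mean(res$projection),
               tolerance = 1e-12)
})

test_that("histogram counts sum to the number of averaged pixels", {
  ph <- make_cryo_phantom(small_cryo_cfg(seed = 5))
  res <- run_redox_pipeline(ph$nadh, ph$fad, keep_intermediates = TRUE)
  expect_equal(sum(res$summary$histogram$count), res$summary$n_foreground)
  full <- mean_redox(res$projection, "full_frame")
  expect_equal(sum(full$histogram$count),
               res$projection$Nx * res$projection$Ny)
})

test_that("pipeline mean is invariant under joint intensity rescaling", {
  ph <- make_cryo_phantom(small_cryo_cfg(seed = 9))
  base <- run_redox_pipeline(ph$nadh, ph$fad)$mean_rr
  for (c_scale in c(0.25, 7)) {
    n2 <- fluorescence_volume(ph$nadh$voxels * c_scale, channel = "NADH")
    f2 <- fluorescence_volume(ph$fad$voxels * c_scale, channel = "FAD")
    expect_equal(run_redox_pipeline(n2, f2)$mean_rr, base,
                 tolerance = 1e-12)
  }
})

test_that("MIP mean is biased no lower than truth and nondecreasing in noise", {
  means <- vapply(c(0, 0.02, 0.05), function(cv) {
    ph <- make_cryo_phantom(small_cryo_cfg(noise_cv = cv, seed = 21))
    run_redox_pipeline(ph$nadh, ph$fad)$mean_rr
  }, numeric(1))
  expect_gte(means[1], 0.92 - 1e-12)
  expect_true(all(diff(means) >= 0))
})

test_that("zero-noise pipeline returns the configured ratio exactly", {
  ph <- make_cryo_phantom(small_cryo_cfg(nadh_mean = 97, noise_cv = 0))
  expect_equal(run_redox_pipeline(ph$nadh, ph$fad)$mean_rr, 0.97)
})

test_that("oxidative shift matches hand arithmetic and its algebraic identity", {
  expect_equal(oxidative_shift(0.66, 0.92), 100 * (0.92 - 0.66) / 0.92)
  expect_equal(round(oxidative_shift(0.66, 0.92), 2), 28.26)
  expect_equal(oxidative_shift(0.5, 0.5), 0)
  expect_equal(round(oxidative_shift(0.97, 0.92), 2), -5.43)
  withr::with_seed(4, {
    for (k in 1:3) {
      a <- runif(1, 0.2, 1.5); b <- runif(1, 0.2, 1.5)
      expect_equal(oxidative_shift(a, b), 100 * (1 - a / b))
    }
  })
  expect_error(oxidative_shift(0.5, 0), class = "retinodex_input_error")
})

test_that("pipeline errors are tagged with their stage", {
  # constant channels fail at the ratio stage (no FAD floor derivable)
  flat <- fluorescence_volume(array(5, c(6, 6, 6)), channel = "NADH")
  flatf <- fluorescence_volume(array(5, c(6, 6, 6)), channel = "FAD")
  err <- tryCatch(run_redox_pipeline(flat, flatf), error = identity)
  expect_s3_class(err, "retinodex_analysis_error")
  expect_match(conditionMessage(err), "\\[ratio\\]")

  # constant-sum channels pass the ratio stage, fail at segmentation
  fadv <- array(rep(c(4, 6), 108), c(6, 6, 6))
  nadv <- 10 - fadv
  err2 <- tryCatch(
    run_redox_pipeline(fluorescence_volume(nadv, channel = "NADH"),
                       fluorescence_volume(fadv, channel = "FAD")),
    error = identity)
  expect_s3_class(err2, "retinodex_analysis_error")
  expect_match(conditionMessage(err2), "\\[segment\\]")
})

test_that("TIFF round trip preserves the pipeline result", {
  ph <- make_cryo_phantom(small_cryo_cfg(seed = 13))
  dir <- withr::local_tempdir()
  np <- file.path(dir, "nadh.tif"); fp <- file.path(dir, "fad.tif")
  common <- max(ph$nadh$voxels, ph$fad$voxels)
  write_volume_tiff(ph$nadh, np, common)
  write_volume_tiff(ph$fad, fp, common)
  in_mem <- run_redox_pipeline(ph$nadh, ph$fad)$mean_rr
  on_disk <- run_redox_pipeline(np, fp)$mean_rr
  expect_equal(on_disk, in_mem, tolerance = 1e-3)
})
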