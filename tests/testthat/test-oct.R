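test_that("LRP is the lateral window mean, with degenerate widths handled", {
  img <- matrix(7, 50, 40)
  b <- bscan(img, axial_scale = 2)
  lrp <- compute_lrp(b, 20, 10)
  expect_true(all(lrp$reflectivity == 7))
  expect_equal(lrp$depth_um, (1:50 - 0.5) * 2)

  img2 <- matrix(runif(50 * 40), 50, 40)
  b2 <- bscan(img2)
  expect_equal(compute_lrp(b2, 13, 1)$reflectivity, img2[, 13])
  expect_error(compute_lrp(b2, 2, 100), class = "retinodex_input_error")
})

test_that("registration recovers planted integer shifts exactly and averages speckle", {
  ph <- make_oct_bscan(small_oct_cfg(speckle_cv = 0.05, seed = 2))
  img <- ph$bscan$image
  shifted <- img * 0
  shifted[4:nrow(img), 1:(ncol(img) - 2)] <- img[1:(nrow(img) - 3), 3:ncol(img)]
  pair <- register_and_average(list(ph$bscan,
                                    bscan(shifted,
                                          lateral_scale = ph$bscan$lateral_scale)))
  sh <- attr(pair, "shifts")
  expect_identical(c(sh$drow[2], sh$dcol[2]), c(-3L, 2L))

  # sqrt(n) averaging law on 80 speckled replicates
  cfg <- small_oct_cfg(speckle_cv = 0.2, seed = 30)
  noiseless <- make_oct_bscan(small_oct_cfg(speckle_cv = 0))$bscan$image
  set80 <- make_oct_scan_set(cfg, 80)
  avg <- register_and_average(set80$bscans)
  sd_single <- sd(set80$bscans[[1]]$image - noiseless)
  sd_avg <- sd(avg$image - noiseless)
  expect_lt(sd_avg, sd_single / 8)
})

test_that("single B-scan averaging is the identity", {
  ph <- make_oct_bscan(small_oct_cfg(speckle_cv = 0.1))
  out <- register_and_average(list(ph$bscan))
  expect_identical(out$image, ph$bscan$image)
  expect_error(register_and_average(list()), class = "retinodex_input_error")
})

test_that("boundaries on a noiseless phantom land within half an axial pixel of truth", {
  ph <- make_oct_bscan(small_oct_cfg())
  bnd <- detect_boundaries(compute_lrp(ph$bscan, 60, 40))
  d <- ph$truth$layer_depths
  expect_lt(abs(bnd$ilm - d[["ilm"]]), 0.5)
  expect_lt(abs(bnd$opl_onl - d[["opl_onl"]]), 0.5)
  expect_lt(abs(bnd$onl_isos - d[["onl_isos"]]), 0.5)
  expect_lt(abs(bnd$bm - d[["bm"]]), 0.5)
  # ordering invariant
  expect_true(bnd$ilm < bnd$opl_onl && bnd$opl_onl < bnd$onl_isos &&
                bnd$onl_isos < bnd$bm)
})

test_that("boundaries under speckle with 40-scan averaging stay within one pixel", {
  set40 <- make_oct_scan_set(small_oct_cfg(speckle_cv = 0.1, seed = 8), 40)
  avg <- register_and_average(set40$bscans)
  bnd <- detect_boundaries(compute_lrp(avg, 60, 100))
  d <- set40$truth$layer_depths
  expect_lt(abs(bnd$ilm - d[["ilm"]]), 1)
  expect_lt(abs(bnd$opl_onl - d[["opl_onl"]]), 1)
  expect_lt(abs(bnd$onl_isos - d[["onl_isos"]]), 1)
  expect_lt(abs(bnd$bm - d[["bm"]]), 1)
})

test_that("degenerate profiles raise analysis errors naming the problem", {
  flat <- structure(tibble::tibble(depth_um = 1:100 - 0.5,
                                   reflectivity = rep(3, 100)),
                    class = c("lrp", "tbl_df", "tbl", "data.frame"))
  expect_error(detect_boundaries(flat), class = "retinodex_analysis_error")
  two_band <- structure(
    tibble::tibble(depth_um = 1:100 - 0.5,
                   reflectivity = c(rep(1, 20), rep(10, 20), rep(1, 20),
                                    rep(10, 20), rep(1, 20))),
    class = c("lrp", "tbl_df", "tbl", "data.frame"))
  expect_error(detect_boundaries(two_band), "missing landmark",
               class = "retinodex_analysis_error")
})

test_that("total thickness recovers configured truth at the 10-location protocol", {
  # noiseless: sub-half-pixel recovery of the 178.1 um configuration
  ph <- make_oct_bscan(small_oct_cfg())
  tt <- total_retinal_thickness(ph$bscan, spacing_px = 15L, width_px = 24L)
  expect_lt(abs(as.numeric(tt) - 178.1), 0.5)
  locs <- attr(tt, "locations")
  expect_equal(nrow(locs), 10)
  # uniform phantom, windows clear of the ONH: all locations identical
  tt_clear <- total_retinal_thickness(ph$bscan, spacing_px = 25L,
                                      width_px = 24L)
  locs_clear <- attr(tt_clear, "locations")
  expect_true(all(abs(locs_clear$total_um - as.numeric(tt_clear)) < 1e-9))

  # speckled + 40-scan averaging: the 169.2 um configuration within 2 um
  set40 <- make_oct_scan_set(
    small_oct_cfg(speckle_cv = 0.1, seed = 4,
                  layer_depths = c(ilm = 20, ipl_inl = 80, inl_opl = 105,
                                   opl_onl = 125, onl_isos = 158,
                                   bm = 189.2)), 40)
  avg <- register_and_average(set40$bscans)
  tt2 <- total_retinal_thickness(avg, spacing_px = 15L, width_px = 24L)
  expect_lt(abs(as.numeric(tt2) - 169.2), 2)
})

test_that("thickness is invariant under global intensity scaling", {
  ph <- make_oct_bscan(small_oct_cfg(speckle_cv = 0.05, seed = 12))
  t1 <- as.numeric(total_retinal_thickness(ph$bscan, spacing_px = 15L,
                                           width_px = 24L))
  b2 <- ph$bscan; b2$image <- b2$image * 40
  t2 <- as.numeric(total_retinal_thickness(b2, spacing_px = 15L,
                                           width_px = 24L))
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("ONL profile is symmetric on a symmetric phantom and recovers truth", {
  cfg <- oct_phantom_profile("PBM-p30")
  cfg$speckle_cv <- 0  # symmetry is exact only without speckle
  ph <- make_oct_bscan(cfg)
  prof <- onl_thickness_profile(ph$bscan)
  onl <- prof$onl
  expect_equal(nrow(onl), 10)
  for (off in c(88, 176, 264, 352, 440)) {
    sup <- onl$onl_um[onl$offset_um == off]
    inf <- onl$onl_um[onl$offset_um == -off]
    expect_equal(sup, inf, tolerance = 1e-6)
  }
  expect_true(all(abs(onl$onl_um - 40) < 0.5))
  expect_true(all(onl$onl_um < prof$total_um))
})

test_that("thickness recovery across 20 seeded phantoms is sub-pixel on average", {
  truths <- seq(120, 190, length.out = 20)
  errs <- vapply(seq_along(truths), function(i) {
    tr <- truths[i]
    depths <- c(ilm = 20, ipl_inl = 20 + 0.30 * tr, inl_opl = 20 + 0.45 * tr,
                opl_onl = 20 + 0.55 * tr, onl_isos = 20 + 0.82 * tr,
                bm = 20 + tr)
    set40 <- make_oct_scan_set(
      small_oct_cfg(speckle_cv = 0.05, seed = 100 + i,
                    layer_depths = depths), 40)
    avg <- register_and_average(set40$bscans)
    tt <- total_retinal_thickness(avg, spacing_px = 15L, width_px = 24L)
    abs(as.numeric(tt) - tr)
  }, numeric(1))
  expect_lt(mean(errs), 1)  # < 1 axial pixel (1 um)
})

test_that("longitudinal summaries flag monotone thinning and difference arithmetic", {
  ages <- c(16, 30, 50, 80)
  mean_um <- c(190, 170, 140, 120)
  cohorts <- purrr::map_dfr(seq_along(ages), function(i) {
    tibble::tibble(age_days = ages[i],
                   total_um = mean_um[i] + c(-1, 0, 1))
  })
  ls <- longitudinal_summary(cohorts)
  expect_true(all(ls$monotone_decrease$monotone_decrease))
  expect_equal(ls$by_age$mean_um, mean_um)

  # two groups, identical: zero differences
  two <- dplyr::bind_rows(
    dplyr::mutate(cohorts, group = "a"),
    dplyr::mutate(cohorts, group = "b"))
  ls2 <- longitudinal_summary(two)
  expect_true(all(ls2$comparisons$difference_um == 0))

  # printed-value subtraction: p25 vs p32 group means
  d3 <- tibble::tibble(age_days = c(25, 32), total_um = c(173.7, 161.6))
  ls3 <- longitudinal_summary(d3)
  expect_equal(diff(ls3$by_age$mean_um), -12.1)

  expect_error(longitudinal_summary(tibble::tibble(age_days = 1,
                                                   total_um = 1)),
               class = "retinodex_input_error")
  expect_error(
    longitudinal_summary(tibble::tibble(age_days = c(1, NA),
                                        total_um = c(1, 2))),
    class = "retinodex_input_error")
})
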