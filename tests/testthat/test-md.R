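# Bilayer MD post-processing: centering, density profiles, peaks, APL.

test_that("membrane centering is an identity on centered frames and
           invariant to rigid shifts and periodic wrapping", {
  tj <- toy_bilayer(n_frames = 1, seed = 2)
  fr <- tj$frames[[1]]
  fr$xyz[, 3] <- fr$xyz[, 3] - mean(fr$xyz[tj$groups$PO4, 3])  # near-centered
  c0 <- center_membrane(fr, tj$groups$PO4)
  # shifting everything by +5 A and recentering recovers the same frame
  fr5 <- fr; fr5$xyz[, 3] <- fr5$xyz[, 3] + 5
  c5 <- center_membrane(fr5, tj$groups$PO4)
  expect_equal(c5$xyz, c0$xyz, tolerance = 1e-9)
  # wrapping across the periodic boundary does not move the center
  Lz <- fr$box[3]
  frw <- fr5
  frw$xyz[, 3] <- frw$xyz[, 3] - Lz * round(frw$xyz[, 3] / Lz)  # wrap copy
  cw <- center_membrane(frw, tj$groups$PO4)
  expect_equal(cw$xyz[, 3], c5$xyz[, 3], tolerance = 1e-9)
  expect_error(center_membrane(fr, integer(0)), "empty reference")
})

test_that("density profiles recover mirrored Gaussian peaks at +/-20 A", {
  tj <- generate_toy_trajectory(
    60, groups = list(PO4 = list(count = 400, mean_z = 20, sd_z = 2)),
    box = c(60, 60, 100), seed = 4)
  prof <- density_profile(tj, bin_width = 1)
  pk <- peak_stats(prof, "PO4")
  expect_false(pk$flagged)
  expect_lt(abs(abs(pk$position) - 20), 0.5)
  # symmetrized: mirrored bins agree exactly
  expect_equal(prof$density[, "PO4"], rev(prof$density[, "PO4"]))
  # expected peak height: half the atoms per leaflet, Gaussian at mode
  rho_exp <- (400 / 2) * dnorm(0) / 2 / (60 * 60) * 1000   # nm^-3
  expect_lt(abs(pk$height - rho_exp) / rho_exp, 0.15)
})

test_that("histogram conservation holds to 1e-9 relative", {
  tj <- toy_bilayer(n_frames = 10, seed = 5)
  prof <- density_profile(tj, bin_width = 1, symmetrize = FALSE)
  A <- 60 * 60
  for (g in colnames(prof$density)) {
    integral <- sum(prof$density[, g]) * prof$bin_width * A / 1000
    expect_lt(abs(integral - prof$counts[[g]]) / prof$counts[[g]], 1e-9)
  }
  # symmetrization preserves the integral and is idempotent
  ps <- density_profile(tj, bin_width = 1, symmetrize = TRUE)
  for (g in colnames(ps$density))
    expect_equal(sum(ps$density[, g]), sum(prof$density[, g]),
                 tolerance = 1e-12)
  d <- ps$density[, 1]
  expect_equal((d + rev(d)) / 2, d, tolerance = 1e-12)
})

test_that("profiles are invariant under rigid z-translation when centering", {
  tj <- toy_bilayer(n_frames = 5, seed = 6)
  tj_shift <- tj
  for (i in seq_along(tj_shift$frames))
    tj_shift$frames[[i]]$xyz[, 3] <- tj_shift$frames[[i]]$xyz[, 3] + 13.7
  p1 <- density_profile(tj, bin_width = 2)
  p2 <- density_profile(tj_shift, bin_width = 2)
  expect_equal(p2$density, p1$density, tolerance = 1e-9)
})

test_that("peak statistics flag flat profiles and scale linearly", {
  tj <- generate_toy_trajectory(
    30, groups = list(W = list(count = 500, uniform = TRUE),
                      PO4 = list(count = 100, mean_z = 20, sd_z = 2)),
    box = c(50, 50, 80), seed = 7)
  prof <- density_profile(tj, bin_width = 2, reference_group = "PO4")
  w <- prof$density[, "W"]
  expect_lt((max(w) - min(w)) / max(w), 0.5)   # roughly uniform
  flat <- prof
  flat$density[, "W"] <- 1
  expect_true(peak_stats(flat, "W")$flagged)
  dbl <- prof
  dbl$density <- prof$density * 2
  expect_equal(peak_stats(dbl, "PO4")$height,
               2 * peak_stats(prof, "PO4")$height)
  expect_equal(peak_stats(dbl, "PO4")$position,
               peak_stats(prof, "PO4")$position)
})

test_that("area per lipid is exact for constant boxes and averages otherwise", {
  frames <- replicate(4, list(xyz = matrix(0, 2, 3), box = c(64, 64, 80)),
                      simplify = FALSE)
  tj <- bilayer_trajectory(frames, groups = list(a = 1:2),
                           lipids_per_leaflet = 64L)
  apl <- area_per_lipid(tj)
  expect_equal(apl$apl, rep(64, 4))
  expect_equal(apl$mean, 64)
  expect_equal(apl$se, 0)
  # two frames with areas 60 and 70 -> mean 65
  f2 <- list(list(xyz = matrix(0, 1, 3), box = c(6, 10, 80)),
             list(xyz = matrix(0, 1, 3), box = c(7, 10, 80)))
  tj2 <- bilayer_trajectory(f2, lipids_per_leaflet = 1L)
  expect_equal(area_per_lipid(tj2)$mean, 65)
  expect_error(area_per_lipid(bilayer_trajectory(f2)), "lipids_per_leaflet")
})

test_that("GRO round-trip preserves coordinates, groups and boxes", {
  tj <- toy_bilayer(n_frames = 3, seed = 8)
  path <- tempfile(fileext = ".gro")
  write_gro(tj, path)
  back <- read_gro(path, lipids_per_leaflet = 64L)
  expect_length(back$frames, 3)
  expect_equal(sort(names(back$groups)), sort(names(tj$groups)))
  for (i in 1:3) {
    expect_equal(back$frames[[i]]$box, tj$frames[[i]]$box, tolerance = 1e-3)
    # GRO stores nm to 3 decimals -> 0.01 A round-off
    expect_lt(max(abs(back$frames[[i]]$xyz - tj$frames[[i]]$xyz)), 0.006)
  }
  # analysis results survive the round trip
  p1 <- density_profile(tj, bin_width = 2, groups = "PO4")
  p2 <- density_profile(back, bin_width = 2, groups = "PO4")
  expect_equal(p2$density, p1$density, tolerance = 0.01)
})
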