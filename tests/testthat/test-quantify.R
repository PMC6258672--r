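test_that("stack preprocessing picks the sharp plane and subtracts background", {
  fr <- fix_rendered()
  pp <- preprocess_stack(fr$imgs$stacks$ecadherin, bg_radius = 20)
  expect_equal(pp$focus_plane, fr$imgs$focus_plane)

  # zero basal signal: processed equals signal
  st <- fr$imgs$stacks$ecadherin
  Z <- dim(st)[3]
  st[, , (Z - 2):Z] <- 0
  pp0 <- preprocess_stack(st, bg_radius = 20)
  expect_equal(pp0$image, pmax(pp0$signal, 0))

  # uniform stack: all zeros out
  ppu <- preprocess_stack(array(3, dim = c(32, 32, 6)), bg_radius = 10)
  expect_true(all(ppu$image == 0))

  expect_error(preprocess_stack(array(0, dim = c(16, 16, 2))), "at least 3")
})

test_that("ROI classes are disjoint and degenerate ROIs are flagged", {
  fr <- fix_identity_render()
  rois <- extract_rois(fr$gen$network, labels = fr$imgs$labels)
  expect_identical(sum(rois$junctional > 0 & rois$medial > 0), 0L)
  # medial ROIs respect the margin: no medial pixel within margin of a band
  jm <- junction_pixel_map(fr$gen$network, dim(fr$imgs$labels),
                          halfwidth = floor(rois$junction_width / 2))
  D <- as.matrix(EBImage::distmap(1 - (jm > 0) * 1))
  expect_true(all(D[rois$medial > 0] >= rois$medial_margin))
})

test_that("a large square cell's medial ROI area matches brute force", {
  # hand-built 41x41 square cell with its four wall junctions
  W <- 61
  lab <- matrix(2L, W, W)
  lab[11:51, 11:51] <- 1L
  .skel <- getFromNamespace(".skeletonize_labels", "junctionforce")
  lab <- .skel(lab)
  vertices <- data.frame(id = 1:4, x = c(10, 51, 51, 10), y = c(10, 10, 51, 51))
  junctions <- data.frame(id = 1:4, v1 = 1:4, v2 = c(2, 3, 4, 1),
                          cell_a = 1L, cell_b = 2L, length = 41,
                          angle = c(0, 90, 0, 90), boundary = FALSE)
  cells <- data.frame(id = 1:2, cx = c(30.5, 5), cy = c(30.5, 5),
                      boundary = c(FALSE, TRUE))
  net <- tissue_network(vertices, junctions, cells, labels = lab)
  rois <- extract_rois(net, labels = lab, junction_width = 5,
                       vertex_radius = 3, medial_margin = 2)
  got <- sum(rois$medial == 1L)
  # brute force: medial pixels stay >= margin away from the full junctional
  # band including the tri-cellular vertex regions
  band <- junction_pixel_map(net, dim(lab), halfwidth = 2, vertex_radius = 0)
  D <- as.matrix(EBImage::distmap(1 - (band > 0) * 1))
  brute <- sum(lab == 1L & D >= 2)
  expect_identical(got, brute)
  # analytic count: walls at 10/51, band half-width 2, margin 2 leaves a
  # 34 x 34 interior square
  expect_identical(got, 34L * 34L)
})

test_that("roi_density is exact for constant and identity-rendered images", {
  fr <- fix_identity_render()
  rois <- extract_rois(fr$gen$network, labels = fr$imgs$labels)
  # constant image: every density equals the constant
  cimg <- matrix(4.2, nrow(fr$imgs$labels), ncol(fr$imgs$labels))
  cd <- roi_density(cimg, rois)
  expect_true(all(abs(cd$junctions$density[!cd$junctions$empty] - 4.2) < 1e-12))
  expect_true(all(abs(cd$cells$density[!cd$cells$empty] - 4.2) < 1e-12))

  # identity render: painted densities recovered exactly
  img <- fr$imgs$stacks$ecadherin[, , fr$cfg$focus_plane]
  rd <- roi_density(img, rois)
  m <- merge(rd$junctions, fr$dens, by = "junction_id")
  m <- m[!m$empty & !m$boundary, ]
  expect_gt(nrow(m), 80)
  expect_lt(max(abs(m$density - m$ecadherin) / m$ecadherin), 1e-12)
})

test_that("densities survive realistic rendering within ten percent", {
  fr <- fix_rendered()
  pp <- preprocess_stack(fr$imgs$stacks$ecadherin, bg_radius = 20)
  rois <- extract_rois(fr$gen$network, labels = fr$imgs$labels)
  rd <- roi_density(pp$image, rois)
  m <- merge(rd$junctions, fr$dens, by = "junction_id")
  m <- m[!m$empty & !m$boundary & m$n_pixels >= 10, ]
  relerr <- abs(m$density - m$ecadherin) / m$ecadherin
  expect_lt(stats::median(relerr), 0.10)
})

test_that("background offsets cancel out of processed densities", {
  fr <- fix_identity_render()
  st <- fr$imgs$stacks$ecadherin
  rois <- extract_rois(fr$gen$network, labels = fr$imgs$labels)
  p0 <- preprocess_stack(st, bg_radius = 20)
  p1 <- preprocess_stack(st + 17.5, bg_radius = 20)
  d0 <- roi_density(p0$image, rois)$junctions
  d1 <- roi_density(p1$image, rois)$junctions
  ok <- !d0$empty
  expect_equal(d1$density[ok], d0$density[ok], tolerance = 1e-6)
})

test_that("polarity profile recovers uniformity, amplitude and errors", {
  set.seed(1)
  ang <- runif(600, 0, 90)
  # uniform densities: PCP 1, flat relative intensity
  pp <- polarity_profile(rep(5, 600), ang)
  expect_equal(pp$pcp, 1)
  expect_true(all(abs(pp$relative_intensity - 1) < 1e-12))

  # empty extreme bin errors with the bin named
  expect_error(polarity_profile(rep(1, 10), rep(45, 10)), "0-15")
  expect_error(polarity_profile(c(1, 1), c(5, 50)), "75-90")

  # zero extreme bin is guarded in both orientations
  dens0 <- ifelse(ang >= 75, 2, 0)
  expect_error(polarity_profile(dens0, ang, "AP/DV"), "positive")
  expect_error(polarity_profile(dens0, ang, "DV/AP"), "positive")
})

test_that("generator polarity amplitudes are recovered from line densities", {
  # noiseless: exact ramp, amplitude recovered within 5%
  cfg <- synth_config(n_cells = 350, domain = c(850, 850), seed = 3,
                      noise_myo = 0, noise_ecad = 0,
                      noise_vinc = 0)
  gen <- generate_equilibrium_network(cfg)
  dens <- assign_intensities(gen$network, gen$truth, cfg)
  int <- !dens$boundary
  expect_gte(sum(int), 300)
  pcp <- polarity_profile(dens$myosin[int], dens$angle[int], "DV/AP")$pcp
  expect_lt(abs(pcp - cfg$pcp_myo) / cfg$pcp_myo, 0.05)
  # E-cadherin is AP-enriched
  pcp_e <- polarity_profile(dens$ecadherin[int], dens$angle[int], "AP/DV")$pcp
  expect_gt(pcp_e, 1)

  # default noise, mean over seeds within 15%
  rec <- vapply(1:5, function(s) {
    cfgs <- synth_config(n_cells = 350, domain = c(850, 850), seed = s)
    g <- generate_equilibrium_network(cfgs)
    d <- assign_intensities(g$network, g$truth, cfgs)
    i <- !d$boundary
    polarity_profile(d$myosin[i], d$angle[i], "DV/AP")$pcp
  }, numeric(1))
  expect_lt(abs(mean(rec) - 2.0) / 2.0, 0.15)
})

test_that("pixel-scale ratio profiles behave on constant, trending and empty inputs", {
  set.seed(4)
  ecad <- matrix(0, 128, 128)
  ecad[40:90, 40:44] <- 120; ecad[40:90, 80:84] <- 220
  ecad <- ecad + matrix(rnorm(128^2, 0, 2), 128, 128)
  mask <- ecad > 50

  # constant per-pixel ratio: every bin mean is that ratio
  pr <- pixel_ratio_profile(0.5 * ecad, ecad, junction_mask = mask,
                            bg_radius = 10)
  expect_false(pr$empty)
  expect_true(all(abs(pr$bins$mean_ratio - 0.5) < 1e-9))

  # ratio increasing with intensity: bin means increase
  vinc <- ecad * (0.2 + 0.002 * ecad)
  pr2 <- pixel_ratio_profile(vinc, ecad, junction_mask = mask, bg_radius = 10)
  big <- pr2$bins[pr2$bins$n_pixels >= 20, ]
  expect_true(all(diff(big$mean_ratio) > 0))
  expect_equal(big$bin_hi - big$bin_lo, rep(25, nrow(big)))

  # pure background: empty profile, flagged
  flat <- matrix(rnorm(64^2, 10, 0.5), 64, 64)
  pr3 <- pixel_ratio_profile(flat, flat, junction_mask = matrix(FALSE, 64, 64),
                             bg_radius = 10)
  expect_true(pr3$empty)
})

test_that("junction ratio equals pixel-weighted ratio when the denominator is constant", {
  fr <- fix_identity_render()
  rois <- extract_rois(fr$gen$network, labels = fr$imgs$labels)
  # constant E-cadherin, spatially varying Vinculin
  W <- nrow(fr$imgs$labels); H <- ncol(fr$imgs$labels)
  ecad <- matrix(100, W, H)
  vinc <- matrix(rep(seq_len(W) / W, H), W, H) * 30
  dj_v <- roi_density(vinc, rois)$junctions
  dj_e <- roi_density(ecad, rois)$junctions
  ratio_of_means <- dj_v$density / dj_e$density
  mean_of_ratios <- roi_density(vinc / ecad, rois)$junctions$density
  ok <- !dj_v$empty
  expect_equal(ratio_of_means[ok], mean_of_ratios[ok], tolerance = 1e-12)
})
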