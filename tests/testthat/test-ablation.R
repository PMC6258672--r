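test_that("recoil velocity reads linear separations and guards frames", {
  tr <- function(d_of_t) {
    do.call(rbind, lapply(seq(0, 3, by = 0.25), function(t) {
      data.frame(t = t, vertex = c(1L, 2L),
                 x = c(0, d_of_t(t)), y = 0)
    }))
  }
  ev_static <- list(tracks = tr(function(t) 5), t0 = 0)
  expect_equal(recoil_velocity(ev_static), 0)

  ev_lin <- list(tracks = tr(function(t) 5 + 0.3 * t), t0 = 0)
  expect_equal(recoil_velocity(ev_lin), 0.3)

  # nearest-frame fallback warns inside tolerance, errors outside
  sparse <- ev_lin
  sparse$tracks <- sparse$tracks[sparse$tracks$t %in% c(0, 1.75), ]
  w <- testthat::capture_warnings(v <- recoil_velocity(sparse, window_s = 2))
  expect_true(length(w) >= 1 && all(grepl("nearest frame", w)))
  expect_equal(v, (0.3 * 1.75) / 2)
  sparse2 <- ev_lin
  sparse2$tracks <- sparse2$tracks[sparse2$tracks$t == 0, ]
  expect_error(recoil_velocity(sparse2), "no track point")
})

test_that("neighbour-normalised intensity requires 20 neighbours", {
  mk <- function(n_nb, abl = 2, nb = 1) {
    dd <- data.frame(t = 0, junction_id = seq_len(n_nb + 1),
                     channel = "ecadherin",
                     density = c(abl, rep(nb, n_nb)))
    list(junction = 1L, densities = dd)
  }
  expect_equal(normalized_junction_intensity(mk(25, abl = 1, nb = 1))$ratio, 1)
  expect_equal(normalized_junction_intensity(mk(25, abl = 2, nb = 1))$ratio, 2)
  expect_error(normalized_junction_intensity(mk(12)), "at least 20")
})

test_that("shear-increase selection follows the quadruple logic", {
  net <- fix_quad_net()
  tens <- quad_tensions(T1 = 3, T2 = 1, T3 = 2, T4 = 1)
  # ablate the junction playing T4 for the central junction: selected
  sel <- select_shear_increase(net, tens, 14L)
  expect_true(sel$selected[sel$junction_id == 10L])
  expect_identical(sel$role[sel$junction_id == 10L], "T4")
  # ablate the junction playing T1 (dominant side): not selected
  sel2 <- select_shear_increase(net, tens, 11L)
  expect_false(sel2$selected[sel2$junction_id == 10L])
  # tie (T1+T3) == (T2+T4): strict inequality, not selected
  tie <- quad_tensions(T1 = 1, T2 = 1, T3 = 1, T4 = 1)
  sel3 <- select_shear_increase(net, tie, 14L)
  expect_false(sel3$selected[sel3$junction_id == 10L])
})

test_that("selection is invariant to relabelling the central junction's sides", {
  tens <- quad_tensions(T1 = 3, T2 = 1, T3 = 2, T4 = 1)
  s0 <- select_shear_increase(fix_quad_net(), tens, 14L)
  s1 <- select_shear_increase(fix_quad_net(swap_sides = TRUE), tens, 14L)
  expect_identical(s0$junction_id[s0$selected], s1$junction_id[s1$selected])
})

test_that("relative change evaluates windows with guards", {
  ser <- data.frame(t = seq(0, 30, by = 2), value = 100)
  expect_equal(relative_change(ser, 0, 20), 0)
  ser2 <- ser; ser2$value <- seq(100, 70, length.out = nrow(ser))
  expect_equal(relative_change(data.frame(t = c(0, 20), value = c(100, 80)),
                               0, 20), -0.2)
  expect_error(relative_change(data.frame(t = c(0, 20), value = c(0, 10)), 0, 20),
               "zero")
  expect_error(relative_change(data.frame(t = c(0, 5), value = c(1, 2)), 0, 20),
               "no frame")
})

test_that("simulated recoil matches the closed-form first step and the drag limit", {
  gen <- fix_hex_tissue()
  cfg <- gen$truth$config
  jn <- gen$network$junctions
  j <- jn$id[jn$retained][1]
  ev <- simulate_ablation(gen$network, gen$truth, j, cfg, n_steps = 2,
                          dt = 1e-3, turnover = FALSE)
  Tab <- gen$truth$tensions$tension[gen$truth$tensions$junction_id == j]
  v0 <- recoil_velocity(ev, window_s = 1e-3, tolerance_s = 1e-3)
  expect_lt(abs(v0 - 2 * Tab / cfg$gamma) / (2 * Tab / cfg$gamma), 0.05)

  # infinite drag: no recoil
  cfg_inf <- gen$truth$config; cfg_inf$gamma <- 1e12
  ev_inf <- simulate_ablation(gen$network, gen$truth, j, cfg_inf, n_steps = 5,
                              dt = 0.1, turnover = FALSE)
  expect_lt(recoil_velocity(ev_inf, window_s = 0.5, tolerance_s = 0.1), 1e-9)
})

test_that("shear-insensitive turnover relaxes to the on/off fixed point", {
  gen <- fix_hex_tissue()
  cfg <- gen$truth$config
  cfg$shear_sens <- 0
  jn <- gen$network$junctions
  j <- jn$id[jn$retained][3]
  ev <- simulate_ablation(gen$network, gen$truth, j, cfg, n_steps = 10, dt = 0.05)
  dd <- ev$densities[ev$densities$t == max(ev$densities$t), ]
  expect_lt(max(abs(dd$density - cfg$k_on / cfg$k_off0)),
            1e-6 * cfg$k_on / cfg$k_off0)
})

test_that("shear-sensitive turnover lowers E-cadherin on shear-increased junctions", {
  gen <- fix_tissue(seed = 4)
  net <- gen$network
  cfg <- gen$truth$config
  jn <- net$junctions
  set.seed(17)
  abl <- sample(jn$id[jn$retained], 12)
  sel_change <- c(); ctrl_change <- c()
  for (j in abl) {
    ev <- simulate_ablation(net, gen$truth, j, cfg, n_steps = 20, dt = 1)
    sel <- select_shear_increase(net, gen$truth$tensions, j)
    picked <- sel$junction_id[sel$selected]
    neigh <- sel$junction_id
    for (cj in picked) {
      ser <- ev$densities[ev$densities$junction_id == cj, c("t", "density")]
      names(ser) <- c("t", "value")
      sel_change <- c(sel_change, relative_change(ser, 0, 20))
    }
    ctrl <- setdiff(jn$id[jn$retained], c(neigh, j))
    for (cj in sample(ctrl, 5)) {
      ser <- ev$densities[ev$densities$junction_id == cj, c("t", "density")]
      names(ser) <- c("t", "value")
      ctrl_change <- c(ctrl_change, relative_change(ser, 0, 20))
    }
  }
  expect_gt(length(sel_change), 5)
  expect_lt(stats::median(sel_change), stats::median(ctrl_change))
})
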