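test_that("stage presets satisfy their defining relations", {
  m <- make_ground_truth("mature")
  expect_gt(m$E_inner, m$E_outer)
  y <- make_ground_truth("young")
  expect_equal(y$E_inner, y$E_outer)
  g <- make_ground_truth("gmc")
  expect_equal(g$E_inner, g$E_outer)
  expect_error(make_ground_truth("mature", E_inner = 5, E_outer = 6),
               "E_inner > E_outer")
  expect_error(make_ground_truth("mature",
                                 pose = list(center = c(5, 5),
                                             axes = c(12, 6.5),
                                             orientation = 0)),
               "fit")
})

test_that("the mature field attains its maximum on the polar caps", {
  gt <- make_ground_truth("mature", map_size = 40)
  xs <- seq(2, 38, by = 0.05)
  grid <- expand.grid(x = xs, y = xs)
  E <- eval_modulus(gt, grid$x, grid$y)
  top <- grid[which.max(E), ]
  poles <- rbind(gt$pose$center + c(gt$pose$axes[1], 0),
                 gt$pose$center - c(gt$pose$axes[1], 0))
  expect_lt(min(sqrt((top$x - poles[, 1])^2 + (top$y - poles[, 2])^2)), 1.5)
  expect_equal(max(E), gt$E_pole, tolerance = 1e-6)
})

test_that("ridge crest values equal the preset moduli", {
  gt <- make_ground_truth("mature", map_size = 40)
  ctr <- gt$pose$center
  b <- gt$pose$axes[2]
  h <- gt$separation / 2
  expect_equal(eval_modulus(gt, ctr[1], ctr[2] + b - h), gt$E_inner,
               tolerance = 1e-3)
  expect_equal(eval_modulus(gt, ctr[1], ctr[2] + b + h), gt$E_outer,
               tolerance = 1e-3)
  expect_equal(eval_modulus(gt, ctr[1], ctr[2]), gt$E_bg, tolerance = 1e-6)
})

test_that("the true diameter gradient of the mature preset is 4 MPa/um", {
  gt <- make_ground_truth("mature", map_size = 40)
  ctr <- gt$pose$center
  yy <- seq(ctr[2] - 10, ctr[2] + 10, by = 0.005)
  E <- eval_modulus(gt, rep(ctr[1], length(yy)), yy)
  # crest values on the upper guard cell
  upper <- yy > ctr[2]
  Ein <- max(E[upper & abs(yy - ctr[2] - (gt$pose$axes[2] - 0.5)) < 0.4])
  Eout <- max(E[upper & abs(yy - ctr[2] - (gt$pose$axes[2] + 0.5)) < 0.4])
  expect_equal((Ein - Eout) / gt$separation, 4.0, tolerance = 0.02)
})

test_that("identical seeds give identical maps, different seeds differ", {
  cfg <- small_afm_cfg(grid = 16)
  gt <- make_ground_truth("young", map_size = cfg$map_size)
  m1 <- simulate_force_map(gt, cfg, noise_model(seed = 7))
  m2 <- simulate_force_map(gt, cfg, noise_model(seed = 7))
  expect_identical(m1$deflection_V, m2$deflection_V)
  m3 <- simulate_force_map(gt, cfg, noise_model(seed = 8))
  expect_false(identical(m1$deflection_V, m3$deflection_V))
})

test_that("simulated indentation depths on stomatal walls match the acquisition regime", {
  cfg <- small_afm_cfg(grid = 48)
  gt <- make_ground_truth("mature", map_size = cfg$map_size)
  fm <- simulate_force_map(gt, cfg, silent_noise())
  em <- process_force_map(fm)
  ok <- em$flag == "ok"
  on_wall <- fm$E_true >= 4
  expect_gt(sum(ok & on_wall), 50)
  expect_true(all(em$delta_max[ok & on_wall] >= 100))
  expect_true(all(em$delta_max[ok & on_wall] <= 1000))
  # nothing indents less than 100 nm at the 1000 nN setpoint
  expect_true(all(em$delta_max[ok] >= 100))
})

test_that("a modulus too low for the approach range flags the pixel saturated", {
  cfg <- small_afm_cfg(grid = 8)
  gt <- make_ground_truth("young", map_size = cfg$map_size, E_bg = 0.5)
  fm <- simulate_force_map(gt, cfg, silent_noise())
  expect_gt(sum(fm$saturated), 0)
  em <- suppressWarnings(process_force_map(fm))
  expect_true(any(em$flag == "saturated"))
})

test_that("noise-free synthetic maps round-trip through the pipeline within 2%", {
  cfg <- small_afm_cfg(grid = 64)
  for (stage in c("mature", "young")) {
    gt <- make_ground_truth(stage, map_size = cfg$map_size)
    fm <- simulate_force_map(gt, cfg, silent_noise())
    em <- process_force_map(fm)
    ok <- em$flag == "ok"
    regions <- list(wall = fm$E_true >= 4,
                    background = fm$E_true < 2.5)
    for (r in regions) {
      sel <- ok & r
      expect_gt(sum(sel), 20)
      expect_lt(abs(stats::median(em$Ea[sel] / fm$E_true[sel]) - 1), 0.02)
    }
  }
})

test_that("the processed mature map shows 4 wall ridges and 2 polar peaks", {
  cfg <- afm_config(map_size = 40)  # full 128 x 128 per-stoma grid
  gt <- make_ground_truth("mature", map_size = 40)
  fm <- simulate_force_map(gt, cfg, silent_noise())
  em <- process_force_map(fm)
  prof <- extract_transect(em, gt$pose, mode = "diameter")
  pk <- stomech:::find_profile_peaks(prof$position, prof$Ea)
  expect_identical(length(pk), 4L)
  gr <- gradient_statistic(prof)
  expect_identical(gr$flag, "ok")
  # inner pair higher than outer pair
  expect_true(all(gr$peaks$Ea[gr$peaks$wall == "inner"] >
                    gr$peaks$Ea[gr$peaks$wall == "outer"]))
  circ <- extract_transect(em, gt$pose, mode = "circumference")
  pc <- stomech:::find_profile_peaks(circ$position, circ$Ea,
                                     prominence_frac = 0.25, min_sep = 3)
  expect_identical(length(pc), 2L)
  # the two main circumferential peaks sit at the poles (quarter and
  # three-quarter arc length from the equatorial start)
  total <- max(circ$position)
  expect_lt(abs(circ$position[pc[1]] / total - 0.25), 0.06)
  expect_lt(abs(circ$position[pc[2]] / total - 0.75), 0.06)
})

test_that("force curves round-trip through CSV", {
  cv <- synth_hertz_curve(E_MPa = 5)
  path <- tempfile(fileext = ".csv")
  write_force_curve_csv(cv, path)
  back <- read_force_curve_csv(path)
  expect_equal(back$z, cv$z)
  expect_equal(back$deflection_V, cv$deflection_V)
})
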