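test_that("voltage-to-force calibration is dimensional and linear", {
  cfg <- afm_config(spring_constant = 45, sensitivity = 20)
  z <- seq(0, 100, by = 5)
  cv <- calibrate_curve(force_curve(z, deflection_V = rep(1, length(z))), cfg)
  expect_equal(cv$force, rep(900, length(z)))  # 1 V * 20 nm/V * 45 N/m
  cv0 <- calibrate_curve(force_curve(z, deflection_V = rep(0, length(z))), cfg)
  expect_equal(cv0$force, rep(0, length(z)))
  cfg2 <- afm_config(spring_constant = 45, sensitivity = 40)
  cv2 <- calibrate_curve(force_curve(z, deflection_V = rep(1, length(z))), cfg2)
  expect_equal(cv2$force, 2 * cv$force)
})

test_that("baseline and tilt are recovered and removed", {
  cfg <- afm_config()
  cv <- synth_hertz_curve(E_MPa = 5, tilt = 0.03, offset = -12)
  cv <- calibrate_curve(cv, cfg)
  cor <- correct_baseline_tilt(cv)
  expect_false(cor$rejected)
  expect_equal(unname(cor$baseline["slope"]), 0.03, tolerance = 0.01)
  expect_equal(unname(cor$baseline["offset"]), -12, tolerance = 0.01 * 12)
  pre <- cor$force[cor$z < 400]
  expect_lt(max(abs(pre)), 1e-6)
  # idempotence on an already-flat curve
  cor2 <- correct_baseline_tilt(cor)
  expect_lt(max(abs(cor2$force - cor$force), na.rm = TRUE), 1e-9)
})

test_that("curves in contact from the first sample are rejected", {
  cfg <- afm_config()
  cv <- synth_hertz_curve(E_MPa = 5, z0 = -200, cfg = cfg)
  cv <- calibrate_curve(cv, cfg)
  cor <- correct_baseline_tilt(cv)
  expect_true(cor$rejected)
})

test_that("contact point is recovered to nm precision", {
  cfg <- afm_config()
  z0_true <- 487
  cv <- correct_baseline_tilt(calibrate_curve(
    synth_hertz_curve(E_MPa = 5, z0 = z0_true, cfg = cfg), cfg))
  z0 <- detect_contact_point(cv)
  expect_lt(abs(z0 - z0_true), 1)
  # all-zero force: no contact
  flat <- force_curve(cv$z, force = rep(0, length(cv$z)))
  flat$calibrated <- TRUE
  flat <- correct_baseline_tilt(flat)
  flat$noise_sd <- 0.1
  flat$corrected <- TRUE
  expect_true(isTRUE(attr(detect_contact_point(flat), "no_contact")))
})

test_that("noisy contact detection tracks the maximum-likelihood precision floor", {
  # at 2%-of-setpoint force noise the achievable contact precision is set
  # by statistics, not the algorithm: the oracle below fits the exact
  # forward model (known baseline, joint least squares over c and z0 by
  # full grid search) and defines the floor the detector is held to
  cfg <- afm_config()
  z0_true <- 500
  k <- cfg$spring_constant
  cc <- stomech:::hertz_prefactor(cfg) * 5
  oracle_err <- vapply(1:100, function(s) {
    set.seed(s)
    z <- seq(0, cfg$z_pre + cfg$z_post, by = cfg$dz)
    zz <- pmax(z - z0_true, 0)
    ck <- cc / k
    delta <- (-1 + sqrt(1 + 4 * ck * zz)) / (2 * ck)
    F <- cc * delta^2 + stats::rnorm(length(z), 0, 0.02 * cfg$setpoint)
    win <- which(z < z[which(cc * delta^2 >= 0.5 * cfg$setpoint)[1]])
    zw <- z[win] - pmax(F[win], 0) / k
    cand <- seq(350, 650, by = 1)
    sse <- vapply(cand, function(zc) {
      d2 <- pmax(zw - zc, 0)^2
      chat <- sum(F[win] * d2) / sum(d2^2)
      sum((F[win] - chat * d2)^2)
    }, numeric(1))
    cand[which.min(sse)] - z0_true
  }, numeric(1))
  errs <- vapply(1:100, function(s) {
    cv <- synth_hertz_curve(E_MPa = 5, z0 = z0_true, cfg = cfg,
                            noise_sd = 0.02 * cfg$setpoint, seed = s)
    cv <- correct_baseline_tilt(calibrate_curve(cv, cfg))
    detect_contact_point(cv, k = cfg$spring_constant) - z0_true
  }, numeric(1))
  floor_med <- stats::median(abs(oracle_err))
  expect_lt(stats::median(abs(errs)), 2 * floor_med + 2)
  expect_lt(stats::median(abs(errs)), 20)
})

test_that("indentation subtracts cantilever bending", {
  cfg <- afm_config()
  # rigid surface: deflection equals piezo travel past contact, depth zero
  z <- seq(0, 1000, by = 5)
  z0 <- 400
  f <- pmax(z - z0, 0) * cfg$spring_constant
  rigid <- force_curve(z, force = f)
  rigid$calibrated <- TRUE; rigid$corrected <- TRUE; rigid$noise_sd <- 1e-9
  di <- compute_indentation(rigid, cfg, z0)
  expect_lt(max(abs(di$delta)), 1e-9)
  # forward model round trip
  cv <- correct_baseline_tilt(calibrate_curve(
    synth_hertz_curve(E_MPa = 5, z0 = 500, cfg = cfg), cfg))
  di <- compute_indentation(cv, cfg, 500)
  di <- di[di$force < cfg$setpoint, ]  # final sample is clamped at setpoint
  cc <- stomech:::hertz_prefactor(cfg) * 5
  expect_equal(di$force, cc * di$delta^2, tolerance = 1e-6)
  cfg_bad <- cfg
  cfg_bad$spring_constant <- -1
  expect_error(compute_indentation(cv, cfg_bad, 500), "positive")
})

test_that("the pyramidal Hertz fit round-trips the forward model", {
  cfg <- afm_config()
  cv <- correct_baseline_tilt(calibrate_curve(
    synth_hertz_curve(E_MPa = 5, z0 = 500, cfg = cfg), cfg))
  di <- compute_indentation(cv, cfg, detect_contact_point(cv))
  fit <- fit_hertz_pyramid(di, cfg)
  expect_identical(fit$flag, "ok")
  expect_equal(fit$Ea, 5, tolerance = 1e-3)
  # depth at 1000 nN on a mid-range modulus lies in the reported range
  expect_gt(fit$delta_max, 100)
  expect_lt(fit$delta_max, 1000)
  # all-zero force: bad fit
  zero <- tibble::tibble(delta = seq(1, 300, length.out = 50),
                         force = rep(0, 50))
  expect_identical(fit_hertz_pyramid(zero, cfg)$flag, "bad_fit")
})

test_that("the quadratic coefficient matches a brute-force grid search", {
  cfg <- afm_config()
  set.seed(21)
  for (i in 1:20) {
    E <- stats::runif(1, 1, 50)
    cc <- stomech:::hertz_prefactor(cfg) * E
    delta <- seq(20, 600, length.out = 80)
    force <- cc * delta^2 + stats::rnorm(80, 0, 2)
    fit <- fit_hertz_pyramid(tibble::tibble(delta = delta, force = force), cfg)
    # brute-force grid search over the coefficient
    grid <- seq(0.2 * cc, 5 * cc, length.out = 20001)
    sse <- vapply(grid, function(g) sum((force - g * delta^2)^2), numeric(1))
    c_grid <- grid[which.min(sse)]
    expect_equal(fit$Ea * stomech:::hertz_prefactor(cfg), c_grid,
                 tolerance = 1e-3)
  }
})

test_that("a uniform noise-free map is recovered within 1% at full grid size", {
  cfg <- small_afm_cfg(grid = 32)
  gt <- make_ground_truth("young", map_size = cfg$map_size,
                          E_bg = 5, E_inner = 5, E_outer = 5, E_pole = 5)
  gt$E_pole <- NA  # flat field
  gt$E_inner <- 5; gt$E_outer <- 5
  fm <- simulate_force_map(gt, cfg, silent_noise())
  em <- process_force_map(fm)
  ok <- em$flag == "ok"
  expect_gt(mean(ok), 0.99)
  expect_lt(max(abs(em$Ea[ok] - fm$E_true[ok]) / fm$E_true[ok]), 0.01)
  expect_identical(nrow(em), 32L * 32L)
})

test_that("adding a constant force offset does not change Ea", {
  cfg <- afm_config()
  base <- synth_hertz_curve(E_MPa = 8, z0 = 500, cfg = cfg)
  shifted <- base
  shifted$deflection_V <- shifted$deflection_V +
    50 / (cfg$spring_constant * cfg$sensitivity)
  fit_of <- function(cv) {
    cv <- correct_baseline_tilt(calibrate_curve(cv, cfg))
    di <- compute_indentation(cv, cfg, detect_contact_point(cv))
    fit_hertz_pyramid(di, cfg)$Ea
  }
  expect_equal(fit_of(base), fit_of(shifted), tolerance = 1e-6)
})

test_that("transects read a uniform map as flat and reject paths off the map", {
  cfg <- small_afm_cfg(grid = 32)
  gt <- make_ground_truth("young", map_size = cfg$map_size)
  fm <- simulate_force_map(gt, cfg, silent_noise())
  em <- process_force_map(fm)
  # uniform synthetic map: overwrite the grid with a constant
  attr(em, "grid")[] <- 7
  prof <- extract_transect(em, gt$pose, mode = "diameter")
  expect_lt(diff(range(prof$Ea, na.rm = TRUE)), 1e-9)
  bad_pose <- gt$pose
  bad_pose$center <- c(39, 39)
  expect_error(extract_transect(em, bad_pose, mode = "diameter"), "exits")
})

test_that("the gradient statistic behaves on constructed profiles", {
  # 4 Gaussians: outer 6 MPa at 1 um, inner 10 MPa at 2 um (cell 1),
  # mirrored for cell 2 -> per-cell gradient (10-6)/1 = 4
  pos <- seq(0, 10, by = 0.01)
  g <- function(c0, A, s = 0.15) A * exp(-(pos - c0)^2 / (2 * s^2))
  val <- 2 + g(1, 4) + g(2, 8) + g(8, 8) + g(9, 4)
  prof <- tibble::tibble(position = pos, Ea = val)
  class(prof) <- c("transect_profile", class(prof))
  gr <- gradient_statistic(prof, refine = FALSE)
  expect_identical(gr$flag, "ok")
  expect_equal(gr$gradient, 4.0, tolerance = 0.01)
  # equal-height peaks: zero gradient
  val0 <- 2 + g(1, 8) + g(2, 8) + g(8, 8) + g(9, 8)
  prof0 <- tibble::tibble(position = pos, Ea = val0)
  class(prof0) <- c("transect_profile", class(prof0))
  expect_equal(gradient_statistic(prof0, refine = FALSE)$gradient, 0,
               tolerance = 1e-9)
  # < 4 peaks: not computable
  val3 <- 2 + g(1, 8) + g(5, 8) + g(9, 8)
  prof3 <- tibble::tibble(position = pos, Ea = val3)
  class(prof3) <- c("transect_profile", class(prof3))
  expect_identical(gradient_statistic(prof3, refine = FALSE)$flag,
                   "not_computable")
  # invariance: adding a constant leaves the gradient unchanged; scaling
  # the profile scales it linearly
  prof_shift <- prof; prof_shift$Ea <- prof$Ea + 3
  expect_equal(gradient_statistic(prof_shift, refine = FALSE)$gradient,
               gr$gradient, tolerance = 1e-9)
  prof_scale <- prof; prof_scale$Ea <- prof$Ea * 2.5
  expect_equal(gradient_statistic(prof_scale, refine = FALSE)$gradient,
               2.5 * gr$gradient, tolerance = 1e-9)
})

test_that("Mann-Whitney U matches symmetry, enumeration and wilcox.test", {
  # identical samples: U = n^2 / 2
  r <- mann_whitney_u(c(1, 2, 3, 4.5), c(1, 2, 3, 4.5))
  expect_equal(r$U, 8)
  # {1,2} vs {3,4}: exact two-sided p = 2 * 1/6 = 1/3
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  # cross-check statistic and p against the stats implementation
  set.seed(31)
  for (i in 1:10) {
    # sizes > 8 so that both implementations use the normal approximation
    a <- stats::rnorm(stats::rpois(1, 6) + 9)
    b <- stats::rnorm(stats::rpois(1, 6) + 9, mean = 0.5)
    ours <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})
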