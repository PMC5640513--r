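#' AFM force-volume acquisition and analysis configuration
#'
#' Describes the cantilever, tip, acquisition grid and Hertz-fit controls
#' used both to analyze and to simulate force-volume maps. The defaults
#' mirror a typical stiff-cantilever pyramidal-tip acquisition: a nominal
#' 45 N/m cantilever, 1000 nN setpoint, 100 x 100 um maps at 128 x 128
#' points.
#'
#' @param spring_constant Cantilever spring constant k (N/m).
#' @param sensitivity Deflection sensitivity s (nm/V).
#' @param tip_half_angle Pyramid face half-angle theta (degrees).
#' @param setpoint Force setpoint (nN).
#' @param nu Sample Poisson ratio (0.5 = incompressible).
#' @param map_size Physical map side length (um).
#' @param grid_size Points per side.
#' @param fit_lower,fit_upper Hertz fit window as fractions of the maximum
#'   indentation depth.
#' @param z_pre Pre-contact approach length (nm) in simulated curves.
#' @param z_post Post-contact approach length (nm).
#' @param dz Piezo sampling step (nm).
#' @return An object of class `afm_config`.
#' @export
afm_config <- function(spring_constant = 45, sensitivity = 20,
                       tip_half_angle = 17.5, setpoint = 1000, nu = 0.5,
                       map_size = 100, grid_size = 128,
                       fit_lower = 0.1, fit_upper = 1.0,
                       z_pre = 500, z_post = 1400, dz = 5) {
  if (spring_constant <= 0 || sensitivity <= 0 || setpoint <= 0) {
    stop("spring constant, sensitivity and setpoint must be positive")
  }
  if (!(tip_half_angle > 0 && tip_half_angle < 90)) {
    stop("tip half-angle must be in (0, 90) degrees")
  }
  if (!(nu >= 0 && nu <= 0.5)) stop("Poisson ratio must be in [0, 0.5]")
  structure(list(spring_constant = spring_constant, sensitivity = sensitivity,
                 tip_half_angle = tip_half_angle, setpoint = setpoint, nu = nu,
                 map_size = map_size, grid_size = as.integer(grid_size),
                 fit_lower = fit_lower, fit_upper = fit_upper,
                 z_pre = z_pre, z_post = z_post, dz = dz),
            class = "afm_config")
}

# pyramidal Hertz prefactor: F = hertz_prefactor(cfg) * E * delta^2 with E
# in MPa, delta in nm, F in nN (the nN/nm^2 <-> GPa conversion is folded in)
hertz_prefactor <- function(cfg) {
  tan(cfg$tip_half_angle * pi / 180) / sqrt(2) / (1 - cfg$nu^2) * 1e-3
}

#' Construct a force curve
#'
#' @param z Piezo extension during the approach (nm, increasing towards the
#'   sample).
#' @param deflection_V Raw photodiode deflection (V); alternatively supply
#'   `force` directly (nN) for already-calibrated data.
#' @param force Calibrated force (nN), optional.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z, deflection_V = NULL, force = NULL) {
  if (is.null(deflection_V) && is.null(force)) {
    stop("supply deflection_V or force")
  }
  n <- length(z)
  if (any(diff(z) <= 0)) stop("approach z must be strictly increasing")
  if (!is.null(deflection_V) && length(deflection_V) != n ||
      !is.null(force) && length(force) != n) {
    stop("z and deflection arrays must have equal length")
  }
  structure(list(z = z, deflection_V = deflection_V, force = force,
                 calibrated = !is.null(force), corrected = FALSE),
            class = "force_curve")
}

#' Convert raw deflection voltages to force
#'
#' `force (nN) = deflection (V) * sensitivity (nm/V) * k (N/m)`; the
#' deflection in nm is retained alongside.
#'
#' @param curve A [force_curve()].
#' @param cfg An [afm_config()] with calibrated `sensitivity` and
#'   `spring_constant`.
#' @return The curve with `force` (nN) and `deflection_nm` filled in.
#' @export
calibrate_curve <- function(curve, cfg) {
  if (is.null(curve$deflection_V)) {
    if (!is.null(curve$force)) {
      curve$deflection_nm <- curve$force / cfg$spring_constant
      curve$calibrated <- TRUE
      return(curve)
    }
    stop("curve has no raw deflection")
  }
  if (is.null(cfg$sensitivity) || is.null(cfg$spring_constant)) {
    stop("missing calibration constants (sensitivity / spring constant)")
  }
  curve$deflection_nm <- curve$deflection_V * cfg$sensitivity
  curve$force <- curve$deflection_nm * cfg$spring_constant
  curve$calibrated <- TRUE
  curve
}

#' Remove baseline offset and tilt from the pre-contact segment
#'
#' Fits a least-squares line to the identified non-contact segment of the
#' approach and subtracts it, so the pre-contact force has zero mean and
#' slope. The pre-contact segment is found by fitting on the initial part
#' of the approach, estimating the noise level, and locating the sustained
#' contact rise.
#'
#' @param curve A calibrated [force_curve()].
#' @param init_frac Initial fraction of samples for the first baseline
#'   guess.
#' @param margin Samples backed off before the detected rise when
#'   refitting.
#' @return The corrected curve, with `noise_sd` (nN) and `contact_index`
#'   attached; `rejected = TRUE` (with a reason) if no pre-contact segment
#'   can be identified.
#' @export
correct_baseline_tilt <- function(curve, init_frac = 0.3, margin = 8) {
  if (!isTRUE(curve$calibrated)) stop("calibrate the curve first")
  z <- curve$z; f <- curve$force
  ok <- which(!is.na(f))
  n <- length(ok)
  k0 <- max(8, floor(init_frac * n))
  idx <- ok[1:k0]
  co <- stats::coef(stats::lm.fit(cbind(1, z[idx]), f[idx]))
  res <- f - (co[1] + co[2] * z)
  sdn <- stats::sd(res[idx])
  # a genuine pre-contact segment is straight: if a quadratic fits the
  # initial window far better than the line does, the tip was already in
  # contact at the first sample
  zq <- z[idx] - mean(z[idx])
  qfit <- stats::lm.fit(cbind(1, zq, zq^2), f[idx])
  sd_quad <- stats::sd(qfit$residuals)
  if (sdn > 3 * sd_quad + 1e-6 * diff(range(f[ok]))) {
    curve$rejected <- TRUE
    curve$reject_reason <- "no identifiable pre-contact region"
    return(curve)
  }
  thr <- 5 * max(sdn, 1e-9)
  above <- res[ok] > thr
  sustained <- which(above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE))
  ci <- if (length(sustained)) ok[sustained[1]] else NA_integer_
  pre_end <- if (is.na(ci)) ok[n] else max(ci - margin, 0)
  if (!is.na(ci)) {
    # the threshold crossing sits well past true contact on soft samples;
    # back-extrapolate the Hertzian rise (sqrt(F) linear in z) so the
    # baseline refit stays strictly before contact
    jend <- which(!is.na(res) & res >= 0.4 * max(res, na.rm = TRUE))[1]
    j <- seq(ci, max(jend, min(ci + 12, n), na.rm = TRUE))
    j <- j[j <= n & !is.na(res[j]) & res[j] > 0]
    if (length(j) >= 4) {
      w <- res[j]
      mz <- sum(w * z[j]) / sum(w)
      ms <- sum(w * sqrt(res[j])) / sum(w)
      b1 <- sum(w * (z[j] - mz) * (sqrt(res[j]) - ms)) /
        sum(w * (z[j] - mz)^2)
      z0_est <- mz - ms / b1
      if (is.finite(z0_est) && z0_est < z[ci] && z0_est > z[1]) {
        pre_end <- min(pre_end, max(which(z < z0_est - margin * (z[2] - z[1]))))
      }
    }
  }
  if (pre_end < ok[1] + 9) {
    curve$rejected <- TRUE
    curve$reject_reason <- "no identifiable pre-contact region"
    return(curve)
  }
  idx2 <- ok[ok <= pre_end]
  co <- stats::coef(stats::lm.fit(cbind(1, z[idx2]), f[idx2]))
  curve$force <- f - (co[1] + co[2] * z)
  curve$baseline <- c(offset = unname(co[1]), slope = unname(co[2]))
  curve$noise_sd <- stats::sd(curve$force[idx2])
  curve$contact_index <- ci
  curve$corrected <- TRUE
  curve$rejected <- FALSE
  curve
}

#' Detect the tip-sample contact point
#'
#' Threshold crossing at `c_sd` times the baseline noise standard
#' deviation, sustained over three samples, refined by fitting the local
#' Hertz-like rise `F = a (z - z0)^2` (linear least squares on
#' `sqrt(F)`) over a short window after the crossing.
#'
#' @param curve A corrected [force_curve()].
#' @param c_sd Detection threshold in units of baseline noise SD.
#' @param refine_window Minimum number of samples used for the refinement.
#' @param k Optional cantilever spring constant (N/m); when given, the
#'   cantilever bending `F/k` is removed from the piezo coordinate during
#'   the refinement, which matters once the window extends into tens of
#'   nN of force.
#' @return Contact piezo position `z0` (nm), or `NA` with attribute
#'   `"no_contact" = TRUE` if the force never rises above threshold.
#' @export
detect_contact_point <- function(curve, c_sd = 5, refine_window = 12,
                                 k = NULL) {
  if (!isTRUE(curve$corrected)) stop("run correct_baseline_tilt first")
  z <- curve$z; f <- curve$force
  ok <- !is.na(f)
  thr <- c_sd * max(curve$noise_sd %||% stats::sd(f[ok][1:20]), 1e-9)
  above <- ok & f > thr
  sustained <- which(above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE))
  if (!length(sustained)) return(structure(NA_real_, no_contact = TRUE))
  i <- sustained[1]
  # refinement window: the lower rise of the curve, where sqrt(F) is
  # linear in z for a Hertzian contact
  fmax <- max(f[ok])
  jend <- which(ok & f >= min(0.4 * fmax, 400 * thr))[1]
  j <- seq(i, max(jend, min(i + refine_window, max(which(ok)))))
  j <- j[!is.na(f[j]) & f[j] > 0]
  if (length(j) >= 4) {
    w <- f[j]
    zj <- z[j] - if (is.null(k)) 0 else f[j] / k
    sj <- sqrt(f[j])
    mz <- sum(w * zj) / sum(w); ms <- sum(w * sj) / sum(w)
    b1 <- sum(w * (zj - mz) * (sj - ms)) / sum(w * (zj - mz)^2)
    z0 <- mz - ms / b1
    # accept the refinement if it lands before the crossing and inside
    # the recorded approach
    if (is.finite(z0) && z0 < z[i] && z0 > z[1]) {
      # on an essentially noise-free curve the sqrt regression is already
      # sub-nanometre; the grid polish below only helps under real noise
      if (thr < 1e-3 * fmax) return(z0)
      # final polish: direct least squares of the quadratic contact model
      # F = c (z - z0 - F/k)^2 over a window that includes the noisy
      # sub-threshold rise, scanning z0 (optimal under force noise, where
      # the sqrt regression must extrapolate)
      dz <- z[2] - z[1]
      hi <- which(ok & f >= 0.5 * fmax)[1]
      if (is.na(hi)) hi <- max(which(ok))
      win <- seq_len(hi)
      win <- win[!is.na(f[win])]
      zw <- z[win] - if (is.null(k)) 0 else pmax(f[win], 0) / k
      fw <- f[win]
      cand <- seq(z0 - 50 * dz, min(z0 + 50 * dz, z[i]), by = dz / 4)
      sse <- vapply(cand, function(zc) {
        d2 <- pmax(zw - zc, 0)^2
        cc <- sum(fw * d2) / max(sum(d2^2), 1e-12)
        sum((fw - cc * d2)^2)
      }, numeric(1))
      b <- which.min(sse)
      if (b > 1 && b < length(cand)) {
        # parabolic sub-grid refinement of the SSE minimum
        s1 <- sse[b - 1]; s2 <- sse[b]; s3 <- sse[b + 1]
        denom <- s1 - 2 * s2 + s3
        off <- if (denom > 0) 0.5 * (s1 - s3) / denom else 0
        return(cand[b] + off * dz / 4)
      }
      return(cand[b])
    }
  }
  # fallback: linear back-extrapolation of the rise to zero force
  if (i > 1 && !is.na(f[i - 1]) && f[i] > f[i - 1]) {
    z[i - 1] - f[i - 1] * (z[i] - z[i - 1]) / (f[i] - f[i - 1])
  } else z[i]
}

#' Compute the indentation depth from a force curve
#'
#' Subtracts the cantilever bending from the piezo travel past contact:
#' `delta = (z - z0) - F/k`. Only non-negative depths are kept.
#'
#' @param curve A corrected [force_curve()].
#' @param cfg An [afm_config()].
#' @param z0 Contact point (nm), e.g. from [detect_contact_point()].
#' @return A tibble with `delta` (nm) and `force` (nN).
#' @export
compute_indentation <- function(curve, cfg, z0) {
  if (cfg$spring_constant <= 0) stop("spring constant must be positive")
  keep <- !is.na(curve$force) & curve$z > z0
  delta <- (curve$z[keep] - z0) - curve$force[keep] / cfg$spring_constant
  force <- curve$force[keep]
  sel <- delta >= 0
  tibble::tibble(delta = delta[sel], force = force[sel])
}

#' Fit the pyramidal Hertz model to indentation data
#'
#' Least-squares fit of `F = (tan(theta)/sqrt(2)) * (E_a/(1 - nu^2)) *
#' delta^2` (four-sided pyramidal indenter) over the configured depth
#' window. The fit is linear in `E_a` given the known quadratic shape.
#'
#' @param df A tibble from [compute_indentation()] (`delta` nm, `force` nN).
#' @param cfg An [afm_config()].
#' @return A list of class `hertz_fit`: `Ea` (MPa), `delta_max` (nm),
#'   `rms` (nN), `n` points used, and `flag` (`"ok"` or `"bad_fit"`).
#' @export
fit_hertz_pyramid <- function(df, cfg) {
  out <- list(Ea = NA_real_, delta_max = NA_real_, rms = NA_real_,
              n = 0L, flag = "bad_fit")
  class(out) <- "hertz_fit"
  if (nrow(df) < 10) return(out)
  dmax <- max(df$delta)
  win <- df$delta >= cfg$fit_lower * dmax & df$delta <= cfg$fit_upper * dmax
  d <- df$delta[win]; f <- df$force[win]
  if (length(d) < 10) return(out)
  chat <- sum(f * d^2) / sum(d^4)
  Ea <- chat / hertz_prefactor(cfg)
  if (!is.finite(Ea) || Ea <= 0) return(out)
  out$Ea <- Ea
  out$delta_max <- dmax
  out$rms <- sqrt(mean((f - chat * d^2)^2))
  out$n <- length(d)
  out$flag <- "ok"
  out
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> Ea = %.3g MPa (%s, n = %d, rms %.3g nN, depth %.0f nm)\n",
              x$Ea, x$flag, x$n, x$rms, x$delta_max))
  invisible(x)
}

#' Process a force-volume map into an apparent-modulus map
#'
#' Runs the per-pixel pipeline calibrate -> baseline/tilt correction ->
#' contact detection -> indentation -> pyramidal Hertz fit over every
#' approach curve of the map (retraction data are never used). Pixels
#' whose curves are rejected, never contact, saturate, or fit badly are
#' masked with a flag.
#'
#' @param fmap A `gc_force_map` (see [simulate_force_map()]) or compatible
#'   list with `z` (nm), `deflection_V` (nz x npixels), `x`, `y` pixel
#'   centers (um).
#' @param cfg An [afm_config()].
#' @return An `ea_map`: tibble with `i`, `j`, `x`, `y`, `Ea` (MPa), `z0`,
#'   `delta_max`, `rms`, `flag`, plus attributes `grid` (matrix of Ea) and
#'   `cfg`. A warning is emitted if more than half of the pixels are
#'   masked.
#' @export
process_force_map <- function(fmap, cfg = fmap$cfg) {
  z <- fmap$z
  nz <- length(z)
  V <- fmap$deflection_V
  np <- ncol(V)
  k <- cfg$spring_constant; s <- cfg$sensitivity
  F <- V * (s * k)
  pref <- hertz_prefactor(cfg)

  n0 <- max(8, floor(0.3 * nz))
  # vectorized baseline fit on the initial segment, per pixel
  zi <- z[1:n0]
  sz <- sum(zi); szz <- sum(zi^2)
  Fi <- F[1:n0, , drop = FALSE]
  sf <- colSums(Fi); sfz <- colSums(Fi * zi)
  det0 <- n0 * szz - sz^2
  slope <- (n0 * sfz - sz * sf) / det0
  offset <- (sf * szz - sz * sfz) / det0
  F <- F - outer(z, rep(1, np)) * rep(slope, each = nz) -
    rep(offset, each = nz)
  sdn <- sqrt(pmax(colSums((F[1:n0, , drop = FALSE] -
                              rep(colMeans(F[1:n0, , drop = FALSE]), each = n0))^2) /
                     (n0 - 1), 1e-18))

  Ea <- z0v <- dmx <- rms <- rep(NA_real_, np)
  flag <- character(np)
  dz <- z[2] - z[1]
  for (p in seq_len(np)) {
    f <- F[, p]
    ok <- !is.na(f)
    thr <- 5 * sdn[p]
    above <- ok & f > thr
    sus <- which(above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE))
    if (!length(sus)) { flag[p] <- "no_contact"; next }
    i <- sus[1]
    # Hertz-shape refinement of the contact point: over the lower rise of
    # the curve sqrt(F) is linear in (z - F/k), with intercept at contact.
    # A long window averages the deflection noise down to nm-level z0.
    sqrt_refine <- function(f, i) {
      jend <- which(!is.na(f) & f >= 0.4 * cfg$setpoint)[1]
      if (is.na(jend)) jend <- max(which(!is.na(f)))
      j <- seq(i, max(jend, min(i + 12, nz)))
      j <- j[!is.na(f[j]) & f[j] > 0]
      if (length(j) < 4) return(NA_real_)
      dj <- z[j] - f[j] / k
      sj <- sqrt(f[j])
      w <- f[j]
      mz <- sum(w * dj) / sum(w); ms <- sum(w * sj) / sum(w)
      b1 <- sum(w * (dj - mz) * (sj - ms)) / sum(w * (dj - mz)^2)
      mz - ms / b1
    }
    z0 <- sqrt_refine(f, i)
    if (!is.finite(z0) || z0 >= z[i] + dz || z0 <= z[10]) z0 <- z[i]
    # refit the baseline strictly before contact, then re-refine
    pre_n <- sum(z < z0 - 8 * dz)
    if (pre_n >= 10) {
      zp <- z[1:pre_n]; fp <- f[1:pre_n]
      mz <- mean(zp); mf <- mean(fp)
      b1 <- sum((zp - mz) * fp) / sum((zp - mz)^2)
      f <- f - (mf - b1 * mz) - b1 * z
      z0b <- sqrt_refine(f, i)
      if (is.finite(z0b) && z0b < z[i] + dz && z0b > z[10]) z0 <- z0b
    }
    if (max(f[ok]) < 0.95 * cfg$setpoint) { flag[p] <- "saturated"; next }
    keep <- ok & z > z0
    delta <- (z[keep] - z0) - f[keep] / k
    fr <- f[keep]
    sel <- delta >= 0
    delta <- delta[sel]; fr <- fr[sel]
    if (length(delta) < 10) { flag[p] <- "too_few_points"; next }
    dmax <- max(delta)
    win <- delta >= cfg$fit_lower * dmax & delta <= cfg$fit_upper * dmax
    d2 <- delta[win]^2
    chat <- sum(fr[win] * d2) / sum(d2^2)
    e <- chat / pref
    if (!is.finite(e) || e <= 0) { flag[p] <- "bad_fit"; next }
    Ea[p] <- e; z0v[p] <- z0; dmx[p] <- dmax
    rms[p] <- sqrt(mean((fr[win] - chat * d2)^2))
    flag[p] <- "ok"
  }
  ngrid <- fmap$grid_size %||% cfg$grid_size
  out <- tibble::tibble(
    i = rep(seq_len(ngrid), times = ngrid),
    j = rep(seq_len(ngrid), each = ngrid),
    x = fmap$x, y = fmap$y,
    Ea = Ea, z0 = z0v, delta_max = dmx, rms = rms, flag = flag
  )
  frac_masked <- mean(flag != "ok")
  if (frac_masked > 0.5) {
    warning(sprintf("%.0f%% of pixels are masked", 100 * frac_masked))
  }
  attr(out, "grid") <- matrix(Ea, nrow = ngrid)
  attr(out, "cfg") <- cfg
  attr(out, "map_size") <- fmap$map_size %||% cfg$map_size
  class(out) <- c("ea_map", class(out))
  out
}

# bilinear interpolation into the Ea grid (NA-aware: any masked corner
# propagates NA at that sample)
ea_interp <- function(eamap, xq, yq) {
  g <- attr(eamap, "grid")
  n <- nrow(g)
  L <- attr(eamap, "map_size")
  pix <- L / n
  u <- xq / pix - 0.5 + 1  # fractional pixel index (pixel centers at (k-0.5)*pix)
  v <- yq / pix - 0.5 + 1
  i0 <- floor(u); j0 <- floor(v)
  fu <- u - i0; fv <- v - j0
  get <- function(i, j) {
    out <- rep(NA_real_, length(i))
    okk <- i >= 1 & i <= n & j >= 1 & j <= n
    out[okk] <- g[cbind(i[okk], j[okk])]
    out
  }
  g00 <- get(i0, j0); g10 <- get(i0 + 1, j0)
  g01 <- get(i0, j0 + 1); g11 <- get(i0 + 1, j0 + 1)
  (1 - fu) * (1 - fv) * g00 + fu * (1 - fv) * g10 +
    (1 - fu) * fv * g01 + fu * fv * g11
}

#' Extract a stomatal transect profile from an apparent-modulus map
#'
#' `mode = "diameter"`: a straight segment through the stoma centre along
#' its short axis (across both guard cells), sampled at sub-pixel spacing
#' by bilinear interpolation and optionally averaged over a band of
#' parallel lines (which suppresses pixel-phase noise on narrow wall
#' ridges). `mode = "circumference"`: a closed elliptical path along the
#' wall annulus midline, starting at the equator.
#'
#' @param eamap An `ea_map` from [process_force_map()].
#' @param pose Stoma pose: list with `center` (um, length 2), `axes`
#'   (semi-axes of the wall midline ellipse, um), `orientation` (radians,
#'   long axis relative to map x).
#' @param mode `"diameter"` or `"circumference"`.
#' @param spacing Sample spacing along the path (um).
#' @param margin Extra length beyond the outer wall on each end of the
#'   diameter path (um).
#' @param band Half-width of the averaging band (um); 0 disables averaging.
#' @param band_step Spacing of the parallel band lines (um).
#' @return A `transect_profile` tibble: `position` (um along the path) and
#'   `Ea` (MPa), with the pose and mode as attributes.
#' @export
extract_transect <- function(eamap, pose, mode = c("diameter", "circumference"),
                             spacing = 0.1, margin = 3,
                             band = 1.5, band_step = 0.25) {
  mode <- match.arg(mode)
  L <- attr(eamap, "map_size")
  ctr <- pose$center
  th <- pose$orientation %||% 0
  e_long <- c(cos(th), sin(th)); e_short <- c(-sin(th), cos(th))
  if (mode == "diameter") {
    half <- pose$axes[2] + margin
    pos <- seq(-half, half, by = spacing)
    offs <- if (band > 0) seq(-band, band, by = band_step) else 0
    acc <- matrix(NA_real_, nrow = length(pos), ncol = length(offs))
    for (o in seq_along(offs)) {
      pts <- cbind(ctr[1] + pos * e_short[1] + offs[o] * e_long[1],
                   ctr[2] + pos * e_short[2] + offs[o] * e_long[2])
      if (any(pts < 0 | pts > L)) stop("transect path exits the map")
      acc[, o] <- ea_interp(eamap, pts[, 1], pts[, 2])
    }
    prof <- rowMeans(acc, na.rm = TRUE)
    prof[is.nan(prof)] <- NA_real_
    out <- tibble::tibble(position = pos - min(pos), Ea = prof)
  } else {
    a <- pose$axes[1]; b <- pose$axes[2]
    # equator start: the point on the short axis; walk the ellipse with
    # near-uniform arc length
    tgrid <- seq(0, 2 * pi, length.out = 4096)
    xs <- a * cos(tgrid); ys <- b * sin(tgrid)
    arc <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
    total <- arc[length(arc)]
    svals <- seq(0, total, by = spacing)
    tval <- stats::approx(arc, tgrid, xout = svals)$y
    # start at the equator (t = pi/2, the +short-axis point)
    tval <- tval + pi / 2
    px <- a * cos(tval); py <- b * sin(tval)
    pts <- cbind(ctr[1] + px * e_long[1] + py * e_short[1],
                 ctr[2] + px * e_long[2] + py * e_short[2])
    if (any(pts < 0 | pts > L)) stop("transect path exits the map")
    out <- tibble::tibble(position = svals, Ea = ea_interp(eamap, pts[, 1], pts[, 2]))
  }
  if (any(diff(out$position) <= 0)) stop("positions must be strictly increasing")
  attr(out, "mode") <- mode
  attr(out, "pose") <- pose
  attr(out, "eamap") <- eamap
  class(out) <- c("transect_profile", class(out))
  out
}

# simple 1D peak detection: local maxima with a prominence and separation
# criterion (prominence relative to the profile range)
find_profile_peaks <- function(pos, val, prominence_frac = 0.1, min_sep = 0.5) {
  ok <- !is.na(val)
  # close NA holes by linear interpolation for detection purposes
  v <- val
  if (any(!ok) && sum(ok) > 2) {
    v[!ok] <- stats::approx(pos[ok], val[ok], xout = pos[!ok], rule = 2)$y
  }
  n <- length(v)
  cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1
  if (!length(cand)) return(integer(0))
  rng <- diff(range(v))
  prom <- vapply(cand, function(i) {
    # prominence: drop to the highest of the two bounding minima, scanning
    # out to the nearest higher point on each side
    left_min <- min(v[cummaxrev_ge(v[1:i], v[i])])
    right_min <- min(v[(i - 1) + cummax_ge(v[i:n], v[i])])
    v[i] - max(left_min, right_min)
  }, numeric(1))
  keep <- cand[prom >= prominence_frac * rng]
  # enforce minimum separation, keeping the higher peak
  if (length(keep) > 1) {
    ordv <- keep[order(v[keep], decreasing = TRUE)]
    sel <- integer(0)
    for (i in ordv) {
      if (!length(sel) || all(abs(pos[i] - pos[sel]) >= min_sep)) sel <- c(sel, i)
    }
    keep <- sort(sel)
  }
  keep
}

# helpers for prominence: indices from the peak to the first higher value
cummax_ge <- function(v, ref) {
  higher <- which(v > ref)
  if (length(higher)) seq_len(min(higher) - 1) else seq_along(v)
}
cummaxrev_ge <- function(v, ref) {
  n <- length(v)
  higher <- which(v > ref)
  if (length(higher)) (max(higher) + 1):n else seq_len(n)
}

# model-based refinement of a wall-ridge peak using the raw map pixels in
# an oriented rectangle around the detected peak: the pixel values are
# exact point samples of the modulus field, so fitting a Gaussian ridge
# cross-profile recovers the crest height even when the ridge is narrower
# than the pixel pitch.
refine_peak_2d <- function(eamap, point, dir, half_len = 0.7, half_wid = 1.5,
                           fallback_height = NA_real_, fallback_pos = 0) {
  g <- attr(eamap, "grid")
  n <- nrow(g); L <- attr(eamap, "map_size"); pix <- L / n
  xs <- (seq_len(n) - 0.5) * pix
  ix <- which(abs(xs - point[1]) <= half_len + half_wid + pix)
  iy <- which(abs(xs - point[2]) <= half_len + half_wid + pix)
  if (!length(ix) || !length(iy)) {
    return(list(height = fallback_height, offset = fallback_pos, ok = FALSE))
  }
  px <- rep(xs[ix], times = length(iy))
  py <- rep(xs[iy], each = length(ix))
  u <- (px - point[1]) * dir[1] + (py - point[2]) * dir[2]
  v <- -(px - point[1]) * dir[2] + (py - point[2]) * dir[1]
  val <- as.vector(g[ix, iy, drop = FALSE])
  sel <- abs(u) <= half_len & abs(v) <= half_wid & !is.na(val)
  if (sum(sel) < 6) {
    return(list(height = fallback_height, offset = fallback_pos, ok = FALSE))
  }
  u <- u[sel]; val <- val[sel]
  # the fit needs genuine cross-ridge phase coverage; an axis-aligned
  # stoma yields only a handful of distinct offsets and a degenerate fit
  if (length(unique(round(u, 2))) < 6) {
    return(list(height = fallback_height, offset = fallback_pos, ok = FALSE))
  }
  b0 <- min(val); A0 <- max(val) - b0
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    val ~ b + A * exp(-(u - u0)^2 / (2 * s^2)),
    start = list(b = b0, A = max(A0, 1e-3), u0 = 0, s = 0.35),
    lower = c(0, 0, -half_len, 0.08), upper = c(Inf, Inf, half_len, 3),
    control = minpack.lm::nls.lm.control(maxiter = 100))), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(height = fallback_height, offset = fallback_pos, ok = FALSE))
  }
  cf <- stats::coef(fit)
  height <- unname(cf["b"] + cf["A"])
  # reject implausible fits (crest far above any sample, or collapsed
  # ridge width at the parameter bound)
  if (!is.finite(height) || height > 1.6 * max(val) || cf["s"] <= 0.09) {
    return(list(height = fallback_height, offset = fallback_pos, ok = FALSE))
  }
  list(height = height, offset = unname(cf["u0"]), ok = TRUE)
}

#' Radial stiffness-gradient statistic of a diameter transect
#'
#' Detects the four wall peaks along the diameter profile (outer, inner,
#' inner, outer), computes per guard cell the difference between the
#' maximum apparent modulus of the inner and the outer radial wall divided
#' by the distance between the two peaks, and returns the mean of the two
#' guard cells as the per-stoma gradient. Peak heights and positions are
#' refined against the underlying map with a Gaussian ridge fit
#' when the map is available (sub-pixel wall ridges are otherwise
#' attenuated by the finite pixel pitch).
#'
#' @param profile A diameter `transect_profile`.
#' @param prominence_frac,min_sep Peak detection controls (fraction of the
#'   profile range; minimum peak separation in um).
#' @param refine Use the 2D map-based Gaussian ridge refinement?
#' @return A list of class `gc_gradient`: `gradient` (MPa/um, `NA` when not
#'   computable), per-cell components, the detected peak table and a flag.
#' @export
gradient_statistic <- function(profile, prominence_frac = 0.1, min_sep = 0.5,
                               refine = TRUE) {
  pos <- profile$position; val <- profile$Ea
  pk <- find_profile_peaks(pos, val, prominence_frac, min_sep)
  out <- list(gradient = NA_real_, per_cell = c(NA_real_, NA_real_),
              n_peaks = length(pk), peaks = NULL, flag = "not_computable")
  class(out) <- "gc_gradient"
  if (length(pk) < 4) return(out)
  # central 4 peaks around the profile midline: outer-inner-inner-outer
  mid <- (max(pos) + min(pos)) / 2
  if (length(pk) > 4) {
    below <- pk[pos[pk] < mid]; above <- pk[pos[pk] >= mid]
    if (length(below) < 2 || length(above) < 2) return(out)
    pk <- c(utils::tail(sort(below), 2), utils::head(sort(above), 2))
  }
  pk <- sort(pk)
  ppos <- pos[pk]; pval <- val[pk]
  if (refine && !is.null(attr(profile, "eamap"))) {
    eamap <- attr(profile, "eamap")
    pose <- attr(profile, "pose")
    th <- pose$orientation %||% 0
    e_short <- c(-sin(th), cos(th))
    half <- pose$axes[2] + 3
    for (q in seq_along(pk)) {
      pt <- pose$center + (ppos[q] - half) * e_short
      rf <- refine_peak_2d(eamap, pt, e_short,
                           fallback_height = pval[q], fallback_pos = 0)
      if (isTRUE(rf$ok)) {
        pval[q] <- rf$height
        ppos[q] <- ppos[q] + rf$offset
      }
    }
  }
  peaks <- tibble::tibble(position = ppos, Ea = pval,
                          wall = c("outer", "inner", "inner", "outer"))
  g1 <- (pval[2] - pval[1]) / abs(ppos[2] - ppos[1])
  g2 <- (pval[3] - pval[4]) / abs(ppos[4] - ppos[3])
  out$gradient <- mean(c(g1, g2))
  out$per_cell <- c(g1, g2)
  out$peaks <- peaks
  out$flag <- "ok"
  out
}

#' @export
print.gc_gradient <- function(x, ...) {
  if (x$flag == "ok") {
    cat(sprintf("<gc_gradient> %.3g MPa/um (cells: %.3g / %.3g)\n",
                x$gradient, x$per_cell[1], x$per_cell[2]))
  } else {
    cat(sprintf("<gc_gradient> %s (%d peaks found)\n", x$flag, x$n_peaks))
  }
  invisible(x)
}

#' Mann-Whitney U rank-sum test
#'
#' U statistic for the first sample with a two-sided p value: exact null
#' distribution when both samples are small and untied, otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param sample_a,sample_b Numeric samples.
#' @param exact_max Use the exact distribution when `min(n) <= exact_max`
#'   and there are no ties.
#' @return A list of class `mw_test`: `U`, `p_value`, `method`, sample
#'   sizes.
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact_max = 8) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 1 || nb < 1) stop("both samples must be non-empty")
  all_v <- c(sample_a, sample_b)
  r <- rank(all_v)
  Ra <- sum(r[seq_len(na)])
  U <- Ra - na * (na + 1) / 2
  ties <- any(duplicated(all_v))
  if (!ties && min(na, nb) <= exact_max) {
    # exact null distribution of U (Wilcoxon rank-sum count distribution)
    p <- 2 * min(stats::pwilcox(U, na, nb),
                 1 - stats::pwilcox(U - 1, na, nb))
    p <- min(p, 1)
    method <- "exact"
  } else {
    n <- na + nb
    tt <- table(all_v)
    tie_term <- sum(tt^3 - tt) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    mu <- na * nb / 2
    zstat <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(zstat))
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(U = U, p_value = p, method = method, n = c(na, nb)),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %g, p = %.3g (%s; n = %d, %d)\n",
              x$U, x$p_value, x$method, x$n[1], x$n[2]))
  invisible(x)
}
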