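#' Ground-truth stiffness pattern of a stomatal complex
#'
#' A 2D apparent-modulus field emulating the stiffness patterns of
#' stomata at three developmental stages, used to manufacture force-volume
#' maps with known truth:
#' * `mature`: wall ridges along the stomatal annulus with the inner
#'   (ventral) ridge stiffer than the outer, plus two polar caps;
#' * `young`: inner and outer ridges of equal stiffness, polar caps
#'   present;
#' * `gmc`: a guard mother cell - outline ring plus a central dividing
#'   wall, three crossings of equal stiffness along the diameter, no polar
#'   caps.
#'
#' Ridges are narrow Gaussian crests (sub-micrometre walls); overlapping
#' features combine by maximum so crest values equal the preset moduli
#' exactly. Preset moduli are chosen such that the pipeline-recovered
#' per-stoma gradient has true value `(E_inner - E_outer) / separation`
#' (4 MPa/um for the mature preset, 0 for young).
#'
#' @param stage `"mature"`, `"young"` or `"gmc"`.
#' @param pose List with `center` (um), `axes` (wall-midline semi-axes,
#'   um), `orientation` (radians). Defaults to a stage-typical stoma at
#'   the map centre.
#' @param E_bg,E_inner,E_outer,E_pole Moduli (MPa); stage presets used
#'   when `NULL`.
#' @param ridge_sd Gaussian ridge cross-profile SD (um).
#' @param separation Inner-outer crest separation (um).
#' @param pole_sd Polar cap SD (um).
#' @param map_size Field extent (um).
#' @return An object of class `gc_ground_truth`.
#' @export
make_ground_truth <- function(stage = c("mature", "young", "gmc"),
                              pose = NULL, E_bg = 2,
                              E_inner = NULL, E_outer = NULL, E_pole = NULL,
                              ridge_sd = 0.25, separation = 1.0,
                              pole_sd = 1.2, map_size = 100) {
  stage <- match.arg(stage)
  preset <- switch(stage,
    mature = list(E_inner = 10, E_outer = 6, E_pole = 12,
                  axes = c(12, 6.5)),
    young = list(E_inner = 8, E_outer = 8, E_pole = 12,
                 axes = c(6, 5.5)),
    gmc = list(E_inner = 8, E_outer = 8, E_pole = NA,
               axes = c(5, 4.5))
  )
  if (is.null(E_inner)) E_inner <- preset$E_inner
  if (is.null(E_outer)) E_outer <- preset$E_outer
  if (is.null(E_pole)) E_pole <- preset$E_pole
  if (is.null(pose)) {
    pose <- list(center = c(map_size / 2, map_size / 2),
                 axes = preset$axes, orientation = 0)
  }
  stopifnot(E_bg > 0, E_inner > 0, E_outer > 0)
  if (stage == "mature" && !(E_inner > E_outer)) {
    stop("mature preset requires E_inner > E_outer")
  }
  if (stage == "young" && E_inner != E_outer) {
    stop("young preset requires E_inner == E_outer")
  }
  ext <- pose$axes[1] + separation + 4 * pole_sd
  if (any(pose$center - ext < 0) || any(pose$center + ext > map_size)) {
    stop("stoma (plus its polar caps) does not fit inside the field")
  }
  structure(list(stage = stage, pose = pose, E_bg = E_bg,
                 E_inner = E_inner, E_outer = E_outer, E_pole = E_pole,
                 ridge_sd = ridge_sd, separation = separation,
                 pole_sd = pole_sd, map_size = map_size),
            class = "gc_ground_truth")
}

# approximate Euclidean distance to an ellipse of semi-axes (a, b) in the
# stoma frame: (rho - 1) / |grad rho| with rho the normalized radius
ellipse_distance <- function(u, v, a, b) {
  rho <- sqrt((u / a)^2 + (v / b)^2)
  gr <- sqrt((u / a^2)^2 + (v / b^2)^2) / pmax(rho, 1e-9)
  (rho - 1) / pmax(gr, 1e-9)
}

#' Evaluate a ground-truth modulus field
#'
#' @param gt A [make_ground_truth()] object.
#' @param x,y Map coordinates (um), vectors of equal length.
#' @return Modulus values (MPa).
#' @export
eval_modulus <- function(gt, x, y) {
  th <- gt$pose$orientation %||% 0
  u <- (x - gt$pose$center[1]) * cos(th) + (y - gt$pose$center[2]) * sin(th)
  v <- -(x - gt$pose$center[1]) * sin(th) + (y - gt$pose$center[2]) * cos(th)
  a <- gt$pose$axes[1]; b <- gt$pose$axes[2]
  s2 <- 2 * gt$ridge_sd^2
  E <- rep(gt$E_bg, length(x))
  if (gt$stage == "gmc") {
    d_out <- ellipse_distance(u, v, a, b)
    E <- pmax(E, gt$E_bg + (gt$E_outer - gt$E_bg) * exp(-d_out^2 / s2))
    # central dividing wall along the long axis
    d_mid <- ifelse(abs(u) <= 0.8 * a, abs(v),
                    sqrt((abs(u) - 0.8 * a)^2 + v^2))
    E <- pmax(E, gt$E_bg + (gt$E_inner - gt$E_bg) * exp(-d_mid^2 / s2))
  } else {
    h <- gt$separation / 2
    d_in <- ellipse_distance(u, v, a - h, b - h)
    d_out <- ellipse_distance(u, v, a + h, b + h)
    E <- pmax(E, gt$E_bg + (gt$E_inner - gt$E_bg) * exp(-d_in^2 / s2))
    E <- pmax(E, gt$E_bg + (gt$E_outer - gt$E_bg) * exp(-d_out^2 / s2))
    if (is.finite(gt$E_pole)) {
      s2p <- 2 * gt$pole_sd^2
      for (sgn in c(-1, 1)) {
        dp2 <- (u - sgn * a)^2 + v^2
        E <- pmax(E, gt$E_bg + (gt$E_pole - gt$E_bg) * exp(-dp2 / s2p))
      }
    }
  }
  E
}

#' Acquisition noise model for synthetic force maps
#'
#' @param deflection_sd Deflection noise SD as a fraction of the setpoint
#'   force.
#' @param contact_jitter Contact-point jitter SD (nm).
#' @param tilt_sd SD of the random baseline tilt slope (nN/nm).
#' @param offset_sd SD of the random baseline force offset (nN).
#' @param modulus_jitter Relative SD of per-pixel modulus jitter.
#' @param seed Mandatory RNG seed: identical seeds give identical maps.
#' @return An object of class `afm_noise_model`.
#' @export
noise_model <- function(deflection_sd = 0.01, contact_jitter = 5,
                        tilt_sd = 0.01, offset_sd = 5,
                        modulus_jitter = 0.02, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  stopifnot(deflection_sd >= 0, contact_jitter >= 0, tilt_sd >= 0,
            offset_sd >= 0, modulus_jitter >= 0)
  structure(list(deflection_sd = deflection_sd, contact_jitter = contact_jitter,
                 tilt_sd = tilt_sd, offset_sd = offset_sd,
                 modulus_jitter = modulus_jitter, seed = as.integer(seed)),
            class = "afm_noise_model")
}

#' Simulate a force-volume map from a ground-truth stiffness field
#'
#' Per pixel, generates an approach curve from the pyramidal Hertz forward
#' model at the local modulus: the observed deflection solves
#' `delta + F/k = z - z0` with `F = c(E) delta^2`, the curve stops at the
#' setpoint, and baseline tilt/offset, deflection noise, contact-point
#' jitter and per-pixel modulus jitter are added per the noise model.
#' Deterministic given the seed.
#'
#' @param gt A [make_ground_truth()] field.
#' @param cfg An [afm_config()].
#' @param noise An [noise_model()].
#' @return A `gc_force_map`: list with `z` (nm), `deflection_V`
#'   (nz x npixels), pixel centers `x`, `y` (um), per-pixel `E_true`,
#'   `saturated` flags, the generating objects and seed.
#' @export
simulate_force_map <- function(gt, cfg = afm_config(), noise) {
  stopifnot(inherits(gt, "gc_ground_truth"), inherits(noise, "afm_noise_model"))
  if (gt$map_size != cfg$map_size) stop("field does not cover the map area")
  set.seed(noise$seed)
  n <- cfg$grid_size
  pix <- cfg$map_size / n
  xs <- (seq_len(n) - 0.5) * pix
  xc <- rep(xs, times = n)
  yc <- rep(xs, each = n)
  np <- n * n
  E <- eval_modulus(gt, xc, yc)
  if (noise$modulus_jitter > 0) {
    E <- E * exp(stats::rnorm(np, 0, noise$modulus_jitter))
  }
  z <- seq(0, cfg$z_pre + cfg$z_post, by = cfg$dz)
  nz <- length(z)
  z0 <- cfg$z_pre + stats::rnorm(np, 0, noise$contact_jitter)
  cc <- hertz_prefactor(cfg) * E            # nN / nm^2
  k <- cfg$spring_constant
  # delta(z): positive root of (c/k) delta^2 + delta - (z - z0) = 0
  Zmat <- matrix(z, nrow = nz, ncol = np)
  zz <- sweep(Zmat, 2, z0)
  zz[zz < 0] <- 0
  ck <- rep(cc / k, each = nz)
  delta <- (-1 + sqrt(1 + 4 * ck * zz)) / (2 * ck)
  Ftrue <- rep(cc, each = nz) * delta^2
  # truncate at setpoint; pixels that never reach it are saturated.
  # F is monotone in z per pixel, so the first sample at/after the
  # setpoint is nz - (count below) + ... a plain column count.
  below <- Ftrue < cfg$setpoint
  nbelow <- colSums(below)
  sat <- nbelow == nz
  reached <- !below
  Ftrue[reached] <- NA_real_
  keep_one <- which(!sat)
  Ftrue[cbind(nbelow[keep_one] + 1L, keep_one)] <- cfg$setpoint
  tilt <- stats::rnorm(np, 0, noise$tilt_sd)
  offset <- stats::rnorm(np, 0, noise$offset_sd)
  Fobs <- Ftrue + rep(tilt, each = nz) * Zmat + rep(offset, each = nz) +
    matrix(stats::rnorm(nz * np, 0, noise$deflection_sd * cfg$setpoint),
           nrow = nz)
  Fobs[is.na(Ftrue)] <- NA_real_
  structure(list(z = z, deflection_V = Fobs / (k * cfg$sensitivity),
                 x = xc, y = yc, E_true = E, saturated = sat,
                 grid_size = n, map_size = cfg$map_size,
                 cfg = cfg, gt = gt, noise = noise, seed = noise$seed),
            class = "gc_force_map")
}

#' @export
print.gc_force_map <- function(x, ...) {
  cat(sprintf("<gc_force_map> %dx%d pixels over %g x %g um (%s stage, seed %d)\n",
              x$grid_size, x$grid_size, x$map_size, x$map_size,
              x$gt$stage, x$seed))
  cat(sprintf("  %d saturated pixels; %d z samples per curve\n",
              sum(x$saturated), length(x$z)))
  invisible(x)
}

#' Extract one pixel of a force map as a force curve
#'
#' @param fmap A `gc_force_map`.
#' @param i,j Pixel indices.
#' @return A [force_curve()].
#' @export
map_pixel_curve <- function(fmap, i, j) {
  p <- (j - 1) * fmap$grid_size + i
  force_curve(fmap$z, deflection_V = fmap$deflection_V[, p])
}

#' Write / read a force curve as CSV
#' @param curve A [force_curve()].
#' @param path File path.
#' @export
write_force_curve_csv <- function(curve, path) {
  df <- data.frame(z_nm = curve$z)
  if (!is.null(curve$deflection_V)) df$deflection_V <- curve$deflection_V
  if (!is.null(curve$force)) df$force_nN <- curve$force
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_curve_csv
#' @export
read_force_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  force_curve(df$z_nm, deflection_V = df$deflection_V,
              force = df$force_nN)
}

#' Write an apparent-modulus map as CSV
#' @param eamap An `ea_map`.
#' @param path File path.
#' @export
write_ea_map_csv <- function(eamap, path) {
  utils::write.csv(as.data.frame(eamap), path, row.names = FALSE)
  invisible(path)
}
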