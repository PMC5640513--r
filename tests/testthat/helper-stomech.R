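# shared fixtures, built once per test run on first use

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small guard-cell mesh for geometry/solver unit tests
small_mesh <- function() fixture("small_mesh", function() {
  build_geometry(geometry_params(mesh_resolution = 300))
})

test_material <- function() material_params()

# a quick low-resolution baseline solve shared by observables tests
small_solution <- function() fixture("small_solution", function() {
  solve_quasistatic(small_mesh(), test_material(),
                    load_protocol(steps = 12, P_gc_max = 3))
})

# noiseless acquisition for round-trip tests
silent_noise <- function(seed = 1) {
  noise_model(deflection_sd = 0, contact_jitter = 0, tilt_sd = 0,
              offset_sd = 0, modulus_jitter = 0, seed = seed)
}

# small synthetic map configuration (per-stoma field, reduced grid)
small_afm_cfg <- function(grid = 64, size = 40) {
  afm_config(map_size = size, grid_size = grid)
}

# random deformation gradient with positive determinant
random_F <- function(scale = 0.1) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, sd = scale), 3)
    if (det(F) > 0.3) return(F)
  }
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# noiseless synthetic Hertz approach curve with known contact point
synth_hertz_curve <- function(E_MPa = 5, z0 = 500, cfg = afm_config(),
                              noise_sd = 0, seed = NULL,
                              tilt = 0, offset = 0) {
  if (!is.null(seed)) set.seed(seed)
  z <- seq(0, cfg$z_pre + cfg$z_post, by = cfg$dz)
  cc <- stomech:::hertz_prefactor(cfg) * E_MPa
  k <- cfg$spring_constant
  zz <- pmax(z - z0, 0)
  ck <- cc / k
  delta <- (-1 + sqrt(1 + 4 * ck * zz)) / (2 * ck)
  Ftrue <- cc * delta^2
  cut <- which(Ftrue >= cfg$setpoint)[1]
  if (!is.na(cut)) {
    Ftrue[cut] <- cfg$setpoint
    if (cut < length(z)) Ftrue[(cut + 1):length(z)] <- NA
  }
  Fobs <- Ftrue + tilt * z + offset +
    if (noise_sd > 0) stats::rnorm(length(z), 0, noise_sd) else 0
  force_curve(z, deflection_V = Fobs / (k * cfg$sensitivity))
}
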