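#' Transversely isotropic Veronda-Westmann wall material
#'
#' Parameters of the guard-cell wall constitutive model: an isotropic
#' Veronda-Westmann matrix (exponential first-invariant term minus a linear
#' second-invariant term) reinforced by a single circumferential fiber
#' family representing the cellulose microfibrils, plus a volumetric
#' penalty enforcing near-incompressibility. The fiber family carries no
#' compression; in tension it follows an exponential toe up to the
#' straightening stretch `lambda_star` and is linear with modulus `C5`
#' beyond it, with the continuity constant solved, not configured.
#'
#' The shipped defaults are calibration values chosen so that the baseline
#' guard-cell model reproduces the qualitative aperture-pressure landmarks
#' (opening near 1.3 MPa, saturation above 5 MPa); they are not wall
#' measurements.
#'
#' @param C1 Matrix exponential scale (MPa).
#' @param C2 Matrix exponent (dimensionless).
#' @param C3 Fiber toe scale (MPa).
#' @param C4 Fiber toe exponent (dimensionless).
#' @param C5 Fiber linear modulus (MPa).
#' @param lambda_star Fiber straightening stretch (>= 1).
#' @param K_bulk Volumetric penalty modulus (MPa); defaults to `50 * C1`.
#' @return An object of class `gc_material_params`.
#' @export
material_params <- function(C1 = 2.5, C2 = 1.2, C3 = 3.0, C4 = 5.0,
                            C5 = 600, lambda_star = 1.05,
                            K_bulk = 50 * C1) {
  if (C1 <= 0 || K_bulk <= 0) stop("C1 and K_bulk must be positive")
  if (C2 <= 0 || C4 <= 0) stop("C2 and C4 must be positive")
  if (C3 < 0 || C5 < 0) stop("C3 and C5 must be non-negative")
  if (lambda_star < 1) stop("lambda_star must be >= 1")
  p <- list(C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5,
            lambda_star = lambda_star, K_bulk = K_bulk)
  # continuity constant of the linear fiber branch, solved at lambda_star
  p$C6 <- C3 * (exp(C4 * (lambda_star - 1)) - 1) - C5 * lambda_star
  class(p) <- "gc_material_params"
  p
}

#' Read material parameters from a YAML config file
#' @param path Path to a flat YAML file with keys matching [material_params()].
#' @export
read_material_config <- function(path) {
  cfg <- yaml_read_flat(path)
  do.call(material_params, cfg)
}

#' Kinematic invariants of a deformation state
#'
#' Computes the isochoric (deviatoric) invariants `I1 = tr(Cbar)` and
#' `I2 = (tr(Cbar)^2 - tr(Cbar^2))/2` of the deviatoric right Cauchy-Green
#' tensor `Cbar = J^(-2/3) F'F`, the fiber stretch `lambda = |F a0|`
#' (computed on the full deformation, fibers are not split), and the volume
#' ratio `J = det F`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param a0 Unit reference fiber direction.
#' @return A list with `I1`, `I2`, `lambda`, `J`.
#' @export
strain_invariants <- function(F, a0) {
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("inverted-element: det(F) <= 0", call. = FALSE)
  }
  if (abs(sqrt(sum(a0^2)) - 1) > 1e-8) stop("a0 must be a unit vector")
  C <- crossprod(F)
  Cb <- J^(-2 / 3) * C
  I1 <- sum(diag(Cb))
  I2 <- 0.5 * (I1^2 - sum(Cb * Cb))
  lambda <- sqrt(drop(crossprod(a0, C %*% a0)))
  list(I1 = I1, I2 = I2, lambda = lambda, J = J)
}

#' Construct a deformation state
#'
#' @param F 3x3 deformation gradient.
#' @param a0 Unit reference fiber direction.
#' @return An object of class `deformation_state` carrying `F`, `a0` and
#'   the invariants of [strain_invariants()].
#' @export
deformation_state <- function(F, a0 = c(1, 0, 0)) {
  inv <- strain_invariants(F, a0)
  structure(c(list(F = F, a0 = a0), inv), class = "deformation_state")
}

# fiber force lambda * dWf/dlambda, the FEBio-style piecewise law:
# 0 below lambda = 1, exponential toe, then linear with solved constant.
fiber_force <- function(lambda, p) {
  ifelse(lambda <= 1, 0,
         ifelse(lambda < p$lambda_star,
                p$C3 * (exp(p$C4 * (lambda - 1)) - 1),
                p$C5 * lambda + p$C6))
}

# fiber strain energy, closed form via the exponential integral Ei
fiber_energy <- function(lambda, p) {
  if (p$C3 == 0 && p$C5 == 0) return(rep(0, length(lambda)))
  toe_energy <- function(l) {
    # integral from 1 to l of C3 (exp(C4 (t-1)) - 1)/t dt
    p$C3 * exp(-p$C4) * (pracma::expint_Ei(p$C4 * l) - pracma::expint_Ei(p$C4)) -
      p$C3 * log(l)
  }
  ls <- p$lambda_star
  out <- numeric(length(lambda))
  toe <- lambda > 1 & lambda < ls
  lin <- lambda >= ls & ls > 1
  out[toe] <- toe_energy(lambda[toe])
  if (any(lin)) {
    W_star <- if (ls > 1) toe_energy(ls) else 0
    out[lin] <- W_star + p$C5 * (lambda[lin] - ls) + p$C6 * log(lambda[lin] / ls)
  }
  if (ls == 1) { # purely linear branch from the start
    above <- lambda >= 1
    out[above] <- p$C5 * (lambda[above] - 1) + p$C6 * log(lambda[above])
  }
  out
}

#' Strain-energy density of the wall material
#'
#' `W = C1 (exp(C2 (I1 - 3)) - 1) - (C1 C2 / 2) (I2 - 3) + W_fiber(lambda)
#'  + (K_bulk / 2) (ln J)^2`, with the deviatoric invariants of
#' [strain_invariants()] and the piecewise fiber law (zero in compression,
#' exponential toe, linear beyond the straightening stretch).
#'
#' @param state A `deformation_state` (or a 3x3 `F`, with `a0` supplied).
#' @param params A [material_params()] object.
#' @param a0 Fiber direction, used when `state` is a bare matrix.
#' @return Energy density in MPa.
#' @export
strain_energy <- function(state, params, a0 = c(1, 0, 0)) {
  if (is.matrix(state)) state <- deformation_state(state, a0)
  W_mat <- params$C1 * (exp(params$C2 * (state$I1 - 3)) - 1) -
    (params$C1 * params$C2 / 2) * (state$I2 - 3)
  W_vol <- (params$K_bulk / 2) * log(state$J)^2
  W_mat + fiber_energy(state$lambda, params) + W_vol
}

#' Cauchy stress of the wall material
#'
#' Analytic push-forward `sigma = (2/J) F (dW/dC) F'` of the strain-energy
#' derivative; symmetric and zero at the identity.
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress (MPa).
#' @export
cauchy_stress <- function(state, params, a0 = c(1, 0, 0)) {
  if (is.matrix(state)) state <- deformation_state(state, a0)
  F <- state$F
  J <- state$J
  C <- crossprod(F)
  Ci <- solve(C)
  I <- diag(3)
  trC <- sum(diag(C))
  I2C <- 0.5 * (trC^2 - sum(C * C))
  W1 <- params$C1 * params$C2 * exp(params$C2 * (state$I1 - 3))
  W2 <- -params$C1 * params$C2 / 2
  # d(I1bar)/dC and d(I2bar)/dC with I1bar = J^(-2/3) trC etc.
  dI1 <- J^(-2 / 3) * (I - (trC / 3) * Ci)
  dI2 <- J^(-4 / 3) * ((trC * I - C) - (2 / 3) * I2C * Ci)
  dWdC <- W1 * dI1 + W2 * dI2
  if (state$lambda > 1) {
    dWf <- fiber_force(state$lambda, params) / state$lambda # dWf/dlambda
    dWdC <- dWdC + (dWf / (2 * state$lambda)) * tcrossprod(state$a0)
  }
  dWdC <- dWdC + (params$K_bulk * log(J) / 2) * Ci
  sig <- (2 / J) * F %*% dWdC %*% t(F)
  (sig + t(sig)) / 2
}
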