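#' Stomatal dimensions of a solved load step
#'
#' Aperture is the minimum transverse (`y`) gap between the two deformed
#' ventral walls on the equatorial ring; complex length is the long-axis
#' (`x`) extent over all deformed nodes; pore length is the `x` extent of
#' the deformed pore lip. All invariant under rigid translation of the
#' solution.
#'
#' @param solution A `gc_solution`.
#' @param step Load-step index (0 = undeformed reference).
#' @return A named list with `aperture`, `complex_length`, `pore_length` (um).
#' @export
measure_dimensions <- function(solution, step) {
  if (step > 0 && !solution$steps$converged[step]) {
    stop("refusing to measure a non-converged state (step ", step, ")")
  }
  x <- solution$coords[[step + 1]]
  mesh <- solution$mesh
  ring <- mesh$node_sets$equatorial_ring
  r1 <- ring[mesh$node_cell[ring] == 1]
  r2 <- ring[mesh$node_cell[ring] == 2]
  aperture <- min(x[r1, 2]) - max(x[r2, 2])
  lip <- mesh$node_sets$pore_lip
  list(aperture = aperture,
       complex_length = diff(range(x[, 1])),
       pore_length = diff(range(x[lip, 1])))
}

#' Aperture-pressure curve of a solution
#'
#' @param solution A `gc_solution`.
#' @return A tibble over load steps: `P_gc`, `P_epi`, `aperture`,
#'   `complex_length`, `pore_length` (the undeformed state is step 0).
#' @export
aperture_curve <- function(solution) {
  steps <- c(0, seq_len(nrow(solution$steps)))
  dims <- purrr::map(steps, function(s) measure_dimensions(solution, s))
  tibble::tibble(
    step = steps,
    P_gc = c(0, solution$steps$P_gc),
    P_epi = c(0, solution$steps$P_epi),
    aperture = purrr::map_dbl(dims, "aperture"),
    complex_length = purrr::map_dbl(dims, "complex_length"),
    pore_length = purrr::map_dbl(dims, "pore_length")
  )
}

#' Turgor pressure at which the aperture starts to increase
#'
#' The opening threshold is the smallest guard-cell turgor at which the
#' aperture exceeds its value at the end of the co-ramp phase (where the
#' epidermal pressure stops rising) by `epsilon`, linearly interpolated
#' between load steps. By default `epsilon` is 1% of the total aperture
#' gain over the curve.
#'
#' @param curve A tibble as returned by [aperture_curve()] (columns `P_gc`,
#'   `P_epi`, `aperture`).
#' @param epsilon Aperture increase (um) defining "starts to increase";
#'   `NULL` for the 1%-of-gain default.
#' @return Threshold pressure (MPa), or `NA` with attribute
#'   `"no_opening" = TRUE` if the aperture never exceeds the threshold.
#' @export
opening_threshold <- function(curve, epsilon = NULL) {
  if (nrow(curve) == 0) stop("empty aperture curve")
  co_end <- if (any(curve$P_epi < max(curve$P_epi))) {
    max(which(curve$P_epi >= max(curve$P_epi))[1], 1)
  } else 1
  a0 <- curve$aperture[co_end]
  gain <- max(curve$aperture) - a0
  if (is.null(epsilon)) epsilon <- 0.01 * gain
  target <- a0 + epsilon
  after <- curve[curve$P_gc >= curve$P_gc[co_end], , drop = FALSE]
  above <- which(after$aperture > target)
  above <- above[above > 1 | length(above) == nrow(after)]
  if (gain <= 0 || length(above) == 0) {
    return(structure(NA_real_, no_opening = TRUE))
  }
  i <- above[1]
  if (i == 1) return(after$P_gc[1])
  p1 <- after$P_gc[i - 1]; p2 <- after$P_gc[i]
  a1 <- after$aperture[i - 1]; a2 <- after$aperture[i]
  p1 + (target - a1) / (a2 - a1) * (p2 - p1)
}

#' Pressure at which the aperture-pressure curve plateaus
#'
#' The smallest turgor above which the aperture gain per additional MPa
#' drops below `frac` of the total aperture gain and stays below it for the
#' rest of the curve.
#'
#' @param curve An [aperture_curve()] tibble.
#' @param frac Slope threshold as a fraction of total gain per MPa.
#' @return Plateau-onset pressure (MPa), `NA` if the slope never settles.
#' @export
plateau_onset <- function(curve, frac = 0.01) {
  co_end <- if (any(curve$P_epi < max(curve$P_epi))) {
    which(curve$P_epi >= max(curve$P_epi))[1]
  } else 1
  gain <- max(curve$aperture) - curve$aperture[co_end]
  if (gain <= 0) return(NA_real_)
  dp <- diff(curve$P_gc)
  slope <- diff(curve$aperture) / dp
  below <- slope < frac * gain
  # first interval index from which the slope stays below threshold
  stays <- rev(cumprod(rev(below))) == 1
  if (!any(stays)) return(NA_real_)
  i <- which(stays)[1]
  if (i == 1) return(curve$P_gc[1])
  # refine by interpolating the slope crossing on the preceding interval
  s_prev <- slope[i - 1]; s_here <- slope[i]
  thr <- frac * gain
  pm_prev <- (curve$P_gc[i - 1] + curve$P_gc[i]) / 2
  pm_here <- (curve$P_gc[i] + curve$P_gc[i + 1]) / 2
  if (is.finite(s_prev) && s_prev > thr && s_here < thr) {
    pm_prev + (s_prev - thr) / (s_prev - s_here) * (pm_here - pm_prev)
  } else {
    curve$P_gc[i]
  }
}

#' Effective (von Mises type) strain and stress per element
#'
#' The effective Cauchy stress is the von Mises invariant
#' `sqrt(3/2 s':s')`; the effective Lagrange strain is the analogous second
#' deviatoric invariant `sqrt(2/3 E':E')` of the Green-Lagrange tensor
#' (the normalization used by common FE postprocessors, equal to the
#' uniaxial strain for incompressible uniaxial deformation). Values are
#' reported uncapped; `cap` truncates the strain for plotting parity.
#'
#' @param solution A `gc_solution`.
#' @param step Load-step index (1-based).
#' @param cap Optional cap applied to the effective strain (e.g. 1).
#' @return A tibble per element: `patch`, `cell`, `eff_strain`, `eff_stress`.
#' @export
effective_measures <- function(solution, step, cap = NULL) {
  st <- element_state(solution, step)
  C11 <- st$C2[, 1]; C12 <- st$C2[, 2]; C22 <- st$C2[, 3]
  # principal stretches of the membrane + thickness stretch
  tr <- C11 + C22
  dd <- sqrt(pmax((C11 - C22)^2 / 4 + C12^2, 0))
  mu1 <- tr / 2 + dd; mu2 <- tr / 2 - dd; mu3 <- st$lambda3^2
  e1 <- (mu1 - 1) / 2; e2 <- (mu2 - 1) / 2; e3 <- (mu3 - 1) / 2
  em <- (e1 + e2 + e3) / 3
  eff_strain <- sqrt(2 / 3 * ((e1 - em)^2 + (e2 - em)^2 + (e3 - em)^2))
  if (!is.null(cap)) eff_strain <- pmin(eff_strain, cap)
  s <- st$sigma
  eff_stress <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                              (s[, 3] - s[, 1])^2) +
                       3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  tibble::tibble(element = seq_along(eff_strain),
                 patch = solution$mesh$patch, cell = solution$mesh$cell,
                 eff_strain = eff_strain, eff_stress = eff_stress)
}

#' Theoretical maximal stomatal pore area
#'
#' `a_max = 0.25 * pi * l^2` for pore length `l` at maximal opening: the
#' area of a circle of diameter `l`, the geometric upper bound a pore of
#' that length can open to. Returns an area (um^2); the aperture elsewhere
#' in this package is a width (um) - the two are never conflated.
#'
#' @param l Stomatal pore length (um) under maximal opening.
#' @return Theoretical maximal pore area (um^2).
#' @export
theoretical_max_aperture <- function(l) {
  if (any(l < 0)) stop("pore length must be non-negative")
  0.25 * pi * l^2
}

#' Work-energy balance of a solution
#'
#' External pressure work along the load path (trapezoidal in the enclosed
#' cell volumes and the epidermal flux volume) compared with the stored
#' energy (membrane strain energy + bending + penalty terms) at the final
#' step. For a converged quasi-static elastic path the two agree closely.
#'
#' @param solution A `gc_solution`.
#' @return A list with `work_external`, `energy_stored`, `rel_gap`.
#' @export
work_energy_balance <- function(solution) {
  mesh <- solution$mesh
  ns <- nrow(solution$steps)
  Pg <- c(0, solution$steps$P_gc)
  Pe <- c(0, solution$steps$P_epi)
  V1 <- V2 <- Vf <- numeric(ns + 1)
  epi <- mesh$patch %in% (solution$epi_patches %||% "dorsal")
  el <- mesh$elems[epi, , drop = FALSE]
  for (s in 0:ns) {
    x <- solution$coords[[s + 1]]
    V1[s + 1] <- mesh_cell_volume(mesh, 1, x)
    V2[s + 1] <- mesh_cell_volume(mesh, 2, x)
    x1 <- x[el[, 1], , drop = FALSE]
    x2 <- x[el[, 2], , drop = FALSE]
    x3 <- x[el[, 3], , drop = FALSE]
    cr <- cbind(x2[, 2] * x3[, 3] - x2[, 3] * x3[, 2],
                x2[, 3] * x3[, 1] - x2[, 1] * x3[, 3],
                x2[, 1] * x3[, 2] - x2[, 2] * x3[, 1])
    Vf[s + 1] <- sum(rowSums(x1 * cr)) / 6
  }
  Pg_mid <- (Pg[-1] + Pg[-(ns + 1)]) / 2
  Pe_mid <- (Pe[-1] + Pe[-(ns + 1)]) / 2
  work <- sum(Pg_mid * diff(V1 + V2)) - sum(Pe_mid * diff(Vf))
  stored <- with(solution$steps[ns, ], E_mem + E_bend + E_contact)
  list(work_external = work, energy_stored = stored,
       rel_gap = abs(work - stored) / max(abs(work), 1e-12))
}

#' Steepest polar stress gradient of a solved state
#'
#' The maximum magnitude of the effective-stress difference between
#' adjacent elements divided by their centroid distance, over element
#' pairs whose midpoint lies in the polar region (reference `|x|` beyond
#' `frac` of the half-length). Reads how steeply stress varies toward the
#' guard-cell poles; pinning the poles steepens it.
#'
#' @param solution A `gc_solution`.
#' @param step Load-step index.
#' @param frac Polar-region cutoff as a fraction of the maximum `|x|`.
#' @param cap Optional cap applied to the effective stress first.
#' @return Maximum polar stress gradient (MPa/um).
#' @export
polar_stress_gradient <- function(solution, step, frac = 0.5, cap = NULL) {
  mesh <- solution$mesh
  el <- mesh$elems
  cent <- (mesh$nodes[el[, 1], ] + mesh$nodes[el[, 2], ] +
             mesh$nodes[el[, 3], ]) / 3
  ed <- rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])
  eid <- rep(seq_len(nrow(el)), 3)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  o <- order(key)
  key <- key[o]; eid <- eid[o]
  same <- which(key[-1] == key[-length(key)])
  eA <- eid[same]; eB <- eid[same + 1]
  dctr <- sqrt(rowSums((cent[eA, , drop = FALSE] -
                          cent[eB, , drop = FALSE])^2))
  midx <- abs(cent[eA, 1] + cent[eB, 1]) / 2
  sel <- midx > frac * max(abs(cent[, 1]))
  s <- effective_measures(solution, step)$eff_stress
  if (!is.null(cap)) s <- pmin(s, cap)
  max(abs(s[eA] - s[eB])[sel] / dctr[sel])
}
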