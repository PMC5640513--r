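#' Parametric description of a stomatal guard-cell pair
#'
#' Collects the dimensions and meshing controls for the two-guard-cell
#' complex. Each guard cell is an inflated, tapering tube ("deformed torus")
#' whose dorsal edge follows the stomatal outline ellipse and whose ventral
#' edge follows the pore ellipse, closed at both ends by flat polar walls
#' that separate the two cells. Default dimensions are calibration values in
#' the range reported for *Vicia faba* stomata; they are knobs, not
#' measurements.
#'
#' Coordinates: the complex long axis is `x`, the transverse (pore-opening)
#' direction is `y`, out of the leaf plane is `z`; origin at the complex
#' centroid. All lengths are in micrometres.
#'
#' @param complex_length Long-axis extent of the complex (um).
#' @param complex_width Transverse extent of the complex (um).
#' @param pore_length0 Undeformed pore length along `x` (um).
#' @param pore_width0 Undeformed pore width along `y` (um).
#' @param cross_section_kind `"circular"` (uniform wall, the baseline
#'   annulus cross-section) or `"rounded_triangular"` (ventral wall
#'   thickened, the VWT variant).
#' @param t_wall Wall thickness away from the poles (um).
#' @param t_pole Polar wall thickness (um).
#' @param m_v Multiplier applied to the ventral-patch thickness only
#'   (1 baseline, 0.9/1.1 for the sensitivity variants).
#' @param mesh_resolution Target number of elements per guard cell.
#' @param ventral_thickening For the rounded-triangular section, the
#'   fractional extra thickness at the ventral crest: thickness there is
#'   `t_wall * (1 + ventral_thickening)`.
#' @param blend_exponent Exponent of the smooth dorsal-to-ventral thickness
#'   blend for the rounded-triangular section.
#' @param ventral_flat_exponent For the rounded-triangular section, the
#'   superellipse exponent flattening the ventral side of the cross-section
#'   (2 = circular; larger = flatter ventral face). The pore lip point is
#'   preserved, so the resting pore outline is unchanged.
#' @param z_flatten Optional out-of-leaf-plane flattening factor applied to
#'   all `z` coordinates (1 = no flattening).
#' @return An object of class `gc_geometry_params`.
#' @export
geometry_params <- function(complex_length = 45,
                            complex_width = 30,
                            pore_length0 = 18,
                            pore_width0 = 0.5,
                            cross_section_kind = c("circular", "rounded_triangular"),
                            t_wall = 1.0,
                            t_pole = 0.3,
                            m_v = 1.0,
                            mesh_resolution = 20000,
                            ventral_thickening = 2.0,
                            blend_exponent = 2,
                            ventral_flat_exponent = 3,
                            z_flatten = 1.6) {
  cross_section_kind <- match.arg(cross_section_kind)
  p <- list(
    complex_length = complex_length, complex_width = complex_width,
    pore_length0 = pore_length0, pore_width0 = pore_width0,
    a_s = complex_length / 2, b_s = complex_width / 2,
    a_p = pore_length0 / 2, b_p = pore_width0 / 2,
    cross_section_kind = cross_section_kind,
    t_wall = t_wall, t_pole = t_pole, m_v = m_v,
    mesh_resolution = mesh_resolution,
    ventral_thickening = ventral_thickening,
    blend_exponent = blend_exponent,
    ventral_flat_exponent = ventral_flat_exponent,
    z_flatten = z_flatten
  )
  class(p) <- "gc_geometry_params"
  validate_geometry_params(p)
  p
}

validate_geometry_params <- function(p) {
  lens <- c(p$complex_length, p$complex_width, p$pore_length0, p$pore_width0,
            p$t_wall, p$t_pole, p$z_flatten)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("invalid-geometry: all lengths must be positive and finite", call. = FALSE)
  }
  if (p$a_p <= 0 || p$b_p <= 0 || p$a_s <= 0 || p$b_s <= 0) {
    stop("invalid-geometry: degenerate ellipse (semi-axis <= 0)", call. = FALSE)
  }
  if (p$a_p >= p$a_s || p$b_p >= p$b_s) {
    stop("invalid-geometry: pore ellipse must lie strictly inside the outline ellipse",
         call. = FALSE)
  }
  if (!is.finite(p$m_v) || p$m_v <= 0) {
    stop("invalid-geometry: m_v must be positive", call. = FALSE)
  }
  invisible(p)
}

#' Read geometry parameters from a YAML config file
#'
#' The config is a flat key-value YAML file whose keys match the arguments
#' of [geometry_params()].
#'
#' @param path Path to a YAML file.
#' @return A `gc_geometry_params` object.
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml_read_flat(path)
  do.call(geometry_params, cfg)
}

# Minimal flat YAML reader (key: value per line, comments with '#').
# Kept dependency-free; the configs this package writes are flat.
yaml_read_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else gsub("^['\"]|['\"]$", "", val)
  }
  out
}

# Tube midline/edge curves. phi in [0, pi] parameterizes one guard cell
# from pole to pole; the pore edge is the pore ellipse, the dorsal edge the
# outline ellipse.
tube_frame <- function(p, phi) {
  pore <- cbind(p$a_p * cos(phi), p$b_p * sin(phi), 0)
  outl <- cbind(p$a_s * cos(phi), p$b_s * sin(phi), 0)
  mid <- (pore + outl) / 2
  d <- (outl - pore) / 2
  r <- sqrt(rowSums(d^2))
  et <- d / r
  list(mid = mid, r = r, et = et)
}

# Decide tessellation sizes for a target element count per cell.
mesh_sizes <- function(p) {
  a_m <- (p$a_p + p$a_s) / 2; b_m <- (p$b_p + p$b_s) / 2
  # Ramanujan perimeter of the midline ellipse; half of it is the tube length
  per <- pi * (3 * (a_m + b_m) - sqrt((3 * a_m + b_m) * (a_m + 3 * b_m)))
  L <- per / 2
  phi <- seq(0, pi, length.out = 181)
  r_mean <- mean(tube_frame(p, phi)$r)
  C <- 2 * pi * r_mean
  R0 <- (p$a_s - p$a_p) / 2
  count_for <- function(s) {
    npsi <- max(8, 2 * round(C / (2 * s)))
    nphi <- max(6, 2 * round(L / (2 * s)))
    nr <- max(2, round(R0 / s))
    list(npsi = npsi, nphi = nphi, nr = nr,
         count = 2 * nphi * npsi + 2 * npsi * (2 * nr - 1))
  }
  s <- sqrt((2 * L * C + 2 * C * R0) / p$mesh_resolution)
  for (i in 1:8) {
    cc <- count_for(s)
    if (abs(cc$count - p$mesh_resolution) / p$mesh_resolution < 0.1) break
    s <- s * sqrt(cc$count / p$mesh_resolution)
  }
  count_for(s)
}

#' Build the guard-cell-pair surface mesh
#'
#' Constructs a closed, oriented triangular surface mesh for each of the two
#' guard cells: a structured tube over the pole-to-pole parameter, capped by
#' flat polar walls lying in the `y = 0` plane. The second cell is the exact
#' mirror image of the first through the long-axis midplane, so the pair is
#' mirror-symmetric by construction. Elements carry a thickness, a
#' circumferential (hoop) fiber direction, and a wall-patch label in
#' `ventral`, `dorsal`, `periclinal_outer`, `periclinal_inner`, `polar_wall`.
#'
#' @param params A [geometry_params()] object.
#' @return An object of class `gc_mesh`: a list with `nodes` (n x 3 um),
#'   `elems` (m x 3 node indices), `thickness`, `fiber`, `patch`, `cell`,
#'   `node_cell`, `node_sets` (`pole_tips`, `long_axis_midplane`,
#'   `equatorial_ring`, `pore_lip`), `hoop_pot` and the originating `params`.
#' @export
build_geometry <- function(params) {
  validate_geometry_params(params)
  if (params$mesh_resolution < 100) {
    stop("mesh_resolution < 100 refused: too coarse to close the guard-cell surface",
         call. = FALSE)
  }
  sz <- mesh_sizes(params)
  npsi <- sz$npsi; nphi <- sz$nphi; nr <- sz$nr
  # force even counts so that psi = pi and phi = pi/2 hit the node lattice
  stopifnot(npsi %% 2 == 0, nphi %% 2 == 0)

  psi <- 2 * pi * (0:(npsi - 1)) / npsi
  phi <- pi * (0:nphi) / nphi
  fr <- tube_frame(params, phi)

  # unit cross-section profile: a circle, with the ventral (pore-facing,
  # cos psi < 0) half blended into a superellipse for the
  # rounded-triangular section. The extreme ventral point (psi = pi) is
  # preserved, so the resting pore outline is identical across sections.
  uu <- cos(psi); vv <- sin(psi)
  if (params$cross_section_kind == "rounded_triangular") {
    p_fl <- params$ventral_flat_exponent
    vent <- uu < 0
    s <- (abs(uu[vent])^p_fl + abs(vv[vent])^p_fl)^(-1 / p_fl)
    uu[vent] <- uu[vent] * s
    vv[vent] <- vv[vent] * s
  }

  n_tube <- (nphi + 1) * npsi
  tube_id <- function(i, j) as.integer(i * npsi + (j %% npsi) + 1L)  # i in 0..nphi, j in 0..npsi-1

  nodes <- matrix(0, nrow = n_tube, ncol = 3)
  hoop <- numeric(n_tube)
  for (i in 0:nphi) {
    ring <- fr$mid[rep(i + 1, npsi), , drop = FALSE] +
      fr$r[i + 1] * (outer(uu, fr$et[i + 1, ]) +
                       outer(vv, c(0, 0, 1)))
    nodes[(i * npsi + 1):((i + 1) * npsi), ] <- ring
    hoop[(i * npsi + 1):((i + 1) * npsi)] <- phi[i + 1]
  }

  elems <- list(); epsi <- list()
  for (i in 0:(nphi - 1)) {
    for (j in 0:(npsi - 1)) {
      a <- tube_id(i, j); b <- tube_id(i + 1, j)
      cc <- tube_id(i + 1, j + 1); d <- tube_id(i, j + 1)
      elems[[length(elems) + 1]] <- c(a, b, cc)
      elems[[length(elems) + 1]] <- c(a, cc, d)
      pm <- psi_mean(psi[j + 1], psi[(j %% npsi) + ifelse(j + 1 == npsi, 1, 2)])
      epsi[[length(epsi) + 1]] <- pm
      epsi[[length(epsi) + 1]] <- pm
    }
  }
  n_nodes <- n_tube
  cap_nodes_all <- integer(0)
  dphi <- pi / nphi
  for (end in c(0, nphi)) {
    # interior rings k = 1..nr-1 plus a centre node; ring nr-k has radius
    # R0 * (nr - k)/nr. Rim ring is the tube row itself.
    R0 <- fr$r[end + 1]
    c0 <- fr$mid[end + 1, ]
    et <- fr$et[end + 1, ]
    ring_ids <- list()
    ring_ids[[1]] <- vapply(0:(npsi - 1), function(j) tube_id(end, j), integer(1))
    for (k in 1:(nr - 1)) {
      rk <- R0 * (nr - k) / nr
      ring <- matrix(c0, nrow = npsi, ncol = 3, byrow = TRUE) +
        rk * (outer(uu, et) + outer(vv, c(0, 0, 1)))
      ids <- n_nodes + (1:npsi)
      nodes <- rbind(nodes, ring)
      hp <- if (end == 0) -(R0 - rk) / R0 * dphi else pi + (R0 - rk) / R0 * dphi
      hoop <- c(hoop, rep(hp, npsi))
      n_nodes <- n_nodes + npsi
      ring_ids[[k + 1]] <- ids
      cap_nodes_all <- c(cap_nodes_all, ids)
    }
    ctr <- n_nodes + 1L
    nodes <- rbind(nodes, c0)
    hoop <- c(hoop, if (end == 0) -dphi else pi + dphi)
    n_nodes <- n_nodes + 1L
    cap_nodes_all <- c(cap_nodes_all, ctr)
    for (k in 1:(nr - 1)) {
      o <- ring_ids[[k]]; inn <- ring_ids[[k + 1]]
      for (j in 0:(npsi - 1)) {
        jn <- (j + 1) %% npsi
        elems[[length(elems) + 1]] <- c(o[j + 1], o[jn + 1], inn[jn + 1])
        elems[[length(elems) + 1]] <- c(o[j + 1], inn[jn + 1], inn[j + 1])
        epsi[[length(epsi) + 1]] <- NA_real_
        epsi[[length(epsi) + 1]] <- NA_real_
      }
    }
    inn <- ring_ids[[nr]]
    for (j in 0:(npsi - 1)) {
      jn <- (j + 1) %% npsi
      elems[[length(elems) + 1]] <- c(inn[j + 1], inn[jn + 1], ctr)
      epsi[[length(epsi) + 1]] <- NA_real_
    }
    # rim nodes of the caps are tube nodes; they are pole_tips too
    cap_nodes_all <- c(cap_nodes_all, ring_ids[[1]])
  }
  elems <- do.call(rbind, elems)
  epsi <- unlist(epsi)
  storage.mode(elems) <- "integer"
  nodes[, 3] <- nodes[, 3] * params$z_flatten

  # orient cell-1 elements outward
  m_el <- nrow(elems)
  is_cap <- is.na(epsi)
  cent <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] + nodes[elems[, 3], ]) / 3
  nrm <- tri_normals(nodes, elems)
  # reference outward direction: tube -> away from local midline; cap -> -y
  phi_el <- atan2(cent[, 2] / ((params$b_p + params$b_s) / 2),
                  cent[, 1] / ((params$a_p + params$a_s) / 2))
  fr_el <- tube_frame(params, pmin(pmax(phi_el, 0), pi))
  outward <- cent - fr_el$mid
  outward[is_cap, ] <- matrix(rep(c(0, -1, 0), sum(is_cap)), ncol = 3, byrow = TRUE)
  flip <- rowSums(nrm * outward) < 0
  elems[flip, ] <- elems[flip, c(1, 3, 2)]

  patch <- rep("polar_wall", m_el)
  co <- cos(epsi[!is_cap])
  si <- sin(epsi[!is_cap])
  lab <- ifelse(co >= cos(pi / 4), "dorsal",
                ifelse(co <= -cos(pi / 4), "ventral",
                       ifelse(si > 0, "periclinal_outer", "periclinal_inner")))
  patch[!is_cap] <- lab

  # mirror to create the second guard cell (y -> -y, winding reversed)
  nodes2 <- nodes
  nodes2[, 2] <- -nodes2[, 2]
  elems2 <- elems[, c(1, 3, 2)] + n_nodes
  mesh <- list(
    nodes = rbind(nodes, nodes2),
    elems = rbind(elems, elems2),
    patch = factor(c(patch, patch),
                   levels = c("ventral", "dorsal", "periclinal_outer",
                              "periclinal_inner", "polar_wall")),
    cell = rep(c(1L, 2L), each = m_el),
    node_cell = rep(c(1L, 2L), each = n_nodes),
    hoop_pot = c(hoop, hoop),
    elem_psi = c(epsi, epsi),
    node_sets = list(
      # the polar walls plus the adjacent collar of the tube ends: the
      # pectin-pinned region whose long-axis motion the fixed-poles
      # variant suppresses
      pole_tips = {
        collar <- which(abs(nodes[, 1]) >=
                          params$a_p + 0.5 * (params$a_s - params$a_p))
        ids <- sort(unique(c(cap_nodes_all, collar)))
        c(ids, ids + n_nodes)
      },
      long_axis_midplane = c(sort(unique(cap_nodes_all)),
                             sort(unique(cap_nodes_all)) + n_nodes),
      equatorial_ring = c(vapply(0:(npsi - 1), function(j) tube_id(nphi / 2, j), integer(1)),
                          vapply(0:(npsi - 1), function(j) tube_id(nphi / 2, j), integer(1)) + n_nodes),
      pore_lip = {
        lip <- vapply(0:nphi, function(i) tube_id(i, npsi / 2), integer(1))
        c(lip, lip + n_nodes)
      }
    ),
    sizes = sz,
    params = params
  )
  # the polar walls are shared between the two cells: the mirrored cap
  # nodes coincide (y = 0) and are tied so the pair is one fused complex
  capids <- sort(unique(cap_nodes_all))
  mesh$tied_nodes <- cbind(slave = capids + n_nodes, master = capids)
  class(mesh) <- "gc_mesh"
  mesh$thickness <- thickness_field(params, mesh)
  mesh <- assign_fiber_field(mesh)
  mesh
}

# circular mean helper for psi labels on the periodic direction
psi_mean <- function(p1, p2) {
  # element pair spans psi in [p1, p2] (p2 may wrap); centroid angle
  if (p2 < p1) p2 <- p2 + 2 * pi
  ((p1 + p2) / 2) %% (2 * pi)
}

tri_normals <- function(nodes, elems, normalize = TRUE) {
  e1 <- nodes[elems[, 2], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  e2 <- nodes[elems[, 3], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) n / sqrt(rowSums(n^2)) else n
}

tri_areas <- function(nodes, elems) {
  0.5 * sqrt(rowSums(tri_normals(nodes, elems, normalize = FALSE)^2))
}

#' Per-element wall thickness field
#'
#' For the circular cross-section every non-polar element has thickness
#' `t_wall`; for the rounded-triangular (VWT) section the thickness blends
#' smoothly from `t_wall` on the dorsal crest to
#' `t_wall * (1 + ventral_thickening)` on the ventral crest, emulating the
#' differential inner-wall thickening of a triangular lumen inside a
#' circular outer surface. The ventral-patch thickness is then scaled by
#' `m_v`. Polar walls always have thickness `t_pole`.
#'
#' @param params A [geometry_params()] object.
#' @param mesh A `gc_mesh` (patch labels and element angles are used).
#' @return Numeric vector of per-element thickness (um).
#' @export
thickness_field <- function(params, mesh) {
  m <- nrow(mesh$elems)
  t <- rep(params$t_wall, m)
  if (params$cross_section_kind == "rounded_triangular") {
    w <- ((1 - cos(mesh$elem_psi)) / 2)^params$blend_exponent
    t <- params$t_wall * (1 + params$ventral_thickening * w)
    t[is.na(mesh$elem_psi)] <- params$t_wall
  }
  t[mesh$patch == "ventral"] <- t[mesh$patch == "ventral"] * params$m_v
  t[mesh$patch == "polar_wall"] <- params$t_pole
  t
}

#' Assign the circumferential microfibril direction to every element
#'
#' Cellulose microfibrils run circumferentially around the guard-cell tube;
#' on the polar walls they continue as circles around the wall centre. The
#' direction is computed per element as the in-surface direction tangent to
#' the level sets of a stored hoop potential (pole-to-pole parameter on the
#' tube, radial distance on the caps), so it is exactly tangent to each
#' element and equivariant under rigid motions of the mesh.
#'
#' @param mesh A `gc_mesh`.
#' @return The mesh with a unit `fiber` (m x 3) per element.
#' @export
assign_fiber_field <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  p1 <- nd[el[, 1], , drop = FALSE]
  e1 <- nd[el[, 2], , drop = FALSE] - p1
  e2 <- nd[el[, 3], , drop = FALSE] - p1
  nn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(nn^2))
  bad <- which(a2 <= 1e-14)
  if (length(bad)) {
    stop("zero-area element(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  nh <- nn / a2
  s1 <- mesh$hoop_pot[el[, 2]] - mesh$hoop_pot[el[, 1]]
  s2 <- mesh$hoop_pot[el[, 3]] - mesh$hoop_pot[el[, 1]]
  # in-plane gradient g of the hoop potential: solve the 2x2 metric system
  a11 <- rowSums(e1 * e1); a12 <- rowSums(e1 * e2); a22 <- rowSums(e2 * e2)
  det <- a11 * a22 - a12^2
  c1 <- (s1 * a22 - s2 * a12) / det
  c2 <- (s2 * a11 - s1 * a12) / det
  g <- c1 * e1 + c2 * e2
  # fiber = unit vector along the level set = n x g
  f <- cbind(nh[, 2] * g[, 3] - nh[, 3] * g[, 2],
             nh[, 3] * g[, 1] - nh[, 1] * g[, 3],
             nh[, 1] * g[, 2] - nh[, 2] * g[, 1])
  fn <- sqrt(rowSums(f^2))
  f <- f / fn
  mesh$fiber <- f
  mesh
}

#' Euler characteristic of one guard cell's surface
#'
#' @param mesh A `gc_mesh`.
#' @param cell 1 or 2.
#' @return Integer V - E + F (2 for a closed sphere-like wall).
#' @export
mesh_euler_characteristic <- function(mesh, cell = 1) {
  el <- mesh$elems[mesh$cell == cell, , drop = FALSE]
  v <- length(unique(as.vector(el)))
  ed <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  ed <- t(apply(ed, 1, sort))
  e <- nrow(unique(ed))
  v - e + nrow(el)
}

#' Total surface area of the mesh (um^2)
#' @param mesh A `gc_mesh`.
#' @param cell Optional cell id to restrict to.
#' @export
mesh_surface_area <- function(mesh, cell = NULL) {
  keep <- if (is.null(cell)) rep(TRUE, nrow(mesh$elems)) else mesh$cell == cell
  sum(tri_areas(mesh$nodes, mesh$elems[keep, , drop = FALSE]))
}

#' Enclosed volume of one guard cell (um^3)
#' @param mesh A `gc_mesh`.
#' @param cell 1 or 2.
#' @param nodes Optional deformed nodal coordinates.
#' @export
mesh_cell_volume <- function(mesh, cell = 1, nodes = mesh$nodes) {
  el <- mesh$elems[mesh$cell == cell, , drop = FALSE]
  x1 <- nodes[el[, 1], , drop = FALSE]
  x2 <- nodes[el[, 2], , drop = FALSE]
  x3 <- nodes[el[, 3], , drop = FALSE]
  cr <- cbind(x2[, 2] * x3[, 3] - x2[, 3] * x3[, 2],
              x2[, 3] * x3[, 1] - x2[, 1] * x3[, 3],
              x2[, 1] * x3[, 2] - x2[, 2] * x3[, 1])
  sum(rowSums(x1 * cr)) / 6
}

#' Write the mesh (and optional fields) as a legacy ASCII VTK file
#'
#' Cell data always includes thickness, the patch label (as an integer
#' code), and the fiber direction; extra per-element scalar fields can be
#' appended.
#'
#' @param mesh A `gc_mesh`.
#' @param path Output file path.
#' @param nodes Optional deformed coordinates to write instead of the
#'   reference ones.
#' @param cell_data Named list of extra per-element numeric vectors.
#' @return Invisibly, `path`.
#' @export
write_mesh_vtk <- function(mesh, path, nodes = mesh$nodes, cell_data = list()) {
  n <- nrow(nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "guard-cell wall surface mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(nodes, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  utils::write.table(cbind(3L, mesh$elems - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(5L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  fields <- c(list(thickness = mesh$thickness,
                   patch = as.integer(mesh$patch),
                   cell = mesh$cell), cell_data)
  for (nmf in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nmf), "LOOKUP_TABLE default"), con)
    writeLines(format(fields[[nmf]], digits = 9, trim = TRUE), con)
  }
  writeLines("VECTORS fiber double", con)
  utils::write.table(format(mesh$fiber, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.gc_mesh <- function(x, ...) {
  cat("<gc_mesh> guard-cell pair surface mesh\n")
  cat(sprintf("  nodes: %d, elements: %d (%d per cell)\n",
              nrow(x$nodes), nrow(x$elems), sum(x$cell == 1)))
  cat(sprintf("  cross-section: %s, t_wall %.3g um, t_pole %.3g um, m_v %.3g\n",
              x$params$cross_section_kind, x$params$t_wall,
              x$params$t_pole, x$params$m_v))
  invisible(x)
}
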