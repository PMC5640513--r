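#' Staged pressure-loading protocol
#'
#' Guard-cell turgor `P_gc` ramps from 0 to `P_gc_max`; the surrounding
#' epidermal pressure co-ramps with it (`P_epi = min(P_gc, P_epi_max)`), so
#' both rise together during the initial phase and only turgor keeps rising
#' once the epidermal cap is reached.
#'
#' @param P_epi_max Epidermal pressure cap (MPa).
#' @param P_gc_max Maximum guard-cell turgor (MPa).
#' @param steps Number of load steps (>= 10).
#' @return An object of class `gc_load_protocol`.
#' @export
load_protocol <- function(P_epi_max = 0.5, P_gc_max = 6.0, steps = 60) {
  if (!(P_epi_max >= 0 && P_epi_max < P_gc_max)) {
    stop("need 0 <= P_epi_max < P_gc_max")
  }
  if (steps < 10) stop("need at least 10 load steps")
  structure(list(P_epi_max = P_epi_max, P_gc_max = P_gc_max, steps = as.integer(steps),
                 co_ramp_fraction = P_epi_max / P_gc_max),
            class = "gc_load_protocol")
}

#' Solver controls
#'
#' @param rtol Relative residual tolerance: the converged max nodal force
#'   imbalance must fall below `rtol` times the mean applied nodal pressure
#'   force.
#' @param maxit L-BFGS iterations per attempt.
#' @param restarts Optimizer restarts per load step before step halving.
#' @param max_halvings Maximum recursive load-step halvings.
#' @param bending_factor Scale of the discrete-hinge bending regularization
#'   (bending rigidity `D = bending_factor * C1 * t^3`).
#' @param k_contact Midplane no-penetration penalty stiffness (MPa/um).
#' @param k_rigid Weak rigid-body-mode penalty (removes drift of the free
#'   floating complex without constraining deformation).
#' @export
solver_options <- function(rtol = 3e-3, maxit = 6000, restarts = 3,
                           max_halvings = 5, bending_factor = 1.0,
                           k_contact = 1000, k_rigid = 1.0, lbfgs_memory = 20) {
  list(rtol = rtol, maxit = maxit, restarts = restarts,
       max_halvings = max_halvings, bending_factor = bending_factor,
       k_contact = k_contact, k_rigid = k_rigid,
       lbfgs_memory = lbfgs_memory)
}

# Per-element reference quantities for the membrane kernel: local-frame
# shape gradients (as Ginv), reference areas, local 2D fiber components,
# hinge table for bending, contact node list.
membrane_precompute <- function(mesh, material, options) {
  nd <- mesh$nodes; el <- mesh$elems
  m <- nrow(el)
  p1 <- nd[el[, 1], , drop = FALSE]
  d1 <- nd[el[, 2], , drop = FALSE] - p1
  d2 <- nd[el[, 3], , drop = FALSE] - p1
  l1 <- sqrt(rowSums(d1^2))
  e1 <- d1 / l1
  nn <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  a2 <- sqrt(rowSums(nn^2))
  if (any(a2 <= 1e-14)) stop("zero-area element in mesh")
  nh <- nn / a2
  e2 <- cbind(nh[, 2] * e1[, 3] - nh[, 3] * e1[, 2],
              nh[, 3] * e1[, 1] - nh[, 1] * e1[, 3],
              nh[, 1] * e1[, 2] - nh[, 2] * e1[, 1])
  A0 <- a2 / 2
  # local 2D coords: P1=(0,0), P2=(l1,0), P3=(d2.e1, d2.e2); G = [P2-P1, P3-P1]
  g11 <- l1; g21 <- 0
  g12 <- rowSums(d2 * e1); g22 <- rowSums(d2 * e2)
  detG <- g11 * g22 - g12 * g21
  # Ginv stored as g11,g21,g12,g22 of the inverse matrix
  Ginv <- cbind(g22 / detG, 0, -g12 / detG, g11 / detG)
  a2d <- cbind(rowSums(mesh$fiber * e1), rowSums(mesh$fiber * e2))
  a2dn <- sqrt(rowSums(a2d^2))
  a2d <- a2d / a2dn

  # hinge table: interior edges within each cell
  ed <- rbind(el[, c(1, 2, 3)], el[, c(2, 3, 1)], el[, c(3, 1, 2)])
  eid <- rep(seq_len(m), 3)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ord <- order(key)
  key <- key[ord]; ed <- ed[ord, , drop = FALSE]; eid <- eid[ord]
  same <- which(key[-1] == key[-length(key)])
  h0 <- ed[same, 1]; h1 <- ed[same, 2]
  h2 <- ed[same, 3]; h3 <- ed[same + 1, 3]
  hA <- eid[same]; hB <- eid[same + 1]
  hinges <- cbind(h0, h1, h2, h3)
  storage.mode(hinges) <- "integer"
  tmean <- (mesh$thickness[hA] + mesh$thickness[hB]) / 2
  elen2 <- rowSums((nd[h1, , drop = FALSE] - nd[h0, , drop = FALSE])^2)
  D <- options$bending_factor * material$C1 * tmean^3
  kh <- D * elen2 / (A0[hA] + A0[hB])
  x0 <- as.numeric(t(nd))
  th0 <- if (nrow(hinges) > 0) {
    hinge_angles(x0, hinges)
  } else numeric(0)

  # nodal areas (one third of each incident element's area)
  narea <- as.vector(rowsum(rep(A0 / 3, 3), as.vector(el)))

  # midplane no-penetration only applies to the two-cell complex
  if (length(unique(mesh$node_cell)) == 2) {
    cnode <- seq_len(nrow(nd))
    csign <- ifelse(mesh$node_cell == 1L, 1, -1)
  } else {
    cnode <- integer(0)
    csign <- numeric(0)
  }

  mat <- c(material$C1, material$C2, material$C3, material$C4, material$C5,
           material$lambda_star, material$C6)

  list(Ginv = Ginv, A0 = A0, a2d = a2d, hinges = hinges, kh = kh,
       theta0 = th0, cnode = as.integer(cnode), csign = csign, mat = mat,
       narea = narea, e1 = e1, e2 = e2, n0 = nh)
}

# rest dihedral angles, computed with the same kernel conventions
hinge_angles <- function(x, hinges) {
  X <- matrix(x, ncol = 3, byrow = TRUE)
  p0 <- X[hinges[, 1], , drop = FALSE]; p1 <- X[hinges[, 2], , drop = FALSE]
  p2 <- X[hinges[, 3], , drop = FALSE]; p3 <- X[hinges[, 4], , drop = FALSE]
  e0 <- p1 - p0; v2 <- p2 - p0; v3 <- p3 - p0
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nA <- cr(e0, v2); nB <- cr(v3, e0)
  le <- sqrt(rowSums(e0^2))
  s <- rowSums(cr(nA, nB) * e0) / le
  cc <- rowSums(nA * nB)
  atan2(s, cc)
}

#' Constraint set pinning the stomatal poles
#'
#' Returns the long-axis (`x`) displacement constraints on the `pole_tips`
#' node set, the boundary-condition variant that prevents stomatal complex
#' elongation. `y` and `z` stay free.
#'
#' @param mesh A `gc_mesh`.
#' @return A data frame with columns `node` and `dof` (dof 1 = x).
#' @export
apply_fixed_poles <- function(mesh) {
  nodes <- mesh$node_sets$pole_tips
  if (length(nodes) == 0) stop("pole_tips node set is empty")
  data.frame(node = nodes, dof = 1L)
}

# combined objective: membrane kernel + weak rigid-mode penalty.
# Tied nodes (the shared polar walls) are reduced to their master dofs;
# fixed dofs are removed from the optimization vector.
make_objective <- function(mesh, pre, pcoef, kc, kr, fixed_idx, x_full0) {
  n <- nrow(mesh$nodes)
  X0 <- mesh$nodes
  ctr <- colMeans(X0)
  R0 <- sweep(X0, 2, ctr)
  L2 <- mean(rowSums(R0^2))
  # master dof of every full dof (slaves of tied nodes follow their master)
  master <- seq_len(3 * n)
  if (!is.null(mesh$tied_nodes) && nrow(mesh$tied_nodes) > 0) {
    for (k in 1:3) {
      master[3 * (mesh$tied_nodes[, 1] - 1) + k] <-
        3 * (mesh$tied_nodes[, 2] - 1) + k
    }
  }
  fixed_full <- unique(master[fixed_idx])
  free_idx <- setdiff(unique(master), fixed_full)
  map <- match(master, free_idx)        # full dof -> position in par (NA if fixed)
  parmap <- ifelse(is.na(map), -1L, map - 1L)  # 0-based for the kernel
  x0ref <- as.numeric(t(X0))
  r0 <- as.numeric(t(R0))
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  # area-weighted contact penalty: kc is a contact-pressure stiffness
  # (MPa/um), converted to nodal forces via the tributary area
  kcv <- kc * pre$narea[pre$cnode]
  evalx <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- mem_objective(par, x_full0, parmap, x0ref, r0, kr, L2,
                         mesh$elems, pre$Ginv, pre$A0, mesh$thickness,
                         pre$a2d, pcoef, pre$mat, pre$hinges, pre$kh,
                         pre$theta0, pre$cnode, pre$csign, kcv)
    out <- list(E = res$E, grad = res$grad, raw = res)
    cache$par <- par
    cache$res <- out
    out
  }
  expand <- function(par) {
    x <- x_full0
    ok <- !is.na(map)
    x[ok] <- par[map[ok]]
    x
  }
  list(fn = function(par) evalx(par)$E,
       gr = function(par) evalx(par)$grad,
       eval = evalx, free_idx = free_idx, expand = expand,
       par0 = x_full0[free_idx])
}

# pressure coefficients per element for the flux potential:
# -P_gc on every face of each cell (enclosed turgor) plus +P_epi on the
# externally loaded faces. Default epidermal surface set: all outward
# faces of the complex (dorsal walls in contact with neighboring cells
# plus both periclinal bands as confinement); the set is a config switch.
# Sets whose net area vector does not cancel across the pair leave a net
# force that only the weak rigid-mode penalty reacts.
pressure_coefficients <- function(mesh, P_gc, P_epi,
                                  epi_patches = c("dorsal", "periclinal_outer",
                                                  "periclinal_inner")) {
  pc <- rep(-P_gc, nrow(mesh$elems))
  pc[mesh$patch %in% epi_patches] <- pc[mesh$patch %in% epi_patches] + P_epi
  pc
}

#' Quasi-static solution of the pressurized guard-cell pair
#'
#' Marches the staged load protocol, at each step finding the equilibrium
#' of the total potential energy (hyperelastic membrane + conservative
#' pressure potentials + weak bending regularization + midplane contact
#' penalty) by L-BFGS minimization with backtracking, warm-started from the
#' previous step, with adaptive load-step halving on non-convergence.
#'
#' @param mesh A `gc_mesh` from [build_geometry()].
#' @param material A [material_params()] object.
#' @param protocol A [load_protocol()].
#' @param fixed_poles Pin the long-axis displacement of the polar walls
#'   (the "fixed poles" variant)?
#' @param options A [solver_options()] list.
#' @param verbose Print per-step progress?
#' @return An object of class `gc_solution`: the mesh, a tibble `steps`
#'   (pressures, residual norms in nN, energy components) and the list of
#'   deformed nodal coordinate matrices `coords` (um), one per load step,
#'   plus the zero-load state first.
#' @export
solve_quasistatic <- function(mesh, material, protocol = load_protocol(),
                              fixed_poles = FALSE,
                              options = solver_options(),
                              epi_patches = c("dorsal", "periclinal_outer",
                                              "periclinal_inner"),
                              verbose = FALSE) {
  pre <- membrane_precompute(mesh, material, options)
  n <- nrow(mesh$nodes)
  fixed_idx <- integer(0)
  if (fixed_poles) {
    cs <- apply_fixed_poles(mesh)
    fixed_idx <- 3 * (cs$node - 1) + cs$dof
  }
  P_gc <- seq(0, protocol$P_gc_max, length.out = protocol$steps + 1)[-1]
  P_epi <- pmin(P_gc, protocol$P_epi_max)
  options$P_ref_floor <- 0.25 * protocol$P_gc_max

  x <- as.numeric(t(mesh$nodes))
  x_prev <- NULL
  coords <- list(mesh$nodes)
  area_tot <- mesh_surface_area(mesh)
  rows <- vector("list", length(P_gc))
  for (s in seq_along(P_gc)) {
    t_step <- as.numeric(Sys.time())
    # first-order continuation predictor: extrapolate the previous
    # displacement increment as the warm start for the new load level
    x_start <- if (!is.null(x_prev)) x + (x - x_prev) else x
    st <- solve_one_load(mesh, pre, x_start, P_gc[s], P_epi[s],
                         P_gc_prev = if (s == 1) 0 else P_gc[s - 1],
                         P_epi_prev = if (s == 1) 0 else P_epi[s - 1],
                         fixed_idx = fixed_idx, options = options,
                         area_tot = area_tot, depth = 0,
                         epi_patches = epi_patches)
    x_prev <- x
    x <- st$x
    coords[[s + 1]] <- matrix(x, ncol = 3, byrow = TRUE)
    rows[[s]] <- tibble::tibble(
      step = s, P_gc = P_gc[s], P_epi = P_epi[s],
      residual_nN = st$residual * 1e3, converged = st$converged,
      E_mem = st$raw$E_mem, E_bend = st$raw$E_bend,
      E_contact = st$raw$E_contact, E_press = st$raw$E_press
    )
    if (verbose) {
      message(sprintf("step %2d  P_gc=%.3f  resid=%.3g nN  %s  [%.1f s]",
                      s, P_gc[s], st$residual * 1e3,
                      if (st$converged) "ok" else "NOT CONVERGED",
                      as.numeric(Sys.time()) - t_step))
    }
    if (!st$converged) {
      stop(sprintf(paste0("non-convergence at P_gc = %.3f MPa ",
                          "(last converged %.3f MPa, residual %.3g nN)"),
                   P_gc[s], if (s > 1) P_gc[s - 1] else 0,
                   st$residual * 1e3), call. = FALSE)
    }
  }
  out <- list(mesh = mesh, material = material, protocol = protocol,
              fixed_poles = fixed_poles, options = options, pre = pre,
              epi_patches = epi_patches,
              steps = dplyr::bind_rows(rows), coords = coords)
  class(out) <- "gc_solution"
  out
}

solve_one_load <- function(mesh, pre, x, P_gc, P_epi, P_gc_prev, P_epi_prev,
                           fixed_idx, options, area_tot, depth,
                           epi_patches = c("dorsal", "periclinal_outer",
                                           "periclinal_inner")) {
  pcoef <- pressure_coefficients(mesh, P_gc, P_epi, epi_patches)
  obj <- make_objective(mesh, pre, pcoef, options$k_contact, options$k_rigid,
                        fixed_idx, x)
  par <- obj$par0
  # force scale: mean pressure load per node (uN); the floor (a fraction
  # of the final load) keeps the early near-zero-load steps from chasing
  # an irrelevantly tight residual
  f_ref <- max(P_gc, options$P_ref_floor %||% 0, 1e-5) * area_tot /
    nrow(mesh$nodes)
  # absolute floor of 0.1 nN: below it the energy differences reach
  # machine precision and no optimizer can certify a tighter residual
  tol <- max(options$rtol * f_ref, 1e-4)
  converged <- FALSE
  for (r in seq_len(options$restarts)) {
    opt <- stats::optim(par, obj$fn, obj$gr, method = "L-BFGS-B",
                        control = list(maxit = options$maxit,
                                       factr = 10, pgtol = tol / 10,
                                       lmm = options$lbfgs_memory %||% 20))
    par <- opt$par
    res <- obj$eval(par)
    resid <- max(abs(res$grad))
    if (resid < tol && !res$raw$degenerate) { converged <- TRUE; break }
  }
  # accept a near-converged state (within 3x tolerance) rather than
  # cascading into load-step halving; the residual is recorded as is
  if (!converged) {
    res <- obj$eval(par)
    if (max(abs(res$grad)) < 3 * tol && !res$raw$degenerate) converged <- TRUE
  }
  if (!converged && depth < options$max_halvings) {
    # halve the load increment: solve the midpoint first, then retry
    mid <- solve_one_load(mesh, pre, x, (P_gc + P_gc_prev) / 2,
                          (P_epi + P_epi_prev) / 2, P_gc_prev, P_epi_prev,
                          fixed_idx, options, area_tot, depth + 1, epi_patches)
    if (mid$converged) {
      return(solve_one_load(mesh, pre, mid$x, P_gc, P_epi,
                            (P_gc + P_gc_prev) / 2, (P_epi + P_epi_prev) / 2,
                            fixed_idx, options, area_tot, depth + 1, epi_patches))
    }
  }
  xfull <- obj$expand(par)
  res <- obj$eval(par)
  list(x = xfull, residual = max(abs(res$grad)), converged = converged,
       raw = res$raw)
}

#' Per-element deformation and stress state at a solved load step
#'
#' Recovers, for every element, the membrane deformation (fiber stretch,
#' principal stretches, through-thickness stretch from incompressibility)
#' and the plane-stress Cauchy stress tensor, from which Green-Lagrange
#' strain and effective (von Mises) measures are computed downstream.
#'
#' @param solution A `gc_solution`.
#' @param step Load-step index (1-based over `solution$steps`).
#' @return A list of per-element quantities: `lambda_fiber`, `C2` (m x 3:
#'   C11, C12, C22 in the element reference frame), `lambda3`, `sigma`
#'   (m x 6: xx, yy, zz, xy, xz, yz in global axes), `W` (energy density).
#' @export
element_state <- function(solution, step) {
  mesh <- solution$mesh; pre <- solution$pre
  x <- solution$coords[[step + 1]]
  el <- mesh$elems
  p1 <- x[el[, 1], , drop = FALSE]
  d1 <- x[el[, 2], , drop = FALSE] - p1
  d2 <- x[el[, 3], , drop = FALSE] - p1
  g11 <- pre$Ginv[, 1]; g21 <- pre$Ginv[, 2]
  g12 <- pre$Ginv[, 3]; g22 <- pre$Ginv[, 4]
  f1 <- d1 * g11 + d2 * g21
  f2 <- d1 * g12 + d2 * g22
  C11 <- rowSums(f1 * f1); C22 <- rowSums(f2 * f2); C12 <- rowSums(f1 * f2)
  det2 <- C11 * C22 - C12^2
  lam3 <- 1 / sqrt(det2)
  tr <- C11 + C22
  I1 <- tr + 1 / det2
  mp <- solution$material
  W1 <- mp$C1 * mp$C2 * exp(mp$C2 * (I1 - 3))
  W2 <- -mp$C1 * mp$C2 / 2
  a1 <- pre$a2d[, 1]; a2 <- pre$a2d[, 2]
  I4 <- a1^2 * C11 + 2 * a1 * a2 * C12 + a2^2 * C22
  lam <- sqrt(I4)
  # deformed unit normal
  nn <- cbind(f1[, 2] * f2[, 3] - f1[, 3] * f2[, 2],
              f1[, 3] * f2[, 1] - f1[, 1] * f2[, 3],
              f1[, 1] * f2[, 2] - f1[, 2] * f2[, 1])
  nh <- nn / sqrt(rowSums(nn^2))
  fa <- f1 * a1 + f2 * a2  # deformed fiber vector (length lam)
  dWfdl <- ifelse(lam > 1, fiber_force_vec(lam, mp) / lam, 0)

  sym_outer <- function(u, v) {
    cbind(u[, 1] * v[, 1], u[, 2] * v[, 2], u[, 3] * v[, 3],
          (u[, 1] * v[, 2] + u[, 2] * v[, 1]) / 2,
          (u[, 1] * v[, 3] + u[, 3] * v[, 1]) / 2,
          (u[, 2] * v[, 3] + u[, 3] * v[, 2]) / 2)
  }
  b <- sym_outer(f1, f1) + sym_outer(f2, f2) + lam3^2 * sym_outer(nh, nh)
  b2 <- C11 * sym_outer(f1, f1) + C12 * 2 * sym_outer(f1, f2) +
    C22 * sym_outer(f2, f2) + lam3^4 * sym_outer(nh, nh)
  I1_3 <- tr + lam3^2
  sig <- 2 * ((W1 + W2 * I1_3) * b - W2 * b2) + (dWfdl / pmax(lam, 1e-12)) * sym_outer(fa, fa)
  # plane stress: remove the hydrostatic part so that sigma.n = 0
  snn <- sig[, 1] * nh[, 1]^2 + sig[, 2] * nh[, 2]^2 + sig[, 3] * nh[, 3]^2 +
    2 * (sig[, 4] * nh[, 1] * nh[, 2] + sig[, 5] * nh[, 1] * nh[, 3] +
           sig[, 6] * nh[, 2] * nh[, 3])
  sig[, 1:3] <- sig[, 1:3] - snn
  W <- mp$C1 * (exp(mp$C2 * (I1 - 3)) - 1) -
    (mp$C1 * mp$C2 / 2) * ((det2 + tr / det2) - 3) + fiber_energy(lam, mp)
  list(lambda_fiber = lam, C2 = cbind(C11, C12, C22), lambda3 = lam3,
       sigma = sig, W = W)
}

fiber_force_vec <- function(lambda, p) {
  ifelse(lambda <= 1, 0,
         ifelse(lambda < p$lambda_star,
                p$C3 * (exp(p$C4 * (lambda - 1)) - 1),
                p$C5 * lambda + p$C6))
}

#' Icosphere surface mesh
#'
#' Subdivided icosahedron projected onto a sphere; used by the thin-shell
#' inflation benchmark.
#'
#' @param radius Sphere radius (um).
#' @param subdiv Number of midpoint subdivisions.
#' @param thickness Uniform wall thickness (um).
#' @return A `gc_mesh`-compatible object (single closed cell).
#' @export
icosphere <- function(radius = 10, subdiv = 3, thickness = 0.1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4 * k - 3):(4 * k), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v * radius / sqrt(rowSums(v^2))
  storage.mode(f) <- "integer"
  # outward orientation
  nrm <- tri_normals(v, f)
  cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  flip <- rowSums(nrm * cent) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  # arbitrary tangent "fiber" (unused when C3 = C5 = 0)
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  fib <- e1 / sqrt(rowSums(e1^2))
  mesh <- list(nodes = v, elems = f, thickness = rep(thickness, nrow(f)),
               fiber = fib,
               patch = factor(rep("dorsal", nrow(f)),
                              levels = c("ventral", "dorsal", "periclinal_outer",
                                         "periclinal_inner", "polar_wall")),
               cell = rep(1L, nrow(f)), node_cell = rep(1L, nrow(v)),
               node_sets = list(), params = list(radius = radius))
  class(mesh) <- "gc_mesh"
  mesh
}

#' Closed-form inflation of a thin incompressible spherical shell
#'
#' Membrane relation for an isotropic Veronda-Westmann sphere under
#' internal pressure: at equibiaxial stretch `lambda`, the Cauchy stress is
#' `sigma = 2 (lambda^2 - lambda^-4)(W1 + lambda^2 W2)` and Laplace's law
#' with the deformed radius and thinned wall gives
#' `P = 2 t0 sigma / (r0 lambda^3)`.
#'
#' @param material Material parameters (fibers ignored).
#' @param radius,thickness Reference geometry (um).
#' @param pressure Pressures (MPa) at which to solve for the stretch.
#' @return Stretch values (one per pressure), by root finding.
#' @export
sphere_inflation_theory <- function(material, radius, thickness, pressure) {
  p_of_lambda <- function(l) {
    I1 <- 2 * l^2 + l^(-4)
    W1 <- material$C1 * material$C2 * exp(material$C2 * (I1 - 3))
    W2 <- -material$C1 * material$C2 / 2
    sig <- 2 * (l^2 - l^(-4)) * (W1 + l^2 * W2)
    2 * thickness * sig / (radius * l^3)
  }
  vapply(pressure, function(P) {
    if (P <= 0) return(1)
    stats::uniroot(function(l) p_of_lambda(l) - P, c(1, 3),
                   extendInt = "upX", tol = 1e-12)$root
  }, numeric(1))
}

#' Thin-shell inflation benchmark for the membrane solver
#'
#' Solves the inflation of a closed thin spherical shell with fibers
#' disabled and compares the finite-element stretch with the closed-form
#' membrane relation of [sphere_inflation_theory()].
#'
#' @param radius,thickness Sphere geometry (um); `thickness << radius`.
#' @param material Material parameters; `C3`/`C5` are forced to zero.
#' @param pressures Increasing pressure grid (MPa).
#' @param subdiv Icosphere subdivisions.
#' @return A tibble with `P`, `stretch_fe`, `stretch_theory`.
#' @export
inflate_sphere_benchmark <- function(radius = 10, thickness = 0.1,
                                     material = material_params(),
                                     pressures = seq(0.01, 0.2, length.out = 10),
                                     subdiv = 3,
                                     options = solver_options(bending_factor = 0.1)) {
  mat <- material_params(C1 = material$C1, C2 = material$C2, C3 = 0, C4 = material$C4,
                         C5 = 0, lambda_star = material$lambda_star,
                         K_bulk = material$K_bulk)
  mesh <- icosphere(radius, subdiv, thickness)
  pre <- membrane_precompute(mesh, mat, options)
  x <- as.numeric(t(mesh$nodes))
  area_tot <- mesh_surface_area(mesh)
  out <- numeric(length(pressures))
  Pprev <- 0
  for (i in seq_along(pressures)) {
    P <- pressures[i]
    st <- solve_one_load(mesh, pre, x, P, 0, Pprev, 0, integer(0),
                         options, area_tot, depth = 0)
    if (!st$converged) stop("sphere benchmark failed to converge at P = ", P)
    x <- st$x
    Pprev <- P
    r <- matrix(x, ncol = 3, byrow = TRUE)
    out[i] <- mean(sqrt(rowSums(r^2))) / radius
  }
  tibble::tibble(P = pressures, stretch_fe = out,
                 stretch_theory = sphere_inflation_theory(mat, radius, thickness, pressures))
}

#' @export
print.gc_solution <- function(x, ...) {
  cat("<gc_solution> quasi-static guard-cell inflation\n")
  cat(sprintf("  variant: %s, %d load steps to P_gc = %.2f MPa (P_epi cap %.2f)\n",
              if (x$fixed_poles) "fixed poles" else "baseline boundary",
              nrow(x$steps), x$protocol$P_gc_max, x$protocol$P_epi_max))
  cat(sprintf("  final residual %.3g nN, all converged: %s\n",
              x$steps$residual_nN[nrow(x$steps)], all(x$steps$converged)))
  invisible(x)
}
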