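test_that("invalid geometries are refused", {
  expect_error(geometry_params(pore_length0 = 0), "invalid-geometry")
  expect_error(geometry_params(pore_length0 = 50), "inside")
  expect_error(geometry_params(complex_width = -3), "invalid-geometry")
  expect_error(geometry_params(m_v = 0), "m_v")
  expect_error(build_geometry(geometry_params(mesh_resolution = 50)),
               "refused")
})

test_that("the undeformed mesh reproduces the prescribed dimensions", {
  mesh <- small_mesh()
  p <- mesh$params
  lip <- mesh$node_sets$pore_lip
  expect_equal(diff(range(mesh$nodes[lip, 1])), p$pore_length0,
               tolerance = 0.01)
  ring <- mesh$node_sets$equatorial_ring
  r1 <- ring[mesh$node_cell[ring] == 1]
  r2 <- ring[mesh$node_cell[ring] == 2]
  expect_equal(min(mesh$nodes[r1, 2]) - max(mesh$nodes[r2, 2]),
               p$pore_width0, tolerance = 0.01 * p$pore_width0)
  expect_equal(diff(range(mesh$nodes[, 1])), p$complex_length,
               tolerance = 1e-8)
  expect_equal(diff(range(mesh$nodes[, 2])), p$complex_width,
               tolerance = 1e-8)
})

test_that("each guard-cell wall is a closed orientable surface", {
  mesh <- small_mesh()
  for (cell in 1:2) {
    expect_identical(mesh_euler_characteristic(mesh, cell), 2L)
    el <- mesh$elems[mesh$cell == cell, ]
    ed <- rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])
    key <- paste(ed[, 1], ed[, 2])
    # consistent orientation: every directed edge appears exactly once and
    # its reverse exists
    expect_false(any(duplicated(key)))
    expect_true(all(key %in% paste(ed[, 2], ed[, 1])))
    expect_gt(mesh_cell_volume(mesh, cell), 0)
  }
})

test_that("element count tracks the requested resolution", {
  for (res in c(500, 2000, 20000)) {
    mesh <- build_geometry(geometry_params(mesh_resolution = res))
    count <- sum(mesh$cell == 1)
    expect_lt(abs(count - res) / res, 0.2)
  }
})

test_that("the pair is mirror-symmetric through the long-axis midplane", {
  mesh <- small_mesh()
  refl <- mesh$nodes
  refl[, 2] <- -refl[, 2]
  # every reflected node must coincide with some node
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6), round(m[, 3], 6))
  expect_true(all(key(refl) %in% key(mesh$nodes)))
})

test_that("surface area converges under refinement", {
  a1 <- mesh_surface_area(build_geometry(geometry_params(mesh_resolution = 2500)))
  a2 <- mesh_surface_area(build_geometry(geometry_params(mesh_resolution = 5000)))
  expect_lt(abs(a2 - a1) / a1, 0.005)
})

test_that("baseline thickness is uniform with thin polar walls", {
  mesh <- small_mesh()
  p <- mesh$params
  expect_true(all(mesh$thickness[mesh$patch != "polar_wall"] == p$t_wall))
  expect_true(all(mesh$thickness[mesh$patch == "polar_wall"] == p$t_pole))
  expect_equal(mean(mesh$thickness[mesh$patch == "ventral"]), 1.0)
})

test_that("rounded-triangular thickness peaks on the ventral wall and m_v scales it", {
  gp <- geometry_params(mesh_resolution = 300,
                        cross_section_kind = "rounded_triangular")
  mesh <- build_geometry(gp)
  walls <- mesh$patch != "polar_wall"
  expect_identical(
    as.character(mesh$patch[walls][which.max(mesh$thickness[walls])]),
    "ventral")
  expect_equal(mean(mesh$thickness[mesh$patch == "dorsal"]), gp$t_wall,
               tolerance = 0.02)
  gp11 <- geometry_params(mesh_resolution = 300, m_v = 1.1,
                          cross_section_kind = "rounded_triangular")
  m11 <- build_geometry(gp11)
  ratio <- mean(m11$thickness[m11$patch == "ventral"]) /
    mean(mesh$thickness[mesh$patch == "ventral"])
  expect_equal(ratio, 1.10, tolerance = 0.01)
  expect_equal(m11$thickness[m11$patch == "dorsal"],
               mesh$thickness[mesh$patch == "dorsal"])
})

test_that("fiber field is unit, tangent, circumferential and equivariant", {
  mesh <- small_mesh()
  expect_equal(unname(sqrt(rowSums(mesh$fiber^2))), rep(1, nrow(mesh$elems)),
               tolerance = 1e-9, ignore_attr = TRUE)
  nrm <- stomech:::tri_normals(mesh$nodes, mesh$elems)
  expect_lt(max(abs(rowSums(nrm * mesh$fiber))), 1e-6)
  # hoop direction: at the outermost dorsal line of the equator the fiber
  # must be perpendicular to the long axis tangent (here x)
  cent <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
             mesh$nodes[mesh$elems[, 3], ]) / 3
  dorsal_eq <- which(mesh$patch == "dorsal" & abs(cent[, 1]) < 4 &
                       mesh$cell == 1)
  expect_gt(length(dorsal_eq), 0)
  expect_lt(max(abs(mesh$fiber[dorsal_eq, 1])), 0.15)
  # equivariance under a rigid rotation
  th <- 0.7
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- mesh
  rot$nodes <- mesh$nodes %*% t(Q)
  rot <- assign_fiber_field(rot)
  expect_equal(unname(abs(rowSums((mesh$fiber %*% t(Q)) * rot$fiber))),
               rep(1, nrow(mesh$elems)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("zero-area elements are reported by name", {
  mesh <- small_mesh()
  bad <- mesh
  bad$nodes[bad$elems[5, 2], ] <- bad$nodes[bad$elems[5, 1], ]
  expect_error(assign_fiber_field(bad), "zero-area")
})

test_that("VTK export writes a readable legacy mesh file", {
  mesh <- small_mesh()
  path <- tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, path)
  lines <- readLines(path)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("^CELLS", lines)))
  expect_true(any(grepl("SCALARS thickness", lines)))
  expect_true(any(grepl("VECTORS fiber", lines)))
})

test_that("geometry config round-trips through YAML", {
  path <- tempfile(fileext = ".yml")
  writeLines(c("complex_length: 40", "pore_length0: 15",
               "cross_section_kind: rounded_triangular",
               "mesh_resolution: 500"), path)
  p <- read_geometry_config(path)
  expect_equal(p$complex_length, 40)
  expect_equal(p$a_p, 7.5)
  expect_identical(p$cross_section_kind, "rounded_triangular")
})
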