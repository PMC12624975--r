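# Solver verification on small problems: patch test, rigid motion,
# energy-residual consistency, displacement field contracts.

test_that("patch test: affine boundary data reproduces homogeneous deformation", {
  m <- arraystrain:::box_tet10_mesh(100, 100, 100, c(3, 3, 3))
  A <- matrix(c(0.02, 0.01, 0, 0.005, -0.01, 0.002, 0, 0.003, 0.015), 3, byrow = TRUE)
  uaff <- m$nodes %*% t(A)
  sol <- arraystrain:::fem_solve(
    m$nodes, m$tets, m$region, list(ogden_material()),
    list(list(nodes = m$sets$boundary, value = uaff[m$sets$boundary, , drop = FALSE])),
    solver_control(n_load_steps = 1))
  expect_lt(max(abs(sol$u - uaff)) / max(abs(uaff)), 1e-8)
})

test_that("rigid translation produces zero strain", {
  m <- arraystrain:::box_tet10_mesh(80, 80, 80, c(2, 2, 3))
  sol <- arraystrain:::fem_solve(
    m$nodes, m$tets, m$region, list(ogden_material()),
    list(list(nodes = m$sets$boundary, value = c(5, 3, 0))),
    solver_control(n_load_steps = 1))
  out <- strain_from_displacement(m, sol)
  expect_lt(max(out$von_mises), 1e-8)
})

test_that("zero displacement yields the zero field", {
  m <- arraystrain:::box_tet10_mesh(50, 50, 50, c(2, 2, 2))
  sol <- arraystrain:::fem_solve(
    m$nodes, m$tets, m$region, list(ogden_material()),
    list(list(nodes = m$sets$boundary, value = c(0, 0, 0))),
    solver_control(n_load_steps = 1))
  expect_equal(max(abs(sol$u)), 0)
  out <- strain_from_displacement(m, sol)
  expect_equal(max(out$von_mises), 0)
})

test_that("assembled residual is the gradient of the total energy", {
  m <- arraystrain:::box_tet10_mesh(60, 60, 60, c(2, 2, 2))
  nn <- nrow(m$nodes)
  dofmap <- seq_len(3L * nn) - 1L # all free for this check
  mp <- matrix(arraystrain:::mat_row(ogden_material()), 1)
  set.seed(10)
  u <- rnorm(3 * nn, 0, 0.4)
  a0 <- arraystrain:::.fem_assemble_cpp(m$nodes, m$tets, m$region, mp, u,
                                        as.integer(dofmap), 3L * nn,
                                        integer(0), numeric(0), FALSE)
  h <- 1e-6
  set.seed(11)
  for (dof in sample.int(3 * nn, 12)) {
    up <- u; up[dof] <- up[dof] + h
    um <- u; um[dof] <- um[dof] - h
    ep <- arraystrain:::.fem_assemble_cpp(m$nodes, m$tets, m$region, mp, up,
                                          as.integer(dofmap), 3L * nn,
                                          integer(0), numeric(0), FALSE)$energy
    em <- arraystrain:::.fem_assemble_cpp(m$nodes, m$tets, m$region, mp, um,
                                          as.integer(dofmap), 3L * nn,
                                          integer(0), numeric(0), FALSE)$energy
    expect_equal(a0$res[dof], (ep - em) / (2 * h),
                 tolerance = 1e-5 * max(1, abs(a0$res[dof])))
  }
})

test_that("Hencky recovery reproduces a pure stretch exactly", {
  m <- arraystrain:::box_tet10_mesh(40, 40, 40, c(2, 2, 2))
  # impose F = diag(exp(0.1), 1, 1) via x-displacement u_x = (e^0.1 - 1) x
  u <- cbind((exp(0.1) - 1) * m$nodes[, 1], 0, 0)
  disp <- structure(list(u = u), class = "displacement_field")
  sf <- strain_from_displacement(m, disp, nu_eff = 0.5)
  # Hencky tensor diag(0.1, 0, 0) at every node
  expect_equal(max(abs(sf$eps[, 1] - 0.1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(sf$eps[, 2:6])), 0, tolerance = 1e-9)
  expect_equal(sf$von_mises, rep(0.1 / 1.5 * sqrt(1.0) * sqrt(1), nrow(u)),
               tolerance = 1e-9)
})

test_that("rigid-mode micromotion solve has the documented structure", {
  mesh <- coarse_shank_mesh()
  disp <- solve_static(mesh, boundary_conditions(10, 0),
                       control = solver_control())
  # array nodes carry the full driven displacement, bottom is fixed
  expect_equal(disp$u[mesh$sets$array_nodes, 2],
               rep(10, length(mesh$sets$array_nodes)))
  expect_equal(max(abs(disp$u[setdiff(mesh$sets$tissue_bottom,
                                      mesh$sets$array_nodes), ])), 0)
  expect_true(all(diff(unique(disp$convergence$t)) > 0))
  sf <- strain_from_displacement(mesh, disp)
  tab <- electrode_strain_table(sf)
  expect_gte(tab$max_strain[1], tab$avg_strain[1])
  expect_gt(tab$avg_strain[1], 0)
})

test_that("solver is deterministic and its two backends agree", {
  mesh <- coarse_shank_mesh()
  d1 <- solve_static(mesh, boundary_conditions(5, 0),
                     control = solver_control(linear_solver = "direct"))
  d1b <- solve_static(mesh, boundary_conditions(5, 0),
                      control = solver_control(linear_solver = "direct"))
  expect_identical(d1$u, d1b$u)
  d2 <- solve_static(mesh, boundary_conditions(5, 0),
                     control = solver_control(linear_solver = "pcg"))
  expect_lt(max(abs(d1$u - d2$u)), 1e-5)
})

test_that("zero displacement yields a zero micromotion field", {
  mesh <- coarse_shank_mesh()
  disp <- solve_static(mesh, boundary_conditions(0, 0))
  expect_equal(max(abs(disp$u)), 0)
  tab <- electrode_strain_table(strain_from_displacement(mesh, disp))
  expect_equal(tab$avg_strain, 0)
  expect_equal(tab$max_strain, 0)
})

test_that("elastic mode solves the silicon region and drives the top face", {
  mesh <- coarse_shank_mesh()
  # at this resolution the voxelized shank is not contiguous: the solver
  # must say so rather than silently produce a compliant array
  expect_warning(
    de <- solve_static(mesh, boundary_conditions(2, 0), mode = "elastic"),
    "contiguous|not meaningful")
  expect_equal(de$u[mesh$sets$array_top, 2],
               rep(2, length(mesh$sets$array_top)))
  expect_true(all(is.finite(de$u)))
})
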