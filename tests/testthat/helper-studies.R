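# Desk-scale study configurations shared by the verification tests and
# reused across test blocks (computed once per run).  Sizes are the
# package's documented desk-scale choices (see the methods vignette).

ring_ordering_case <- function() {
  fixture("ring_ordering_case", {
    geom <- build_geometry(array_spec(4, 4), tissue_spec())
    mesh <- generate_mesh(geom,
                          mesh_spec(tip_max_edge = 3, sphere_of_influence_radius = 3,
                                    global_target_edge = 300, grade_slope = 2),
                          half_x = TRUE)
    disp <- solve_static(mesh, boundary_conditions(10, 0),
                         control = solver_control(tol_rel = 1e-6))
    sf <- strain_from_displacement(mesh, disp)
    list(mesh = mesh, displacement = disp, strain = sf,
         table = electrode_strain_table(sf))
  })
}

convergence_study <- function() {
  fixture("convergence_study", {
    geom <- build_geometry(array_spec(1, 1), tissue_spec())
    mspec <- mesh_spec(tip_max_edge = 3, sphere_of_influence_radius = 3,
                       global_target_edge = 300, grade_slope = 2)
    rows <- lapply(c(3, 2, 1, 0.5), function(h) {
      ms <- mspec
      ms$tip_max_edge <- h
      mesh <- generate_mesh(geom, ms, half_x = TRUE)
      disp <- solve_static(mesh, boundary_conditions(10, 0),
                           control = solver_control(tol_rel = 1e-6))
      sf <- strain_from_displacement(mesh, disp)
      tab <- electrode_strain_table(sf)
      data.frame(tip_edge = h, avg_strain = tab$avg_strain[1],
                 max_strain = tab$max_strain[1],
                 n_elements = mesh$n_elements, n_nodes = mesh$n_nodes)
    })
    out <- do.call(rbind, rows)
    out$rel_error <- abs(out$avg_strain - out$avg_strain[nrow(out)]) /
      abs(out$avg_strain[nrow(out)])
    out
  })
}

magnitude_sweep_tables <- function() {
  fixture("magnitude_sweep_tables", {
    geom <- build_geometry(array_spec(4, 4), tissue_spec())
    mesh <- generate_mesh(geom,
                          mesh_spec(tip_max_edge = 30, sphere_of_influence_radius = 8,
                                    global_target_edge = 300, grade_slope = 2),
                          half_x = TRUE)
    sw <- solve_magnitude_sweep(mesh, c(1, 5, 10, 20, 50),
                                control = solver_control(tol_rel = 1e-6))
    lapply(sw, `[[`, "table")
  })
}

angle_sweep_tables <- function() {
  fixture("angle_sweep_tables", {
    geom <- build_geometry(array_spec(4, 4), tissue_spec())
    mesh <- generate_mesh(geom,
                          mesh_spec(tip_max_edge = 30, sphere_of_influence_radius = 8,
                                    global_target_edge = 300, grade_slope = 2))
    # the angle-0 edge > interior ordering is already established by the
    # magnitude sweep; the full-domain mesh is needed only off-axis
    out <- lapply(c(22.5, 45), function(ang) {
      disp <- solve_static(mesh, boundary_conditions(10, ang),
                           control = solver_control(tol_rel = 1e-6))
      electrode_strain_table(strain_from_displacement(mesh, disp))
    })
    names(out) <- c("22.5", "45")
    out
  })
}

group_means <- function(tab) {
  sapply(split(tab$avg_strain, tab$group), mean)
}
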