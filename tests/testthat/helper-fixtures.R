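# Shared fixtures.  Heavy finite-element results are computed lazily and
# cached for the whole test run; every fixture is generated in code.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# coarse single-shank mesh with a reduced tissue block: cheap enough for
# repeated solver unit tests
coarse_shank_mesh <- function() {
  fixture("coarse_shank_mesh", {
    geom <- build_geometry(array_spec(1, 1),
                           tissue_spec(margin_below_tips = 400, margin_lateral = 600))
    generate_mesh(geom, mesh_spec(tip_max_edge = 12, sphere_of_influence_radius = 10,
                                  global_target_edge = 400))
  })
}

# synthetic strain field on a regular node cloud (no FEM solve): von Mises
# values given by `fn(r)` around a nominal tip at the origin
synthetic_strain_field <- function(fn, spacing = 1.5, extent = 55) {
  g <- seq(-extent, extent, by = spacing)
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
  r <- sqrt(rowSums(nodes^2))
  structure(list(
    von_mises = fn(r),
    n_contrib = rep(1L, nrow(nodes)),
    nu_eff = 0.5,
    mesh = list(nodes = nodes, sets = list(array_nodes = integer(0)), geom = NULL)
  ), class = "strain_field")
}
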