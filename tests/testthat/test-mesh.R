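test_that("every element is a 10-node tetrahedron with positive volume", {
  mesh <- coarse_shank_mesh()
  expect_equal(ncol(mesh$tets), 10)
  vol <- arraystrain:::.tet_volumes_cpp(mesh$nodes[seq_len(mesh$n_vertex), ],
                                        mesh$tets[, 1:4])
  expect_true(all(vol > 0))
  # midside nodes sit at the edge midpoints of their parent vertices
  mp <- mesh$midside_parents
  mid <- mesh$nodes[mesh$n_vertex + seq_len(nrow(mp)), ]
  expect_equal(mid, (mesh$nodes[mp[, 1], ] + mesh$nodes[mp[, 2], ]) / 2)
})

test_that("tip spheres of influence bound the local edge lengths", {
  geom <- build_geometry(array_spec(1, 1),
                         tissue_spec(margin_below_tips = 500, margin_lateral = 800))
  spec <- mesh_spec(tip_max_edge = 6, sphere_of_influence_radius = 10,
                    global_target_edge = 350)
  mesh <- generate_mesh(geom, spec)
  el <- arraystrain:::tip_edge_lengths(mesh, geom$tips[1, ], 10)
  expect_true(length(el) > 0)
  expect_lte(max(el), 6 * (1 + 1e-6))
})

test_that("mesh refinement holds simultaneously at every tip of an array", {
  geom <- build_geometry(array_spec(2, 2),
                         tissue_spec(margin_below_tips = 400, margin_lateral = 600))
  mesh <- generate_mesh(geom, mesh_spec(tip_max_edge = 8,
                                        sphere_of_influence_radius = 8,
                                        global_target_edge = 350))
  for (k in 1:4) {
    el <- arraystrain:::tip_edge_lengths(mesh, geom$tips[k, ], 8)
    expect_lte(max(el), 8 * (1 + 1e-6))
  }
  expect_equal(sum(mesh$region == 2L) > 0, TRUE)
})

test_that("meshing is deterministic", {
  geom <- build_geometry(array_spec(1, 1),
                         tissue_spec(margin_below_tips = 500, margin_lateral = 800))
  spec <- mesh_spec(tip_max_edge = 10, sphere_of_influence_radius = 10,
                    global_target_edge = 350)
  m1 <- generate_mesh(geom, spec)
  m2 <- generate_mesh(geom, spec)
  expect_identical(m1$n_elements, m2$n_elements)
  expect_identical(m1$n_nodes, m2$n_nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$nodes, m2$nodes)
})

test_that("boundary node sets are present and consistent", {
  mesh <- coarse_shank_mesh()
  expect_true(all(lengths(mesh$sets[c("tissue_bottom", "array_top",
                                      "array_nodes", "interface")]) > 0))
  # interface nodes are shared by tissue and array elements (bonded contact)
  tn <- unique(as.vector(mesh$tets[mesh$region == 1L, ]))
  an <- unique(as.vector(mesh$tets[mesh$region == 2L, ]))
  expect_true(all(mesh$sets$interface %in% intersect(tn, an)))
  expect_true(length(mesh$sets$interface) > 0)
})

test_that("half-domain meshes keep only x >= 0 and tag the symmetry plane", {
  geom <- build_geometry(array_spec(2, 2),
                         tissue_spec(margin_below_tips = 400, margin_lateral = 600))
  mesh <- generate_mesh(geom, mesh_spec(tip_max_edge = 10,
                                        sphere_of_influence_radius = 8,
                                        global_target_edge = 350), half_x = TRUE)
  expect_gte(min(mesh$nodes[, 1]), -1e-9)
  expect_true(length(mesh$sets$sym_x) > 0)
})

test_that("VTU export writes a readable XML unstructured grid", {
  mesh <- coarse_shank_mesh()
  f <- tempfile(fileext = ".vtu")
  write_vtu(mesh, f, point_data = list(z = mesh$nodes[, 3]))
  txt <- readLines(f, n = 5)
  expect_match(txt[2], "VTKFile")
  doc <- xml2::read_xml(f)
  pieces <- xml2::xml_find_all(doc, "//Piece")
  expect_equal(as.integer(xml2::xml_attr(pieces, "NumberOfCells")), mesh$n_elements)
})
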