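test_that("tissue block extents follow the array footprint and shank length", {
  g10 <- build_geometry(array_spec(10, 10), tissue_spec())
  expect_equal(diff(g10$x_range), 8000) # 4000 + 2*2000
  expect_equal(diff(g10$y_range), 8000)
  expect_equal(g10$z_range[1], -2500)   # 1500 shank + 1000 below tips

  g106 <- build_geometry(array_spec(10, 6), tissue_spec())
  expect_equal(sort(c(diff(g106$x_range), diff(g106$y_range))), c(6400, 8000))

  g1 <- build_geometry(array_spec(1, 1), tissue_spec())
  expect_equal(nrow(g1$tips), 1)
  expect_equal(g1$tips[1, ], c(x = 0, y = 0, z = -1500))
})

test_that("invalid array geometry is rejected", {
  expect_error(array_spec(4, 4, pitch = 100), "overlapping")
  expect_error(tissue_spec(margin_lateral = 0))
  expect_error(mesh_spec(tip_max_edge = 10, global_target_edge = 5))
})

test_that("shank cross-section tapers from the base square to the tip circle", {
  a <- array_spec(1, 1)
  geom <- build_geometry(a, tissue_spec())
  # near the base: inside at the square half-width, outside past the corner radius
  expect_true(inside_array(geom, 70, 0, -1))
  expect_false(inside_array(geom, 80, 0, -1))
  # at the taper end the radius is the tip minor radius (5 um)
  expect_true(inside_array(geom, 4.5, 0, -1489))
  expect_false(inside_array(geom, 6, 0, -1489))
  # tip apex
  expect_true(inside_array(geom, 0, 0, -1499.5))
  expect_false(inside_array(geom, 3, 0, -1499.5))
  # base substrate is closed at z = 0 under the footprint
  expect_true(inside_array(geom, 100, 100, 0))
  expect_false(inside_array(geom, 300, 0, 0))
})

test_that("ring labels partition all three study grids with a corner group", {
  counts <- function(rows, cols) table(ring_labels(rows, cols)$group)
  c10 <- counts(10, 10)
  expect_equal(as.integer(c10[c("corner", "ring5", "ring4", "ring3", "ring2", "ring1")]),
               c(4, 32, 28, 20, 12, 4))
  c8 <- counts(8, 8)
  expect_equal(as.integer(c8[c("corner", "ring4", "ring3", "ring2", "ring1")]),
               c(4, 24, 20, 12, 4))
  expect_equal(sum(counts(10, 6)), 60)
  expect_equal(sum(c10), 100)
  expect_equal(sum(c8), 64)
  # 2x2: all four electrodes are corners
  expect_true(all(ring_labels(2, 2)$is_corner))
})

test_that("connectivity presets reproduce the standard unconnected counts", {
  expect_equal(sum(!connectivity_preset(10, 10, "corners")), 4)
  p2 <- connectivity_preset(10, 10, "corner_triples")
  expect_equal(sum(!p2), 12)
  rl <- ring_labels(10, 10)
  expect_true(all(!p2[rl$is_corner])) # every corner is removed
  cb <- connectivity_preset(10, 6, "checkerboard")
  expect_equal(sum(cb), 30)
})

test_that("neighbor map is the Moore adjacency restricted to connected electrodes", {
  nb <- neighbor_map(10, 10)
  sizes <- lengths(nb)
  expect_equal(sort(unique(sizes)), c(3, 5, 8))
  rl <- ring_labels(10, 10)
  expect_true(all(sizes[rl$is_corner] == 3))
  inner <- rl$row > 0 & rl$row < 9 & rl$col > 0 & rl$col < 9
  expect_true(all(sizes[inner] == 8))
  edge <- !inner & !rl$is_corner
  expect_true(all(sizes[edge] == 5))
  # disconnected electrodes drop out of all lists
  con <- connectivity_preset(10, 10, "corners")
  nb2 <- neighbor_map(10, 10, con)
  expect_equal(lengths(nb2)[rl$is_corner], rep(0L, 4), ignore_attr = TRUE)
  expect_false(any(vapply(nb2, function(v) any(!con[v]), TRUE)))
})

test_that("electrode layout carries tips, groups and connectivity", {
  lay <- electrode_layout(array_spec(4, 4), "corners")
  expect_equal(nrow(lay), 16)
  expect_equal(sum(!lay$connected), 4)
  expect_equal(max(abs(lay$tip_x)), 600) # (4-1)/2 * 400
  expect_equal(unique(lay$tip_z), -1500)
  f <- tempfile(fileext = ".csv")
  write_layout_csv(lay, f)
  back <- read.csv(f)
  expect_equal(back$tip_x, lay$tip_x)
})
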