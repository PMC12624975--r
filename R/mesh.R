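# Conforming quadratic-tetrahedron meshing of the array + tissue model.
#
# Strategy: a graded tensor-product hexahedral background grid is split
# into tetrahedra (Freudenthal/Kuhn pattern, conforming across cells),
# then refined by Maubach newest-vertex bisection towards the shank tips
# until every element intersecting a tip's sphere of influence has edges
# no longer than the requested tip edge length.  Elements are tagged
# tissue/array by centroid membership in the implicit array solid, so the
# bonded contact is realized as a single conforming mesh with shared
# interface nodes (stair-step interface at the local mesh resolution).
# Midside nodes are inserted afterwards to form 10-node tetrahedra.

# geometric sequence of breakpoints from `from` towards `to` (either side),
# starting at step h0 and growing by `growth`
grow_breaks <- function(from, to, h0, growth) {
  if (abs(to - from) < 1e-9) return(numeric(0))
  s <- sign(to - from)
  br <- numeric(0)
  x <- from
  h <- h0
  while (s * (to - x) > 1e-9) {
    h <- h * growth
    x2 <- x + s * h
    if (s * (to - x2) < 0.45 * h) x2 <- to
    br <- c(br, x2)
    x <- x2
  }
  br
}

# breakpoints for one axis: uniform core over the footprint, geometric
# growth towards the domain boundaries
axis_breaks <- function(fp_lo, fp_hi, lo, hi, h0, growth) {
  # even core count keeps the midplane (x = 0) as a breakpoint, which the
  # half-domain symmetry mode relies on
  ncore <- max(2, 2 * ceiling((fp_hi - fp_lo) / h0 / 2))
  core <- seq(fp_lo, fp_hi, length.out = ncore + 1)
  h <- (fp_hi - fp_lo) / ncore
  sort(unique(c(rev(grow_breaks(fp_lo, lo, h, growth)), core,
                grow_breaks(fp_hi, hi, h, growth))))
}

# Kuhn (Freudenthal) split of a structured hex grid into 6 tets per cell;
# conforming because every cell uses the same diagonal orientation.
kuhn_split <- function(bx, by, bz) {
  nx <- length(bx) - 1; ny <- length(by) - 1; nz <- length(bz) - 1
  nodes <- as.matrix(expand.grid(x = bx, y = by, z = bz))
  vid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  cells <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  i <- cells$i; j <- cells$j; k <- cells$k
  corner <- function(di, dj, dk) vid(i + di, j + dj, k + dk)
  v <- list(
    c000 = corner(0, 0, 0), c100 = corner(1, 0, 0),
    c010 = corner(0, 1, 0), c110 = corner(1, 1, 0),
    c001 = corner(0, 0, 1), c101 = corner(1, 0, 1),
    c011 = corner(0, 1, 1), c111 = corner(1, 1, 1))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  key <- function(d) paste0("c", d[1], d[2], d[3])
  tets <- vector("list", 6)
  for (p in seq_along(perms)) {
    pm <- perms[[p]]
    d0 <- c(0, 0, 0); d1 <- d0; d1[pm[1]] <- 1; d2 <- d1; d2[pm[2]] <- 1
    tets[[p]] <- cbind(v[[key(d0)]], v[[key(d1)]], v[[key(d2)]], v[[key(c(1, 1, 1))]])
  }
  # NOTE: vertex order is the Kuhn path ordering required by the Maubach
  # bisection tags; orientation is normalized only after refinement.
  list(nodes = nodes, tets = do.call(rbind, tets))
}

# swap two vertices of negatively oriented tets (after refinement, when
# the bisection-tag ordering is no longer needed)
fix_orientation <- function(nodes, T4) {
  vol <- .tet_volumes_cpp(nodes, T4)
  neg <- vol < 0
  if (any(neg)) T4[neg, c(3, 4)] <- T4[neg, c(4, 3)]
  T4
}

#' Generate the conforming quadratic tetrahedral mesh
#'
#' Meshes the tissue block with the embedded array solid, refining towards
#' every shank tip so that all elements intersecting the sphere of
#' influence have edge lengths of at most `spec$tip_max_edge`.  Fully
#' deterministic: the same geometry and mesh specification always yield
#' the identical mesh.
#'
#' @param geom An [build_geometry()] result.
#' @param spec A [mesh_spec()].
#' @param half_x Mesh only the half-space x >= 0 and tag the symmetry
#'   plane.  Valid for geometries and loads that are mirror-symmetric
#'   about the x = 0 plane (displacement along Y); [solve_static()] then
#'   imposes the symmetry condition u_x = 0 on the plane and
#'   [electrode_strain_table()] evaluates mirrored tips at their image
#'   position.
#' @return Object of class `tet_mesh`: `nodes` (n x 3, um), `tets`
#'   (ne x 10, 1-based; first 4 columns are vertices), `region` (1 =
#'   tissue, 2 = array), node sets (`tissue_bottom`, `array_top`,
#'   `array_nodes`, `interface`) and provenance metadata.
#' @export
generate_mesh <- function(geom, spec, half_x = FALSE) {
  stopifnot(inherits(geom, "array_geometry"), inherits(spec, "mesh_spec"))
  a <- geom$array
  h0 <- spec$global_target_edge
  gr <- spec$far_growth
  fx <- geom$footprint[1]; fy <- geom$footprint[2]
  bx <- axis_breaks(-fx, fx, geom$x_range[1], geom$x_range[2], h0, gr)
  by <- axis_breaks(-fy, fy, geom$y_range[1], geom$y_range[2], h0, gr)
  # z: uniform core from just below the tips to the base underside, slab
  # above, geometric growth below
  ztip <- -a$total_shank_length
  zcore_lo <- ztip - min(2 * spec$sphere_of_influence_radius, geom$tissue$margin_below_tips / 2)
  ncz <- max(1, ceiling((0 - zcore_lo) / h0))
  zcore <- seq(zcore_lo, 0, length.out = ncz + 1)
  zslab <- seq(0, geom$z_range[2], length.out = max(1, ceiling(a$base_lz / h0)) + 1)
  bz <- sort(unique(c(grow_breaks(zcore_lo, geom$z_range[1], (0 - zcore_lo) / ncz, gr),
                      zcore, zslab)))
  bg <- kuhn_split(bx, by, bz)

  ref <- .refine_tets_cpp(bg$nodes, bg$tets, geom$tips,
                          spec$tip_max_edge, spec$sphere_of_influence_radius,
                          spec$grade_slope, 500L)
  V <- ref$nodes
  T4 <- fix_orientation(V, ref$tets)

  cx <- (V[T4[, 1], 1] + V[T4[, 2], 1] + V[T4[, 3], 1] + V[T4[, 4], 1]) / 4
  cy <- (V[T4[, 1], 2] + V[T4[, 2], 2] + V[T4[, 3], 2] + V[T4[, 4], 2]) / 4
  cz <- (V[T4[, 1], 3] + V[T4[, 2], 3] + V[T4[, 3], 3] + V[T4[, 4], 3]) / 4
  in_arr <- inside_array(geom, cx, cy, cz)
  void <- cz > 0 & !in_arr
  if (half_x) void <- void | cx < 0
  keep <- !void
  T4 <- T4[keep, , drop = FALSE]
  region <- ifelse(in_arr[keep], 2L, 1L)

  # drop vertices orphaned by void removal
  used <- sort(unique(as.vector(T4)))
  remap <- integer(nrow(V)); remap[used] <- seq_along(used)
  V <- V[used, , drop = FALSE]
  T4 <- matrix(remap[T4], ncol = 4)

  vol <- .tet_volumes_cpp(V, T4)
  if (any(vol <= 0)) stop("meshing error: ", sum(vol <= 0), " non-positive element Jacobians")

  q <- .tet10_build_cpp(V, T4)
  nodes <- q$nodes; T10 <- q$tets10

  tol <- 1e-6 * max(abs(geom$z_range))
  node_in_arr <- inside_array(geom, nodes[, 1], nodes[, 2], nodes[, 3])
  arr_tets <- region == 2L
  arr_el_nodes <- sort(unique(as.vector(T10[arr_tets, , drop = FALSE])))
  array_nodes <- sort(unique(c(arr_el_nodes, which(node_in_arr))))
  tissue_nodes <- sort(unique(as.vector(T10[!arr_tets, , drop = FALSE])))
  sets <- list(
    tissue_bottom = which(abs(nodes[, 3] - geom$z_range[1]) < tol),
    array_top = which(abs(nodes[, 3] - geom$z_range[2]) < tol &
                        abs(nodes[, 1]) <= fx + tol & abs(nodes[, 2]) <= fy + tol),
    array_nodes = array_nodes,
    interface = intersect(arr_el_nodes, tissue_nodes)
  )
  if (half_x) sets$sym_x <- which(abs(nodes[, 1]) < tol)
  if (any(vapply(sets, length, 1L) == 0))
    stop("meshing error: empty boundary node set")

  structure(list(
    nodes = nodes, tets = T10, n_vertex = nrow(V), region = region,
    midside_parents = q$midside_parents, half_x = half_x,
    sets = sets, tips = geom$tips, geom = geom, spec = spec,
    n_elements = nrow(T10), n_nodes = nrow(nodes),
    provenance = list(refine_passes = ref$passes,
                      background_cells = c(length(bx), length(by), length(bz)) - 1L)
  ), class = "tet_mesh")
}

#' @exportS3Method base::print
print.tet_mesh <- function(x, ...) {
  cat("Quadratic tetrahedral mesh:", x$n_elements, "elements,",
      x$n_nodes, "nodes (", x$n_vertex, "vertices )\n")
  cat("  regions: tissue", sum(x$region == 1L), "| array", sum(x$region == 2L), "\n")
  cat("  tip edge", x$spec$tip_max_edge, "um in", x$spec$sphere_of_influence_radius,
      "um spheres at", nrow(x$tips), "tips\n")
  invisible(x)
}

# all unique vertex-edge lengths of elements whose minimum vertex distance
# to `tip` is below `radius` (used by tests and mesh diagnostics)
tip_edge_lengths <- function(mesh, tip, radius) {
  V <- mesh$nodes[seq_len(mesh$n_vertex), , drop = FALSE]
  T4 <- mesh$tets[, 1:4, drop = FALSE]
  d2 <- (V[, 1] - tip[1])^2 + (V[, 2] - tip[2])^2 + (V[, 3] - tip[3])^2
  near_v <- d2 <= radius^2
  sel <- near_v[T4[, 1]] | near_v[T4[, 2]] | near_v[T4[, 3]] | near_v[T4[, 4]]
  if (!any(sel)) return(numeric(0))
  Ts <- T4[sel, , drop = FALSE]
  ep <- rbind(Ts[, c(1, 2)], Ts[, c(1, 3)], Ts[, c(1, 4)],
              Ts[, c(2, 3)], Ts[, c(2, 4)], Ts[, c(3, 4)])
  sqrt(rowSums((V[ep[, 1], , drop = FALSE] - V[ep[, 2], , drop = FALSE])^2))
}

# structured quadratic-tet box mesh (verification problems: patch test,
# small-strain oracle on a plain block)
box_tet10_mesh <- function(lx = 1, ly = 1, lz = 1, n = c(2, 2, 2)) {
  bg <- kuhn_split(seq(0, lx, length.out = n[1] + 1),
                   seq(0, ly, length.out = n[2] + 1),
                   seq(0, lz, length.out = n[3] + 1))
  bg$tets <- fix_orientation(bg$nodes, bg$tets)
  q <- .tet10_build_cpp(bg$nodes, bg$tets)
  nodes <- q$nodes
  tol <- 1e-9 * max(lx, ly, lz)
  on_bnd <- abs(nodes[, 1]) < tol | abs(nodes[, 1] - lx) < tol |
    abs(nodes[, 2]) < tol | abs(nodes[, 2] - ly) < tol |
    abs(nodes[, 3]) < tol | abs(nodes[, 3] - lz) < tol
  structure(list(
    nodes = nodes, tets = q$tets10, n_vertex = q$n_vertex,
    midside_parents = q$midside_parents,
    region = rep(1L, nrow(q$tets10)),
    sets = list(boundary = which(on_bnd),
                bottom = which(abs(nodes[, 3]) < tol),
                top = which(abs(nodes[, 3] - lz) < tol)),
    n_elements = nrow(q$tets10), n_nodes = nrow(nodes)
  ), class = "tet_mesh")
}

#' Export a mesh (with optional nodal fields) as VTU
#'
#' Writes an ASCII VTK XML unstructured-grid file with quadratic
#' tetrahedra, the element region tag, and any nodal point-data fields
#' supplied (e.g. displacement components, von Mises strain).
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file.
#' @param point_data Named list of nodal vectors (length `n_nodes`) or
#'   matrices (`n_nodes` rows).
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  n <- mesh$n_nodes; ne <- mesh$n_elements
  # VTK_QUADRATIC_TETRA = 24; VTK edge order matches (1,2),(2,3),(1,3),
  # (1,4),(2,4),(3,4) -> permute our edge columns (5..10)
  perm <- c(1, 2, 3, 4, 5, 8, 6, 7, 9, 10)
  conn <- mesh$tets[, perm, drop = FALSE] - 1L
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n, '" NumberOfCells="', ne, '">')
  w("<Points><DataArray type='Float64' NumberOfComponents='3' format='ascii'>")
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("</DataArray></Points>")
  w("<Cells><DataArray type='Int64' Name='connectivity' format='ascii'>")
  writeLines(apply(conn, 1, paste, collapse = " "), con)
  w("</DataArray><DataArray type='Int64' Name='offsets' format='ascii'>")
  writeLines(as.character(seq_len(ne) * 10L), con)
  w("</DataArray><DataArray type='UInt8' Name='types' format='ascii'>")
  writeLines(as.character(rep(24L, ne)), con)
  w("</DataArray></Cells>")
  w("<CellData><DataArray type='Int32' Name='region' format='ascii'>")
  writeLines(as.character(mesh$region), con)
  w("</DataArray></CellData>")
  if (length(point_data)) {
    w("<PointData>")
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      w("<DataArray type='Float64' Name='", nm, "' NumberOfComponents='", nc,
        "' format='ascii'>")
      if (is.matrix(v)) writeLines(apply(v, 1, paste, collapse = " "), con)
      else writeLines(as.character(v), con)
      w("</DataArray>")
    }
    w("</PointData>")
  }
  w("</Piece></UnstructuredGrid></VTKFile>")
  invisible(path)
}
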