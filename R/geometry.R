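# Parametric array / tissue geometry and electrode layout structures.
# All lengths are micrometres; the consistent unit system is Pa-um-pN.
# Coordinate convention: base plane = XY with the origin at the array-base
# centre, shank axis = -Z (tips at z = -total_shank_length), "Y direction"
# displacement is in-plane lateral shear.

#' Array specification
#'
#' Dimensions of a bed-of-needles ("Utah") microelectrode array: a
#' rows x cols grid of tapered silicon shanks on a common base substrate.
#' Defaults follow standard commercial geometry: 400 um pitch, shanks
#' tapering from a 150 um x 150 um square at the base to a 10 um diameter
#' circle at 1.49 mm, capped by a revolved quarter ellipse (major radius
#' 10 um along the axis, minor radius 5 um) for a total shank length of
#' 1.5 mm.  Base extents default to `pitch * (n - 1) + 400` per side
#' (4 mm x 4 mm for a 10 x 10 grid) with a 200 um thick substrate.
#'
#' @param rows,cols Grid dimensions (rows along y, cols along x).
#' @param pitch Electrode spacing, um.
#' @param base_lx,base_ly,base_lz Base substrate extents, um.
#' @param shank_base_side Side of the square shank cross-section at the
#'   base, um.
#' @param shank_taper_length Length of the square-to-circle taper, um.
#' @param tip_major_radius,tip_minor_radius Quarter-ellipse tip cap radii
#'   (major along the shank axis), um.
#' @param shank_profile `"superellipse"` lofts the cross-section through
#'   superellipses interpolating exponent from square to circle;
#'   `"frustum"` is a documented fallback approximating the shank as a
#'   circular frustum with matched tip geometry.
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(rows, cols, pitch = 400,
                       base_lx = pitch * (cols - 1) + 400,
                       base_ly = pitch * (rows - 1) + 400,
                       base_lz = 200,
                       shank_base_side = 150,
                       shank_taper_length = 1490,
                       tip_major_radius = 10,
                       tip_minor_radius = 5,
                       shank_profile = c("superellipse", "frustum")) {
  stopifnot(rows >= 1, cols >= 1, pitch > 0, base_lz > 0)
  shank_profile <- match.arg(shank_profile)
  total <- shank_taper_length + tip_major_radius
  if (rows > 1 || cols > 1) {
    if (pitch <= shank_base_side)
      stop("overlapping shanks: pitch (", pitch, " um) must exceed shank_base_side (",
           shank_base_side, " um)")
  }
  if (pitch * (cols - 1) > base_lx || pitch * (rows - 1) > base_ly)
    stop("grid does not fit on the base substrate at this pitch")
  structure(list(
    rows = as.integer(rows), cols = as.integer(cols), pitch = pitch,
    base_lx = base_lx, base_ly = base_ly, base_lz = base_lz,
    shank_base_side = shank_base_side,
    shank_taper_length = shank_taper_length,
    tip_major_radius = tip_major_radius,
    tip_minor_radius = tip_minor_radius,
    total_shank_length = total,
    shank_profile = shank_profile
  ), class = "array_spec")
}

#' Tissue block specification
#'
#' The surrounding cortical tissue is a rectangular prism extending
#' `margin_below_tips` beyond the electrode tips and `margin_lateral`
#' outward from the base on all sides.
#'
#' @param margin_below_tips,margin_lateral Margins, um (defaults 1000 and
#'   2000).
#' @export
tissue_spec <- function(margin_below_tips = 1000, margin_lateral = 2000) {
  stopifnot(margin_below_tips > 0, margin_lateral > 0)
  structure(list(margin_below_tips = margin_below_tips,
                 margin_lateral = margin_lateral), class = "tissue_spec")
}

#' Mesh control specification
#'
#' Controls quadratic-tetrahedron mesh generation.  A sphere of influence
#' of radius `sphere_of_influence_radius` at each shank tip constrains all
#' element edges of intersecting elements to at most `tip_max_edge`.
#' `global_target_edge` sets the background cell size near the array;
#' `grade_slope` controls how fast the element size may grow with distance
#' from the tip spheres (dimensionless, edge growth per unit distance).
#'
#' The full-fidelity tip edge is 1 um inside a 10 um sphere; relaxed
#' settings (2-3 um) are intended for full-array desk-scale runs.
#'
#' @param tip_max_edge Maximum edge length near tips, um.
#' @param sphere_of_influence_radius Refinement sphere radius, um.
#' @param global_target_edge Background element size near the array, um.
#' @param far_growth Geometric growth ratio of background cells away from
#'   the array footprint.
#' @param grade_slope Size-field growth rate outside the tip spheres.
#' @param element_order Always 2 (10-node tetrahedra).
#' @export
mesh_spec <- function(tip_max_edge = 1, sphere_of_influence_radius = 10,
                      global_target_edge = 150, far_growth = 1.7,
                      grade_slope = 0.9, element_order = 2L) {
  stopifnot(tip_max_edge > 0, sphere_of_influence_radius > 0,
            tip_max_edge <= global_target_edge, far_growth > 1,
            grade_slope > 0)
  if (element_order != 2L) stop("only 2nd order (10-node) tetrahedra are supported")
  structure(list(tip_max_edge = tip_max_edge,
                 sphere_of_influence_radius = sphere_of_influence_radius,
                 global_target_edge = global_target_edge,
                 far_growth = far_growth,
                 grade_slope = grade_slope,
                 element_order = 2L), class = "mesh_spec")
}

#' Concentric ring labels with a separate corner group
#'
#' Electrodes are grouped by the number of rows/columns away from the edge
#' of the array, generating concentric electrode rings; the outermost ring
#' carries the largest label and the four corner electrodes form their own
#' group.
#'
#' @param rows,cols Grid dimensions.
#' @return A data.frame with `row`, `col` (0-based), `ring_label`
#'   (1 = innermost), `is_corner`, and `group` (factor, `"corner"` or
#'   `"ring<k>"`).
#' @export
ring_labels <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  g <- expand.grid(col = 0:(cols - 1), row = 0:(rows - 1))
  d <- pmin(g$row, rows - 1 - g$row, g$col, cols - 1 - g$col)
  nring <- ceiling(min(rows, cols) / 2)
  ring <- nring - d
  corner <- (g$row %in% c(0, rows - 1)) & (g$col %in% c(0, cols - 1))
  grp <- ifelse(corner, "corner", paste0("ring", ring))
  lev <- c("corner", paste0("ring", sort(unique(ring[!corner]), decreasing = TRUE)))
  data.frame(row = g$row, col = g$col, ring_label = ring, is_corner = corner,
             group = factor(grp, levels = lev))
}

#' Connectivity-mask presets
#'
#' Standard patterns of unconnected electrodes: `"all"` (everything
#' connected), `"corners"` (the four corner electrodes unconnected),
#' `"corner_triples"` (three electrodes per corner unconnected: each corner
#' plus its two grid-adjacent electrodes, an L-shaped triple), and
#' `"checkerboard"` (alternate electrodes connected).
#'
#' @param rows,cols Grid dimensions.
#' @param preset Mask name.
#' @return Logical vector, length `rows * cols`, row-major over the grid
#'   (`TRUE` = connected).
#' @export
connectivity_preset <- function(rows, cols,
                                preset = c("all", "corners", "corner_triples",
                                           "checkerboard")) {
  preset <- match.arg(preset)
  g <- expand.grid(col = 0:(cols - 1), row = 0:(rows - 1))
  con <- rep(TRUE, nrow(g))
  corner_rc <- expand.grid(row = c(0, rows - 1), col = c(0, cols - 1))
  idx <- function(r, c) which(g$row == r & g$col == c)
  if (preset == "corners") {
    for (k in seq_len(nrow(corner_rc)))
      con[idx(corner_rc$row[k], corner_rc$col[k])] <- FALSE
  } else if (preset == "corner_triples") {
    for (k in seq_len(nrow(corner_rc))) {
      r <- corner_rc$row[k]; c <- corner_rc$col[k]
      dr <- if (r == 0) 1 else -1
      dc <- if (c == 0) 1 else -1
      con[idx(r, c)] <- FALSE
      con[idx(r + dr, c)] <- FALSE
      con[idx(r, c + dc)] <- FALSE
    }
  } else if (preset == "checkerboard") {
    con <- ((g$row + g$col) %% 2) == 0
  }
  con
}

#' Moore-neighborhood electrode adjacency
#'
#' Eight-connected grid adjacency restricted to connected electrodes
#' (3-8 neighbors depending on location for a fully connected array).
#'
#' @param rows,cols Grid dimensions (both at least 2).
#' @param connected Logical connectivity mask (row-major); electrodes that
#'   are not connected have empty neighbor lists and do not appear in any
#'   list.
#' @return List of integer vectors of electrode ids (row-major,
#'   1-based), one per electrode.
#' @export
neighbor_map <- function(rows, cols, connected = rep(TRUE, rows * cols)) {
  stopifnot(rows >= 2, cols >= 2, length(connected) == rows * cols)
  id <- function(r, c) r * cols + c + 1L
  out <- vector("list", rows * cols)
  for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
    me <- id(r, c)
    if (!connected[me]) { out[[me]] <- integer(0); next }
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 0 || rr >= rows || cc < 0 || cc >= cols) next
      other <- id(rr, cc)
      if (connected[other]) nb <- c(nb, other)
    }
    out[[me]] <- nb
  }
  out
}

#' Electrode layout table
#'
#' Per-electrode tip positions, ring labels, connectivity and neighbor
#' lists for an array.  Electrode ids are row-major over the grid.
#'
#' @param array An [array_spec()].
#' @param connected Logical connectivity mask or a preset name accepted by
#'   [connectivity_preset()].
#' @return A data.frame (class `electrode_layout`) with columns
#'   `electrode_id`, `row`, `col`, `tip_x`, `tip_y`, `tip_z`,
#'   `ring_label`, `is_corner`, `group`, `connected`,
#'   `dist_center`; the Moore neighbor map is attached as attribute
#'   `"neighbors"`.
#' @export
electrode_layout <- function(array, connected = "all") {
  stopifnot(inherits(array, "array_spec"))
  rl <- ring_labels(array$rows, array$cols)
  if (is.character(connected))
    connected <- connectivity_preset(array$rows, array$cols, connected)
  stopifnot(length(connected) == nrow(rl))
  tip_x <- (rl$col - (array$cols - 1) / 2) * array$pitch
  tip_y <- (rl$row - (array$rows - 1) / 2) * array$pitch
  out <- data.frame(
    electrode_id = seq_len(nrow(rl)),
    row = rl$row, col = rl$col,
    tip_x = tip_x, tip_y = tip_y, tip_z = -array$total_shank_length,
    ring_label = rl$ring_label, is_corner = rl$is_corner, group = rl$group,
    connected = connected,
    dist_center = sqrt(tip_x^2 + tip_y^2)
  )
  if (array$rows >= 2 && array$cols >= 2)
    attr(out, "neighbors") <- neighbor_map(array$rows, array$cols, connected)
  class(out) <- c("electrode_layout", "data.frame")
  out
}

#' Write an electrode layout to CSV
#'
#' @param layout An [electrode_layout()].
#' @param path Output file.
#' @export
write_layout_csv <- function(layout, path) {
  cols <- c("electrode_id", "row", "col", "tip_x", "tip_y", "tip_z",
            "ring_label", "is_corner", "connected")
  utils::write.csv(as.data.frame(layout)[, cols], path, row.names = FALSE)
  invisible(path)
}

# Shank cross-section half-width (circumscribed radius for the frustum) at
# taper fraction t in [0, 1] (0 = base).
shank_halfwidth <- function(array, t) {
  (1 - t) * array$shank_base_side / 2 + t * array$tip_minor_radius
}

# Superellipse exponent interpolated from near-square at the base (n = 12)
# to circle (n = 2) at the taper end.
shank_exponent <- function(t) 2 + 10 * (1 - t)^2

#' Build the array + tissue solid model
#'
#' Constructs the implicit solid model of the array (base substrate,
#' tapered shanks, revolved quarter-ellipse tips) embedded in the tissue
#' block, in bonded contact (realized downstream as a single conforming
#' mesh with shared interface nodes).
#'
#' @param array An [array_spec()].
#' @param tissue A [tissue_spec()].
#' @return An object of class `array_geometry` holding domain extents, tip
#'   positions and the point-membership function used by the mesher.
#' @export
build_geometry <- function(array, tissue) {
  stopifnot(inherits(array, "array_spec"), inherits(tissue, "tissue_spec"))
  layout <- electrode_layout(array)
  ext_x <- array$base_lx / 2 + tissue$margin_lateral
  ext_y <- array$base_ly / 2 + tissue$margin_lateral
  depth <- array$total_shank_length + tissue$margin_below_tips
  geom <- structure(list(
    array = array, tissue = tissue, layout = layout,
    tips = cbind(x = layout$tip_x, y = layout$tip_y, z = layout$tip_z),
    x_range = c(-ext_x, ext_x), y_range = c(-ext_y, ext_y),
    z_range = c(-depth, array$base_lz),
    footprint = c(array$base_lx / 2, array$base_ly / 2)
  ), class = "array_geometry")
  geom
}

#' Point membership in the array solid
#'
#' Vectorized inside test used for mesh region tagging and rigid-mode
#' boundary conditions.  The base substrate is closed (points on the base
#' underside plane z = 0 under the footprint are inside, modelling the
#' bonded tissue-substrate contact).
#'
#' @param geom An [build_geometry()] result.
#' @param x,y,z Point coordinates, um.
#' @return Logical vector.
#' @export
inside_array <- function(geom, x, y, z) {
  a <- geom$array
  inside <- abs(x) <= a$base_lx / 2 & abs(y) <= a$base_ly / 2 &
    z >= 0 & z <= a$base_lz
  taper <- a$shank_taper_length
  total <- a$total_shank_length
  cand <- which(!inside & z < 0 & z >= -total)
  if (length(cand)) {
    # map each candidate point to its nearest shank axis via the grid
    px <- x[cand]; py <- y[cand]; pz <- z[cand]
    cx <- pmin(pmax(round(px / a$pitch + (a$cols - 1) / 2), 0), a$cols - 1)
    cy <- pmin(pmax(round(py / a$pitch + (a$rows - 1) / 2), 0), a$rows - 1)
    ax <- (cx - (a$cols - 1) / 2) * a$pitch
    ay <- (cy - (a$rows - 1) / 2) * a$pitch
    dx <- px - ax; dy <- py - ay
    hit <- rep(FALSE, length(cand))
    in_taper <- pz >= -taper
    if (any(in_taper)) {
      t <- -pz[in_taper] / taper
      w <- shank_halfwidth(a, t)
      if (a$shank_profile == "frustum") {
        hit[in_taper] <- dx[in_taper]^2 + dy[in_taper]^2 <= w^2
      } else {
        n <- shank_exponent(t)
        hit[in_taper] <- (abs(dx[in_taper]) / w)^n + (abs(dy[in_taper]) / w)^n <= 1
      }
    }
    in_cap <- !in_taper
    if (any(in_cap)) {
      s <- (-pz[in_cap] - taper) / a$tip_major_radius # 0..1
      r <- a$tip_minor_radius * sqrt(pmax(0, 1 - s^2))
      hit[in_cap] <- dx[in_cap]^2 + dy[in_cap]^2 <= r^2
    }
    inside[cand] <- hit
  }
  inside
}
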