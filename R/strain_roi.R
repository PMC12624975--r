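# ROI summarization: binned radial strain profiles around each electrode
# tip, volume-weighted averages over the 50 um recording sphere, maxima,
# and ring / radial-distance group summaries.

roi_node_ids <- function(sf) {
  ids <- which(sf$n_contrib > 0)
  setdiff(ids, sf$mesh$sets$array_nodes)
}

#' Binned radial strain profile around an electrode tip
#'
#' Tissue nodes within `radius` of the tip (nodes belonging to array
#' elements are excluded) are assigned to half-open radial bins
#' `[r, r + bin_width)` by Euclidean distance from the tip, and the mean
#' nodal von Mises strain per bin is reported together with the ideal
#' spherical-shell volume of each bin.  Shell volumes (rather than
#' mesh-dependent nodal volumes) de-bias the profile from local mesh
#' density.
#'
#' @param sf A `strain_field` from [strain_from_displacement()].
#' @param tip Tip coordinate (length-3, um).
#' @param radius ROI radius, um (default 50, the approximate single-unit
#'   recording distance).
#' @param bin_width Radial bin width, um (default 2.5).
#' @return data.frame of class `roi_profile`: `bin_lo`, `bin_hi`,
#'   `mean_strain` (NA for empty bins), `n_nodes`, `shell_volume` (um^3).
#' @export
roi_profile <- function(sf, tip, radius = 50, bin_width = 2.5) {
  stopifnot(inherits(sf, "strain_field"), length(tip) == 3)
  ids <- roi_node_ids(sf)
  X <- sf$mesh$nodes[ids, , drop = FALSE]
  d <- sqrt((X[, 1] - tip[1])^2 + (X[, 2] - tip[2])^2 + (X[, 3] - tip[3])^2)
  inroi <- d <= radius
  if (!any(inroi))
    stop("empty ROI: no tissue nodes within ", radius, " um of the tip")
  gx <- sf$mesh$geom
  if (!is.null(gx)) {
    ok <- tip[1] - radius >= gx$x_range[1] && tip[1] + radius <= gx$x_range[2] &&
      tip[2] - radius >= gx$y_range[1] && tip[2] + radius <= gx$y_range[2] &&
      tip[3] - radius >= gx$z_range[1]
    if (!ok) warning("ROI extends outside the tissue domain; shell volumes are not truncated")
  }
  nb <- ceiling(radius / bin_width)
  lo <- (seq_len(nb) - 1) * bin_width
  hi <- pmin(lo + bin_width, radius)
  bin <- pmin(floor(d[inroi] / bin_width) + 1L, nb)
  v <- sf$von_mises[ids][inroi]
  mean_strain <- rep(NA_real_, nb)
  agg <- tapply(v, bin, mean)
  mean_strain[as.integer(names(agg))] <- as.numeric(agg)
  n_nodes <- integer(nb)
  tb <- table(bin)
  n_nodes[as.integer(names(tb))] <- as.integer(tb)
  out <- data.frame(bin_lo = lo, bin_hi = hi,
                    mean_strain = mean_strain, n_nodes = n_nodes,
                    shell_volume = 4 * pi / 3 * (hi^3 - lo^3))
  attr(out, "tip") <- tip
  attr(out, "radius") <- radius
  class(out) <- c("roi_profile", "data.frame")
  out
}

#' Volume-weighted average ROI strain
#'
#' Binned mean strains normalized by the volume they occupy:
#' \eqn{\sum_b \bar\varepsilon_b V_b / \sum_b V_b} over non-empty bins,
#' where \eqn{V_b} is the ideal spherical-shell volume of bin b.
#'
#' @param profile An [roi_profile()].
#' @export
volume_weighted_average <- function(profile) {
  stopifnot(inherits(profile, "roi_profile"))
  use <- profile$n_nodes > 0
  if (!any(use)) stop("all ROI bins are empty")
  sum(profile$mean_strain[use] * profile$shell_volume[use]) /
    sum(profile$shell_volume[use])
}

#' Maximum nodal strain in the ROI
#'
#' @param sf A `strain_field`.
#' @param tip Tip coordinate, um.
#' @param radius ROI radius, um.
#' @export
max_strain <- function(sf, tip, radius = 50) {
  ids <- roi_node_ids(sf)
  X <- sf$mesh$nodes[ids, , drop = FALSE]
  d2 <- (X[, 1] - tip[1])^2 + (X[, 2] - tip[2])^2 + (X[, 3] - tip[3])^2
  sel <- d2 <= radius^2
  if (!any(sel)) stop("empty ROI: no tissue nodes within ", radius, " um of the tip")
  max(sf$von_mises[ids][sel])
}

#' Per-electrode ROI strain table
#'
#' Summarizes a solved strain field into one row per electrode:
#' volume-weighted average and maximum von Mises strain in the tip ROI,
#' with ring labels and distance from the array centre.
#'
#' @param sf A `strain_field` on an array mesh.
#' @param radius,bin_width ROI parameters, um.
#' @return data.frame of class `electrode_strain_table` with columns
#'   `electrode_id`, `row`, `col`, `ring_label`, `is_corner`, `group`,
#'   `connected`, `dist_center`, `avg_strain`, `max_strain`.  Radial
#'   profiles are attached as attribute `"profiles"`.
#' @export
electrode_strain_table <- function(sf, radius = 50, bin_width = 2.5) {
  stopifnot(inherits(sf, "strain_field"))
  layout <- sf$mesh$geom$layout
  profs <- vector("list", nrow(layout))
  avg <- mx <- numeric(nrow(layout))
  for (k in seq_len(nrow(layout))) {
    tip <- c(layout$tip_x[k], layout$tip_y[k], layout$tip_z[k])
    # on a half-domain (x >= 0) mesh, tips at x < 0 are evaluated at their
    # mirror image; the von Mises field is symmetric
    if (isTRUE(sf$mesh$half_x)) tip[1] <- abs(tip[1])
    profs[[k]] <- roi_profile(sf, tip, radius, bin_width)
    avg[k] <- volume_weighted_average(profs[[k]])
    mx[k] <- max_strain(sf, tip, radius)
  }

  out <- data.frame(
    electrode_id = layout$electrode_id, row = layout$row, col = layout$col,
    ring_label = layout$ring_label, is_corner = layout$is_corner,
    group = layout$group, connected = layout$connected,
    dist_center = layout$dist_center,
    avg_strain = avg, max_strain = mx)
  attr(out, "profiles") <- profs
  class(out) <- c("electrode_strain_table", "data.frame")
  out
}

#' Grouped strain summaries
#'
#' Groups per-electrode strains by concentric ring (corners separate) or
#' by distance from the array centre, producing the per-group means and
#' SDs fed to the ANOVA stage.
#'
#' @param table An [electrode_strain_table()] (or any data.frame with
#'   `avg_strain`, `group`, `dist_center`).
#' @param mode `"ring"` or `"radial_distance"`.
#' @param value Column to summarize (`"avg_strain"` or `"max_strain"`).
#' @param n_dist_groups Number of equal-width distance bins for
#'   `"radial_distance"` mode.
#' @return data.frame: `group`, `n`, `mean`, `sd`, `median`; electrode
#'   group assignments attached as attribute `"membership"`.
#' @export
group_strains <- function(table, mode = c("ring", "radial_distance"),
                          value = "avg_strain", n_dist_groups = 5) {
  mode <- match.arg(mode)
  x <- table[[value]]
  g <- if (mode == "ring") factor(table$group) else
    cut(table$dist_center, breaks = n_dist_groups, include.lowest = TRUE)
  out <- data.frame(
    group = levels(g),
    n = as.integer(tapply(x, g, length)),
    mean = as.numeric(tapply(x, g, mean)),
    sd = as.numeric(tapply(x, g, stats::sd)),
    median = as.numeric(tapply(x, g, stats::median))
  )
  out$sd[is.na(out$sd)] <- 0
  attr(out, "membership") <- g
  attr(out, "value") <- value
  out
}

#' Write an electrode strain table (or its ROI profiles) to CSV
#'
#' @param table An [electrode_strain_table()].
#' @param path Output file.
#' @param what `"table"` for the per-electrode summary, `"profiles"` for
#'   the long-format radial profiles.
#' @export
write_strain_csv <- function(table, path, what = c("table", "profiles")) {
  what <- match.arg(what)
  if (what == "table") {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  } else {
    profs <- attr(table, "profiles")
    long <- do.call(rbind, lapply(seq_along(profs), function(k) {
      p <- as.data.frame(profs[[k]])
      cbind(electrode_id = table$electrode_id[k], p)
    }))
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}
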