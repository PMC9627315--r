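# Ultra-high-density electrode montage: hemispherical layout, neighbor
# graph, ROI mask, and reduced-density electrode subsets.

# One geodesic step on a sphere of radius R: move from point p (|p| = R)
# along unit tangent direction d by arc length t. Returns the new point and
# the parallel-transported direction of travel.
geodesic_step <- function(p, d, t, R) {
  a <- t / R
  ph <- p / R
  list(p = p * cos(a) + R * d * sin(a),
       d = d * cos(a) - ph * sin(a))
}

# Map planar patch coordinates (u, v) in mm (relative to the projection
# center at the sphere vertex) onto the sphere by a single geodesic walk in
# direction atan2(v, u) over arc length sqrt(u^2 + v^2) -- an azimuthal
# equidistant placement. Returns the 3D position and the parallel-transported
# orthonormal tangent frame aligned with the planar (u, v) axes.
map_patch_point <- function(u, v, R) {
  p <- c(0, 0, R); e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  r <- sqrt(u^2 + v^2)
  if (r == 0) return(list(pos = p, f1 = e1, f2 = e2))
  ca <- u / r; sa <- v / r
  d <- ca * e1 + sa * e2          # walk direction
  q <- -sa * e1 + ca * e2         # perpendicular, transported unchanged
  s <- geodesic_step(p, d, r, R)
  # rotate the transported (d', q) frame back by -alpha to recover u/v axes
  list(pos = s$p,
       f1 = ca * s$d - sa * q,
       f2 = sa * s$d + ca * q)
}

# Rotation matrix taking unit vector a to unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) return(diag(c(-1, -1, 1)))  # antipodal fallback
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Construct an ultra-high-density electrode montage
#'
#' Builds `n_grids` contiguous 4x4 electrode grids (16 electrodes each,
#' diamond-shaped tiles sharing sides) at a fixed center-to-center pitch,
#' laid out on a hemispherical scalp surface. Grid 0 is anchored at the
#' vertex (Cz-analog); subsequent grids tile laterally and downward. Each
#' grid is placed geodesically: grid centers are reached by two geodesic
#' walks from the vertex, and electrodes within a grid sit at geodesic-polar
#' offsets in the grid's transported tangent frame, so realized
#' center-to-center spacing stays within a fraction of a millimetre of the
#' nominal pitch across the patch.
#'
#' The region of interest (ROI) marks interior electrodes of the tiled
#' patch: the outermost ring is removed everywhere and a second ring is
#' removed along the top and bottom (most anterior/posterior) edges,
#' retaining electrodes over the sensorimotor-hand-area analog.
#'
#' @param n_grids number of 4x4 grids (16 gives the full 256-channel patch).
#' @param pitch_mm center-to-center electrode spacing in mm (default 8.6).
#' @param radius_mm scalp sphere radius in mm (default 90).
#' @return An object of class `uhd_montage`: a data frame with columns
#'   `label`, `x`, `y`, `z` (mm), `grid_id` (0-based), `roi`, `row`, `col`
#'   (0-based lattice indices), `edge`; attributes `pitch_mm`, `radius_mm`.
#' @examples
#' m <- build_uhd_montage(n_grids = 1)
#' nrow(m)  # 16
#' @export
build_uhd_montage <- function(n_grids = 16, pitch_mm = 8.6, radius_mm = 90) {
  if (!is.numeric(n_grids) || length(n_grids) != 1L || n_grids < 1 ||
      n_grids != round(n_grids))
    stop("'n_grids' must be a positive integer")
  check_scalar(pitch_mm, "pitch_mm")
  if (pitch_mm <= 0) stop("'pitch_mm' must be positive")
  check_scalar(radius_mm, "radius_mm")
  if (radius_mm <= 0) stop("'radius_mm' must be positive")

  n_grids <- as.integer(n_grids)
  nbc <- ceiling(sqrt(n_grids))          # blocks per row of the tiling
  step <- 4 * pitch_mm                   # grid center spacing

  # Planar grid-center lattice, centered on the patch centroid so that the
  # azimuthal-equidistant placement distorts least; each rigid 4x4 grid is
  # then laid out geodesically in its center's transported tangent frame.
  a_idx <- (seq_len(n_grids) - 1L) %% nbc      # lateral block index
  b_idx <- (seq_len(n_grids) - 1L) %/% nbc     # downward block index
  u0 <- mean(a_idx) * step
  v0 <- mean(b_idx) * step

  rows <- integer(0); cols <- integer(0); grid <- integer(0)
  pos <- matrix(0, 0, 3)
  for (g in seq_len(n_grids) - 1L) {
    a <- a_idx[g + 1L]; b <- b_idx[g + 1L]
    ctr <- map_patch_point(a * step - u0, b * step - v0, radius_mm)
    for (i in 0:3) for (j in 0:3) {
      w <- (i - 1.5) * pitch_mm * ctr$f1 + (j - 1.5) * pitch_mm * ctr$f2
      rho <- sqrt(sum(w^2))
      p <- ctr$pos * cos(rho / radius_mm) +
        radius_mm * (w / rho) * sin(rho / radius_mm)
      pos <- rbind(pos, p)
      rows <- c(rows, a * 4L + i)
      cols <- c(cols, b * 4L + j)
      grid <- c(grid, g)
    }
  }

  # Anchor grid 0 at the vertex (Cz-analog): rotate the sphere so the first
  # grid's center maps to (0, 0, R). Rotation is an isometry, so realized
  # electrode spacing is unchanged.
  c0 <- map_patch_point(-u0, -v0, radius_mm)$pos
  rot <- rotation_between(c0 / radius_mm, c(0, 0, 1))
  pos <- pos %*% t(rot)

  rmin <- min(rows); rmax <- max(rows); cmin <- min(cols); cmax <- max(cols)
  edge <- rows == rmin | rows == rmax | cols == cmin | cols == cmax
  # ROI: interior after removing the outer ring, plus the second ring along
  # the anterior/posterior (row) edges when the patch is large enough.
  ring_r <- if (rmax - rmin >= 7L) 2L else 1L
  roi <- rows >= rmin + ring_r & rows <= rmax - ring_r &
    cols >= cmin + 1L & cols <= cmax - 1L

  m <- data.frame(
    label = sprintf("G%02dE%02d", grid, (rows %% 4L) * 4L + (cols %% 4L)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    grid_id = grid, roi = roi, row = rows, col = cols, edge = edge,
    stringsAsFactors = FALSE)
  rownames(m) <- NULL
  attr(m, "pitch_mm") <- pitch_mm
  attr(m, "radius_mm") <- radius_mm
  attr(m, "rotation") <- rot
  attr(m, "centroid_uv") <- c(u0, v0)
  class(m) <- c("uhd_montage", "data.frame")
  m
}

#' Construct a flat rectangular grid montage
#'
#' Utility montage on a plane (z = 0), mainly for examples and validation of
#' neighbor-graph logic against hand-countable layouts.
#'
#' @param nrow,ncol lattice dimensions.
#' @param spacing_mm lattice spacing in mm.
#' @return `uhd_montage` object.
#' @export
planar_grid_montage <- function(nrow, ncol, spacing_mm = 8.6) {
  idx <- expand.grid(row = seq_len(nrow) - 1L, col = seq_len(ncol) - 1L)
  m <- data.frame(
    label = sprintf("P%03d", seq_len(nrow(idx)) - 1L),
    x = idx$row * spacing_mm, y = idx$col * spacing_mm, z = 0,
    grid_id = 0L,
    roi = idx$row > 0 & idx$row < nrow - 1L & idx$col > 0 & idx$col < ncol - 1L,
    row = idx$row, col = idx$col,
    edge = idx$row == 0 | idx$row == nrow - 1L |
      idx$col == 0 | idx$col == ncol - 1L,
    stringsAsFactors = FALSE)
  attr(m, "pitch_mm") <- spacing_mm
  attr(m, "radius_mm") <- NA_real_
  class(m) <- c("uhd_montage", "data.frame")
  m
}

montage_positions <- function(montage) {
  as.matrix(montage[, c("x", "y", "z")])
}

# Geometric interior rule used when a montage carries no lattice `edge`
# column: an electrode counts as interior when the directions to its four
# nearest neighbors (projected into the local tangent plane) leave no
# angular gap of 180 degrees or more, i.e. the neighbors enclose it.
geometric_interior <- function(pos) {
  n <- nrow(pos)
  D <- as.matrix(stats::dist(pos))
  vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[2:5]
    vecs <- sweep(pos[nb, , drop = FALSE], 2, pos[i, ])
    # local tangent basis from the neighbor directions
    sv <- svd(vecs)
    uv <- vecs %*% sv$v[, 1:2]
    ang <- sort(atan2(uv[, 2], uv[, 1]))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    max(gaps) < pi - 1e-9
  }, logical(1))
}

#' Four-nearest-neighbor graph of a montage
#'
#' For every interior (non-edge) electrode, its four nearest neighbors by
#' center-to-center Euclidean distance contribute unordered pairs; edge
#' electrodes only serve as neighbors and contribute no pairs of their own.
#' Duplicate pairs are collapsed.
#'
#' @param montage `uhd_montage`.
#' @param include_edge if `TRUE`, edge electrodes also contribute pairs
#'   (useful for sparse density-subset montages that consist entirely of
#'   hull electrodes).
#' @return An object of class `uhd_neighbor_graph`: data frame with columns
#'   `i`, `j` (channel indices, `i < j`) and `distance_mm`.
#' @export
four_nearest_neighbors <- function(montage, include_edge = FALSE) {
  pos <- montage_positions(montage)
  n <- nrow(pos)
  if (n < 5L) stop("montage must have at least 5 electrodes")
  interior <- if (include_edge) rep(TRUE, n)
  else if ("edge" %in% names(montage)) !montage$edge
  else geometric_interior(pos)
  D <- as.matrix(stats::dist(pos))
  pr <- matrix(integer(0), 0, 2)
  for (i in which(interior)) {
    nb <- order(D[i, ])[2:5]
    pr <- rbind(pr, cbind(pmin(i, nb), pmax(i, nb)))
  }
  if (nrow(pr) == 0L) stop("montage has no interior electrodes")
  pr <- unique(pr)
  g <- data.frame(i = pr[, 1], j = pr[, 2],
                  distance_mm = D[pr])
  g <- g[order(g$i, g$j), ]
  rownames(g) <- NULL
  class(g) <- c("uhd_neighbor_graph", "data.frame")
  g
}

#' Built-in density-subset target positions
#'
#' Two fixed target-position sets standing in for the 10-10 (sparse, 6
#' positions at ~36 mm spacing) and extended 10-10 (dense, 11 positions at
#' ~24 mm spacing) electrode systems over the patch. Positions are laid out
#' around the patch centroid with the same geodesic mapping as the montage
#' itself, so they live in the montage coordinate frame. These are synthetic
#' stand-ins for standard-system coordinates on a parametric head.
#'
#' @param montage `uhd_montage` the targets should cover.
#' @param set `"sparse"` (~10-10) or `"dense"` (~extended 10-10).
#' @return numeric matrix (targets x 3) of positions in mm.
#' @export
density_targets <- function(montage, set = c("sparse", "dense")) {
  set <- match.arg(set)
  R <- attr(montage, "radius_mm")
  rot <- attr(montage, "rotation")
  # slightly off-symmetric offsets so no target is exactly equidistant
  # between two electrodes (nearest-electrode selection stays unique)
  off <- if (set == "sparse") {
    as.matrix(expand.grid(u = c(-36.2, 0.3, 36.1), v = c(-18.4, 17.8)))
  } else {
    o <- as.matrix(expand.grid(u = c(-36.2, -12.3, 12.2, 36.1),
                               v = c(-24.3, 0.2, 23.9)))
    o[-nrow(o), , drop = FALSE]   # drop one corner -> 11 positions
  }
  if (is.na(R) || is.null(rot)) {
    # planar montage: offsets around the planar centroid
    ctr <- colMeans(montage_positions(montage))
    cbind(ctr[1] + off[, 1], ctr[2] + off[, 2], ctr[3])
  } else {
    p <- t(apply(off, 1, function(w) map_patch_point(w[1], w[2], R)$pos))
    p %*% t(rot)
  }
}

#' Select the electrode subset best matching target positions
#'
#' For each target position the single nearest montage electrode is
#' selected; the returned mask has at most one electrode per target (two
#' targets mapping to the same electrode collapse to one).
#'
#' @param montage `uhd_montage`.
#' @param target_positions numeric matrix (targets x 3) in the montage
#'   coordinate frame, or one of `"sparse"` / `"dense"` for the built-in
#'   sets from [density_targets()].
#' @return logical channel mask of length `nrow(montage)`.
#' @export
select_density_subset <- function(montage, target_positions) {
  if (is.character(target_positions) && length(target_positions) == 1L)
    target_positions <- density_targets(montage, target_positions)
  tp <- as.matrix(target_positions)
  if (nrow(tp) == 0L) stop("target position list must be non-empty")
  if (ncol(tp) != 3L) stop("target positions must be n x 3")
  pos <- montage_positions(montage)
  sel <- apply(tp, 1, function(p)
    which.min(colSums((t(pos) - p)^2)))
  mask <- rep(FALSE, nrow(pos))
  mask[unique(sel)] <- TRUE
  mask
}

#' Restrict a montage to a channel subset
#'
#' @param montage `uhd_montage`.
#' @param mask logical mask or integer indices.
#' @param recompute_edge if `TRUE`, re-derive the `edge` column from the
#'   subset geometry (all electrodes of very sparse subsets are edges).
#' @return `uhd_montage` with the selected channels.
#' @export
subset_montage <- function(montage, mask, recompute_edge = TRUE) {
  sub <- montage[mask, , drop = FALSE]
  rownames(sub) <- NULL
  if (recompute_edge && nrow(sub) >= 5L)
    sub$edge <- !geometric_interior(montage_positions(sub))
  attr(sub, "pitch_mm") <- attr(montage, "pitch_mm")
  attr(sub, "radius_mm") <- attr(montage, "radius_mm")
  class(sub) <- c("uhd_montage", "data.frame")
  sub
}

#' Mirror a montage across the sagittal plane
#'
#' Flips the sign of the x coordinate, e.g. to pool a left-handed subject's
#' layout with right-handed ones.
#'
#' @param montage `uhd_montage`.
#' @return mirrored `uhd_montage`.
#' @export
mirror_montage_x <- function(montage) {
  montage$x <- -montage$x
  montage
}

#' Write / read a montage file
#'
#' Tab-separated columns `label`, `x_mm`, `y_mm`, `z_mm`, `grid_id`,
#' `roi` (0/1).
#'
#' @param montage `uhd_montage`.
#' @param path file path.
#' @return `write_montage` returns `path` invisibly; `read_montage` returns
#'   a `uhd_montage` (edge status re-derived geometrically when the montage
#'   has at least 5 electrodes).
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(label = montage$label,
                   x_mm = montage$x, y_mm = montage$y, z_mm = montage$z,
                   grid_id = montage$grid_id,
                   roi = as.integer(montage$roi))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  m <- data.frame(label = df$label, x = df$x_mm, y = df$y_mm, z = df$z_mm,
                  grid_id = df$grid_id, roi = df$roi > 0,
                  stringsAsFactors = FALSE)
  m$row <- NA_integer_; m$col <- NA_integer_
  m$edge <- if (nrow(m) >= 5L)
    !geometric_interior(as.matrix(m[, c("x", "y", "z")]))
  else rep(TRUE, nrow(m))
  attr(m, "pitch_mm") <- NA_real_
  attr(m, "radius_mm") <- NA_real_
  class(m) <- c("uhd_montage", "data.frame")
  m
}

#' @export
print.uhd_montage <- function(x, ...) {
  cat(sprintf("uHD montage: %d electrodes, %d grid(s), pitch %.1f mm, %d in ROI\n",
              nrow(x), length(unique(x$grid_id)),
              attr(x, "pitch_mm"), sum(x$roi)))
  invisible(x)
}
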