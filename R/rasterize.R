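# Even-odd point-in-polygon test, vectorised over query points.
# px, py: query coordinates; poly: n-by-2 vertex matrix (closed implicitly).
# A point on an edge may land on either side; contours in this package are
# defined on voxel-centre grids where ties are measure-zero.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize closed slice contours into a label mask
#'
#' Fills every voxel whose centre lies inside a contour's polygon on that
#' contour's slice, with inclusion decided by the even-odd (crossing-parity)
#' rule against that polygon. Slices without contours remain background;
#' several contours on one slice combine by union.
#'
#' @param contours List of closed [contour2d] objects sharing one `plane_axis`.
#' @param image The parent [image3d] defining the voxel lattice.
#' @param label Positive integer label to assign.
#' @return A [label_mask].
#' @export
rasterize_contours <- function(contours, image, label = 1L) {
  stopifnot(inherits(image, "image3d"))
  if (!length(contours)) stop("rasterize_contours: no contours supplied")
  if (inherits(contours, "contour2d")) contours <- list(contours)
  if (!all(vapply(contours, inherits, logical(1), "contour2d"))) {
    stop("rasterize_contours: contours must be contour2d objects")
  }
  if (any(!vapply(contours, function(ct) ct$closed, logical(1)))) {
    stop("rasterize_contours: open contour supplied; only closed contours can be filled")
  }
  axes <- unique(vapply(contours, function(ct) ct$plane_axis, character(1)))
  if (length(axes) != 1L) stop("rasterize_contours: contours mix plane axes")
  ax <- axis_index(axes)
  ip <- inplane_axes(ax)
  dims <- dim(image$voxels)
  labels <- array(0L, dims)

  u <- axis_coords(image, ip[1])
  v <- axis_coords(image, ip[2])
  grid_u <- rep(u, times = length(v))
  grid_v <- rep(v, each = length(u))

  any_outside <- FALSE
  for (ct in contours) {
    s <- ct$slice_index + 1L
    if (s < 1L || s > dims[ax]) { any_outside <- TRUE; next }
    inside <- points_in_polygon(grid_u, grid_v, ct$vertices)
    if (!any(inside)) { any_outside <- TRUE; next }
    plane <- matrix(inside, nrow = length(u), ncol = length(v))
    idx <- slice_indexer(dims, ax, s)
    cur <- do.call(`[`, c(list(labels), idx))
    cur[plane] <- label
    labels <- do.call(`[<-`, c(list(labels), idx, list(cur)))
  }
  if (any_outside) {
    warning("rasterize_contours: some contours lie outside the image extent or enclose no voxel centre")
  }
  label_mask(labels, image)
}

# Index list selecting slice s (1-based) along axis ax; other axes full.
slice_indexer <- function(dims, ax, s) {
  idx <- lapply(dims, seq_len)
  idx[[ax]] <- s
  idx
}
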