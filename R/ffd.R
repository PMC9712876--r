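#' A single drag gesture
#'
#' The atomic proofreading interaction: the user grabs an inaccurate boundary
#' at `start` and drags it by `motion`. Both live in physical mm — in the
#' slice plane (length 2) for contour editing, in 3-space (length 3) for
#' surface editing. Zero motion is legal and encodes an identity edit.
#'
#' @param start Numeric 2- or 3-vector (mm), the grab point.
#' @param motion Numeric vector of the same length (mm), the displacement.
#' @return A `drag_gesture` object.
#' @export
drag_gesture <- function(start, motion) {
  start <- as.numeric(start)
  motion <- as.numeric(motion)
  if (!length(start) %in% 2:3 || length(motion) != length(start)) {
    stop("drag_gesture: start and motion must both have length 2 or 3")
  }
  if (!all(is.finite(start)) || !all(is.finite(motion))) {
    stop("drag_gesture: start and motion must be finite")
  }
  structure(list(start = start, motion = motion, dim = length(start)),
            class = "drag_gesture")
}

GRID_NODES <- 6L  # nodes per axis; 5 cells per axis

#' Build the deformation control grid around a drag
#'
#' Constructs the regular 6-nodes-per-axis control lattice (6x6 in 2D,
#' 6x6x6 in 3D) centred on the drag start point, with all node deformation
#' vectors zero. The lattice is placed so the start point has normalized
#' local coordinate 0.5 on every axis of the central cell, giving a
#' symmetric falloff of the edit.
#'
#' @param gesture A [drag_gesture].
#' @param spacing Grid cell size in mm (> 0). The default,
#'   `max(|motion|, 5)`, scales the edited neighbourhood with the gesture.
#' @param dim 2 or 3; defaults to the gesture's dimensionality.
#' @return A `deformation_grid` with fields `dim`, `axes` (list of node
#'   coordinates per axis), `spacing`, and `node_vectors` (array
#'   `6 x 6 [x 6] x dim`, all zero).
#' @export
build_grid <- function(gesture, spacing = NULL, dim = gesture$dim) {
  stopifnot(inherits(gesture, "drag_gesture"))
  if (is.null(spacing)) spacing <- max(vnorm(gesture$motion), 5)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("build_grid: spacing must be a single positive number")
  }
  dim <- as.integer(dim)
  if (!dim %in% 2:3) stop("build_grid: dim must be 2 or 3")
  if (length(gesture$start) != dim) {
    stop("build_grid: gesture dimensionality does not match dim")
  }
  # Node k (0-based) at start + (k - 2.5) * spacing: the start point sits at
  # the centre of the central cell (cell index 2 of 0..4).
  axes <- lapply(seq_len(dim), function(a) {
    gesture$start[a] + ((0:(GRID_NODES - 1L)) - (GRID_NODES - 1L) / 2) * spacing
  })
  nv <- array(0, c(rep(GRID_NODES, dim), dim))
  structure(list(dim = dim, axes = axes, spacing = spacing, node_vectors = nv),
            class = "deformation_grid")
}

#' @export
print.deformation_grid <- function(x, ...) {
  cat(sprintf("<deformation_grid> %dD, %d nodes/axis, cell %.3g mm, max |p| = %.3g mm\n",
              x$dim, GRID_NODES, x$spacing,
              sqrt(max(apply(x$node_vectors^2, seq_len(x$dim), sum)))))
  invisible(x)
}

# Cubic Bernstein weights B_i(t) = C(3,i) (1-t)^(3-i) t^i, i = 0..3.
bernstein3 <- function(t) {
  c((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
}

# Uniform cubic B-spline weights on the same 4-node neighbourhood (option
# flag; the default tensor weights are the Bernstein form above).
bspline3 <- function(t) {
  c((1 - t)^3, 3 * t^3 - 6 * t^2 + 4, -3 * t^3 + 3 * t^2 + 3 * t + 1, t^3) / 6
}

basis_weights <- function(t, basis) {
  if (basis == "bernstein") bernstein3(t) else bspline3(t)
}

# Locate a point on one grid axis: returns NULL outside the lattice support,
# else list(base = first node (1-based) of the 4-node neighbourhood,
#           t = normalized local coordinate in the containing cell).
# The cell containing the point is c (0-based, 0..4); its neighbourhood is
# nodes b..b+3 with b = clamp(c - 1, 0, 2), always a full 4-node window.
axis_locate <- function(coord, nodes, spacing) {
  lo <- nodes[1]
  hi <- nodes[GRID_NODES]
  if (coord < lo || coord > hi) return(NULL)
  cell <- min(max(floor((coord - lo) / spacing), 0), GRID_NODES - 2L)
  t <- (coord - (lo + cell * spacing)) / spacing
  base <- min(max(cell - 1L, 0L), GRID_NODES - 4L)
  list(base = as.integer(base) + 1L, t = t, cell = as.integer(cell))
}

# Tensor-product weights at a point: returns NULL outside the support, else
# list(index = matrix of node indices (one row per active node, dim cols),
#      w = weight vector of length 16 (2D) or 64 (3D)).
grid_point_weights <- function(grid, point, basis = "bernstein") {
  locs <- vector("list", grid$dim)
  for (a in seq_len(grid$dim)) {
    loc <- axis_locate(point[a], grid$axes[[a]], grid$spacing)
    if (is.null(loc)) return(NULL)
    locs[[a]] <- loc
  }
  ws <- lapply(locs, function(l) basis_weights(l$t, basis))
  offs <- lapply(locs, function(l) l$base + 0:3)
  if (grid$dim == 2L) {
    w <- as.numeric(outer(ws[[1]], ws[[2]]))
    index <- as.matrix(expand.grid(i = offs[[1]], j = offs[[2]]))
  } else {
    w <- as.numeric(outer(outer(ws[[1]], ws[[2]]), ws[[3]]))
    index <- as.matrix(expand.grid(i = offs[[1]], j = offs[[2]], k = offs[[3]]))
  }
  list(index = index, w = w)
}

#' Evaluate the deformation field of a control grid
#'
#' Interpolates the per-node deformation vectors at arbitrary physical
#' points with the tensor-product cubic Bernstein weights
#' `sum_i C(3,i)(1-m)^(3-i) m^i * sum_j C(3,j)(1-n)^(3-j) n^j * p_ij`
#' (and a third factor in 3D), where `(m, n[, l])` is the normalized local
#' coordinate of the point in its grid cell and the `p_ij` are the 4x4
#' (4x4x4) neighbourhood's node vectors. Points outside the lattice support
#' get the zero vector: the edit is strictly local.
#'
#' @param grid A `deformation_grid`.
#' @param points A single point or n-by-dim matrix of physical points (mm).
#' @param basis `"bernstein"` (default, the reference form) or `"bspline"`
#'   (uniform cubic B-spline weights on the same neighbourhood).
#' @return Deformation vectors: same shape as `points`.
#' @export
evaluate_grid <- function(grid, points, basis = c("bernstein", "bspline")) {
  stopifnot(inherits(grid, "deformation_grid"))
  basis <- match.arg(basis)
  single <- !is.matrix(points)
  pts <- if (single) matrix(points, nrow = 1L) else points
  if (ncol(pts) != grid$dim) stop("evaluate_grid: point dimensionality mismatch")
  out <- matrix(0, nrow(pts), grid$dim)
  nv <- grid$node_vectors
  nvm <- matrix(nv, ncol = grid$dim)  # flatten nodes x dim
  nnodes <- GRID_NODES^grid$dim
  for (r in seq_len(nrow(pts))) {
    gw <- grid_point_weights(grid, pts[r, ], basis)
    if (is.null(gw)) next
    flat <- flat_node_index(gw$index, grid$dim)
    out[r, ] <- colSums(gw$w * nvm[flat, , drop = FALSE])
  }
  if (single) out[1, ] else out
}

flat_node_index <- function(index, dim) {
  if (dim == 2L) {
    (index[, 2] - 1L) * GRID_NODES + index[, 1]
  } else {
    ((index[, 3] - 1L) * GRID_NODES + (index[, 2] - 1L)) * GRID_NODES + index[, 1]
  }
}

#' Extrapolate a drag to the control grid (inverse interpolation)
#'
#' Solves for node deformation vectors such that the interpolated field
#' reproduces the drag motion exactly at the drag start point. One drag
#' constrains 16 (2D) or 64 (3D) active node vectors, so the system is
#' under-determined; the minimum-norm (Moore-Penrose) solution is returned:
#' each active node receives the motion scaled by its own basis weight,
#' normalized by the sum of squared weights. This is deterministic, exact at
#' the start point, and decays smoothly away from it.
#'
#' @param grid A `deformation_grid` from [build_grid()].
#' @param gesture The [drag_gesture]; its start must lie strictly inside the
#'   lattice.
#' @param basis Weight family, as in [evaluate_grid()].
#' @return The grid with `node_vectors` filled in.
#' @export
solve_grid_vectors <- function(grid, gesture, basis = c("bernstein", "bspline")) {
  stopifnot(inherits(grid, "deformation_grid"), inherits(gesture, "drag_gesture"))
  basis <- match.arg(basis)
  if (length(gesture$start) != grid$dim) {
    stop("solve_grid_vectors: gesture dimensionality does not match the grid")
  }
  for (a in seq_len(grid$dim)) {
    nodes <- grid$axes[[a]]
    if (gesture$start[a] <= nodes[1] || gesture$start[a] >= nodes[GRID_NODES]) {
      stop("solve_grid_vectors: drag start lies outside the grid interior")
    }
  }
  nv <- array(0, c(rep(GRID_NODES, grid$dim), grid$dim))
  if (any(gesture$motion != 0)) {
    gw <- grid_point_weights(grid, gesture$start, basis)
    scale <- gw$w / sum(gw$w^2)
    flat <- flat_node_index(gw$index, grid$dim)
    nvm <- matrix(nv, ncol = grid$dim)
    for (d in seq_len(grid$dim)) {
      nvm[flat, d] <- scale * gesture$motion[d]
    }
    nv <- array(nvm, dim(nv))
  }
  grid$node_vectors <- nv
  grid
}

#' Correct a 2D contour with one drag
#'
#' The complete drag-proofreading edit for slice annotations: a control grid
#' is built around the drag start, the drag is extrapolated to the grid nodes
#' by inverse interpolation, and every contour vertex is displaced by the
#' interpolated deformation field. Vertex count, ordering, closedness and the
#' `kind` tag are preserved; vertices outside the grid support are untouched.
#' If the edit makes a closed contour self-intersect, the contour is returned
#' with a warning and attribute `self_intersecting = TRUE` rather than an
#' error, so the user can re-drag.
#'
#' @param contour A [contour2d]; the gesture is interpreted in its slice
#'   plane (2D in-plane mm coordinates).
#' @param gesture A 2D [drag_gesture].
#' @param spacing Grid cell size (mm); default as in [build_grid()].
#' @param basis Weight family, as in [evaluate_grid()].
#' @return The displaced [contour2d].
#' @export
apply_drag_contour <- function(contour, gesture, spacing = NULL,
                               basis = c("bernstein", "bspline")) {
  stopifnot(inherits(contour, "contour2d"), inherits(gesture, "drag_gesture"))
  basis <- match.arg(basis)
  if (gesture$dim != 2L) {
    stop("apply_drag_contour: contour editing needs a 2D (in-plane) gesture")
  }
  if (all(gesture$motion == 0)) return(contour)
  grid <- solve_grid_vectors(build_grid(gesture, spacing, dim = 2L), gesture,
                             basis = basis)
  newv <- contour$vertices + evaluate_grid(grid, contour$vertices, basis = basis)
  out <- contour
  out$vertices <- newv
  if (out$closed && !polygon_is_simple(newv)) {
    warning("apply_drag_contour: edit introduced a self-intersection")
    attr(out, "self_intersecting") <- TRUE
  }
  out
}

#' Correct a 3D surface mesh with one drag
#'
#' 3D analogue of [apply_drag_contour()]: vertices are displaced by the
#' solved deformation field; the face topology is unchanged.
#'
#' @param mesh A [surface_mesh].
#' @param gesture A 3D [drag_gesture].
#' @param spacing Grid cell size (mm); default as in [build_grid()].
#' @param basis Weight family, as in [evaluate_grid()].
#' @return The displaced [surface_mesh].
#' @export
apply_drag_mesh <- function(mesh, gesture, spacing = NULL,
                            basis = c("bernstein", "bspline")) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(gesture, "drag_gesture"))
  basis <- match.arg(basis)
  if (gesture$dim != 3L) stop("apply_drag_mesh: mesh editing needs a 3D gesture")
  if (all(gesture$motion == 0)) return(mesh)
  grid <- solve_grid_vectors(build_grid(gesture, spacing, dim = 3L), gesture,
                             basis = basis)
  mesh$vertices <- mesh$vertices + evaluate_grid(grid, mesh$vertices, basis = basis)
  mesh
}
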