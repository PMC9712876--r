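#' Point landmark annotation
#'
#' @param name Label string.
#' @param position Physical 3-vector (mm).
#' @return A `landmark` object.
#' @export
landmark <- function(name, position) {
  if (!is.character(name) || length(name) != 1L) stop("landmark: name must be a string")
  position <- as.numeric(position)
  if (!is_finite_vec(position, 3L)) stop("landmark: position must be a finite 3-vector")
  structure(list(name = name, position = position), class = "landmark")
}

#' Axis-aligned physical-space bounding box
#'
#' @param min_corner,max_corner Physical 3-vectors (mm) with
#'   `min_corner <= max_corner` componentwise.
#' @return A `bounding_box` object.
#' @export
bounding_box <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner)
  max_corner <- as.numeric(max_corner)
  if (!is_finite_vec(min_corner, 3L) || !is_finite_vec(max_corner, 3L)) {
    stop("bounding_box: corners must be finite 3-vectors")
  }
  if (any(min_corner > max_corner)) {
    stop("bounding_box: min_corner must not exceed max_corner on any axis")
  }
  structure(list(min_corner = min_corner, max_corner = max_corner),
            class = "bounding_box")
}

#' Planar contour, curve or scribble annotation
#'
#' A polyline drawn in one image slice, stored as ordered in-plane physical
#' coordinates (mm). A closed contour delineates a region boundary; open
#' contours serve as curves or scribbles, distinguished only by the `kind`
#' tag since they share geometry. The in-plane axes are the two image axes
#' other than `plane_axis`, in ascending (x, y, z) order.
#'
#' @param vertices n-by-2 matrix of in-plane physical coordinates (mm).
#' @param plane_axis `"x"`, `"y"` or `"z"`: the axis the slice is orthogonal to.
#' @param slice_index 0-based slice index along `plane_axis`.
#' @param closed Logical; closed contours need >= 3 vertices and must be
#'   simple (non-self-intersecting), open ones >= 2.
#' @param kind Role tag: `"contour"`, `"curve"` or `"scribble"`.
#' @return A `contour2d` object.
#' @export
contour2d <- function(vertices, plane_axis = "z", slice_index = 0L,
                      closed = TRUE, kind = c("contour", "curve", "scribble")) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2L || !all(is.finite(vertices))) {
    stop("contour2d: vertices must be a finite n-by-2 matrix")
  }
  if (closed && nrow(vertices) < 3L) {
    stop("contour2d: a closed contour needs at least 3 vertices")
  }
  if (!closed && nrow(vertices) < 2L) {
    stop("contour2d: an open contour needs at least 2 vertices")
  }
  plane_axis <- AXIS_NAMES[axis_index(plane_axis)]
  if (closed && !polygon_is_simple(vertices)) {
    stop("contour2d: closed contour is self-intersecting (must be simple)")
  }
  structure(
    list(vertices = vertices, plane_axis = plane_axis,
         slice_index = as.integer(slice_index), closed = isTRUE(closed),
         kind = kind),
    class = "contour2d"
  )
}

# Simple-polygon test: no two non-adjacent edges intersect. O(n^2) segment
# tests; adequate for hand- or phantom-sized contours.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):n) {
      if (j == i || nxt[j] == i || nxt[i] == j) next  # adjacent edges share a vertex
      if (segments_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  eps <- 1e-12
  (abs(d1) < eps && on_segment(p3, p4, p1)) ||
    (abs(d2) < eps && on_segment(p3, p4, p2)) ||
    (abs(d3) < eps && on_segment(p1, p2, p3)) ||
    (abs(d4) < eps && on_segment(p1, p2, p4))
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

on_segment <- function(a, b, p) {
  min(a[1], b[1]) - 1e-12 <= p[1] && p[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= p[2] && p[2] <= max(a[2], b[2]) + 1e-12
}

#' Triangle surface mesh in physical coordinates
#'
#' @param vertices n-by-3 matrix of physical coordinates (mm).
#' @param faces m-by-3 integer matrix of 1-based vertex indices.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || !all(is.finite(vertices))) {
    stop("surface_mesh: vertices must be a finite n-by-3 matrix")
  }
  if (ncol(faces) != 3L) stop("surface_mesh: faces must be m-by-3")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("surface_mesh: face indices out of range")
  }
  areas <- triangle_areas(vertices, faces)
  if (any(areas <= 1e-12)) {
    stop(sprintf("surface_mesh: %d degenerate (zero-area) triangles",
                 sum(areas <= 1e-12)))
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

triangle_areas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Integer label volume congruent with a parent image
#'
#' Label 0 is reserved for background. The mask carries the parent's spacing
#' and origin so it remains anchored in physical space on its own.
#'
#' @param labels 3D integer array, same shape as the parent image.
#' @param image The parent [image3d] (supplies shape check, spacing, origin).
#' @param label_names Optional named character vector mapping label integers
#'   (names) to structure names.
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels, image, label_names = NULL) {
  stopifnot(inherits(image, "image3d"))
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (!identical(dim(labels), dim(image$voxels))) {
    stop("label_mask: labels shape must equal the parent image shape")
  }
  if (any(labels < 0L)) stop("label_mask: labels must be non-negative (0 = background)")
  structure(
    list(labels = labels, spacing = image$spacing, origin = image$origin,
         label_names = label_names),
    class = "label_mask"
  )
}

#' @export
dim.label_mask <- function(x) dim(x$labels)

#' Typed container of annotations anchored to one image
#'
#' @param image_ref Identifier string of the annotated image.
#' @param landmarks,boxes,contours,curves,scribbles,meshes,masks Lists of the
#'   corresponding annotation objects (all optional).
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(image_ref = "", landmarks = list(), boxes = list(),
                           contours = list(), curves = list(),
                           scribbles = list(), meshes = list(),
                           masks = list()) {
  check_all <- function(lst, cls, what) {
    if (!all(vapply(lst, inherits, logical(1), cls))) {
      stop(sprintf("annotation_set: %s must all be %s objects", what, cls))
    }
  }
  check_all(landmarks, "landmark", "landmarks")
  check_all(boxes, "bounding_box", "boxes")
  check_all(contours, "contour2d", "contours")
  check_all(curves, "contour2d", "curves")
  check_all(scribbles, "contour2d", "scribbles")
  check_all(meshes, "surface_mesh", "meshes")
  check_all(masks, "label_mask", "masks")
  structure(
    list(image_ref = as.character(image_ref), landmarks = landmarks,
         boxes = boxes, contours = contours, curves = curves,
         scribbles = scribbles, meshes = meshes, masks = masks),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> image_ref='%s': %d landmarks, %d boxes, %d contours, %d curves, %d scribbles, %d meshes, %d masks\n",
    x$image_ref, length(x$landmarks), length(x$boxes), length(x$contours),
    length(x$curves), length(x$scribbles), length(x$meshes), length(x$masks)))
  invisible(x)
}
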