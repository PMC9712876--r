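# Signed distance of the in-plane voxel-centre grid to a set of closed
# contours on one slice: negative inside the union of polygons (even-odd per
# polygon), magnitude = distance to the nearest polygon edge.
slice_sdf <- function(contours, u, v) {
  grid_u <- rep(u, times = length(v))
  grid_v <- rep(v, each = length(u))
  d <- rep(Inf, length(grid_u))
  inside <- logical(length(grid_u))
  for (ct in contours) {
    poly <- ct$vertices
    n <- nrow(poly)
    j <- n
    for (i in seq_len(n)) {
      d <- pmin(d, point_segment_dist(grid_u, grid_v, poly[j, ], poly[i, ]))
      j <- i
    }
    inside <- inside | points_in_polygon(grid_u, grid_v, poly)
  }
  matrix(ifelse(inside, -d, d), nrow = length(u), ncol = length(v))
}

point_segment_dist <- function(px, py, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(pmax(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0), 1)
  sqrt((px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2)
}

#' Interpolate a 3D ROI from interleaved slice contours
#'
#' Reconstructs a solid region of interest that was contoured on only a few
#' parallel slices. Each annotated slice is converted to a signed distance
#' field (negative inside); the fields are interpolated linearly along the
#' slice axis, and the zero level set yields the in-between boundaries. On
#' annotated slices the returned mask equals the direct rasterization of the
#' drawn contour exactly. Slices outside the annotated range stay background.
#' A closed triangle mesh of the boundary is lofted from the per-slice zero
#' isolines (largest component per slice) and capped at the extreme slices.
#'
#' @param contours List of >= 2 closed [contour2d] on distinct parallel
#'   slices (same `plane_axis`).
#' @param image The parent [image3d].
#' @param label Label value for the output mask.
#' @param ring_points Number of points each lofted boundary ring is resampled
#'   to (mesh resolution; does not affect the mask).
#' @return A list with elements `mesh` ([surface_mesh]) and `mask`
#'   ([label_mask]).
#' @export
interpolate_roi_surface <- function(contours, image, label = 1L,
                                    ring_points = 64L) {
  stopifnot(inherits(image, "image3d"))
  if (inherits(contours, "contour2d")) contours <- list(contours)
  if (length(contours) < 2L) {
    stop("interpolate_roi_surface: need at least 2 contours on distinct slices")
  }
  if (any(!vapply(contours, function(ct) ct$closed, logical(1)))) {
    stop("interpolate_roi_surface: all contours must be closed")
  }
  axes <- unique(vapply(contours, function(ct) ct$plane_axis, character(1)))
  if (length(axes) != 1L) stop("interpolate_roi_surface: contours mix plane axes")
  ax <- axis_index(axes)
  ip <- inplane_axes(ax)
  dims <- dim(image$voxels)
  slices <- sort(unique(vapply(contours, function(ct) ct$slice_index, integer(1))))
  if (length(slices) < 2L) {
    stop("interpolate_roi_surface: need at least 2 contours on distinct slices")
  }
  if (any(slices < 0L | slices >= dims[ax])) {
    stop("interpolate_roi_surface: contour slice index outside the image")
  }

  u <- axis_coords(image, ip[1])
  v <- axis_coords(image, ip[2])
  sdf_by_slice <- list()
  for (s in slices) {
    cts <- Filter(function(ct) ct$slice_index == s, contours)
    sdf_by_slice[[as.character(s)]] <- slice_sdf(cts, u, v)
  }

  labels <- array(0L, dims)
  rings <- list()
  slice_pos <- axis_coords(image, ax)
  for (s in slices[1]:slices[length(slices)]) {
    annotated <- s %in% slices
    if (annotated) {
      sdf <- sdf_by_slice[[as.character(s)]]
    } else {
      s0 <- max(slices[slices < s])
      s1 <- min(slices[slices > s])
      w <- (s - s0) / (s1 - s0)
      sdf <- (1 - w) * sdf_by_slice[[as.character(s0)]] +
        w * sdf_by_slice[[as.character(s1)]]
    }
    if (annotated) {
      # exact agreement with rasterize_contours on drawn slices: use the
      # polygon-inclusion bit, not the (tie-prone) sign of the distance field
      cts <- Filter(function(ct) ct$slice_index == s, contours)
      grid_u <- rep(u, times = length(v))
      grid_v <- rep(v, each = length(u))
      inside <- logical(length(grid_u))
      for (ct in cts) inside <- inside | points_in_polygon(grid_u, grid_v, ct$vertices)
      plane <- matrix(inside, nrow = length(u), ncol = length(v))
    } else {
      plane <- sdf < 0
    }
    if (any(plane)) {
      idx <- slice_indexer(dims, ax, s + 1L)
      cur <- do.call(`[`, c(list(labels), idx))
      cur[plane] <- label
      labels <- do.call(`[<-`, c(list(labels), idx, list(cur)))
    }
    ring <- zero_isoline(u, v, sdf, ring_points)
    if (!is.null(ring)) {
      rings[[length(rings) + 1L]] <- list(slice = s, pos = slice_pos[s + 1L],
                                          ring = ring)
    }
  }
  mask <- label_mask(labels, image)
  mesh <- loft_rings(rings, ax, ip)
  list(mesh = mesh, mask = mask)
}

# Largest zero-level isoline of a slice field, resampled to n points,
# counter-clockwise. NULL when the field has no zero crossing.
zero_isoline <- function(u, v, sdf, n) {
  cl <- grDevices::contourLines(u, v, sdf, levels = 0)
  if (!length(cl)) return(NULL)
  lens <- vapply(cl, function(c0) ring_length(cbind(c0$x, c0$y)), numeric(1))
  ring <- cl[[which.max(lens)]]
  pts <- cbind(ring$x, ring$y)
  # drop duplicated closing point if present
  if (nrow(pts) > 1L && all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-12)) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  if (nrow(pts) < 3L) return(NULL)
  if (polygon_signed_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  resample_ring(pts, n)
}

ring_length <- function(pts) {
  d <- diff(rbind(pts, pts[1, ]))
  sum(sqrt(rowSums(d^2)))
}

polygon_signed_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2]) / 2
}

# Arc-length-uniform resampling of a closed ring to exactly n points.
resample_ring <- function(pts, n) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  targets <- (0:(n - 1L)) * total / n
  out <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    i <- findInterval(targets[k], cum, rightmost.closed = TRUE)
    i <- min(i, nrow(closed) - 1L)
    t <- if (seg[i] > 0) (targets[k] - cum[i]) / seg[i] else 0
    out[k, ] <- (1 - t) * closed[i, ] + t * closed[i + 1L, ]
  }
  out
}

# Stitch per-slice rings into a closed triangle mesh with centroid caps.
loft_rings <- function(rings, ax, ip) {
  if (length(rings) < 2L) {
    stop("interpolate_roi_surface: fewer than 2 boundary rings; region too thin to mesh")
  }
  n <- nrow(rings[[1]]$ring)
  to3d <- function(ring2d, pos) {
    m <- matrix(0, nrow(ring2d), 3)
    m[, ip[1]] <- ring2d[, 1]
    m[, ip[2]] <- ring2d[, 2]
    m[, ax] <- pos
    m
  }
  # align each ring's start to the previous ring (cyclic shift minimising
  # total vertex distance) for clean quads
  for (i in 2:length(rings)) {
    prev <- rings[[i - 1L]]$ring
    cur <- rings[[i]]$ring
    best <- 0L; bestd <- Inf
    for (shift in 0:(n - 1L)) {
      idx <- ((seq_len(n) - 1L + shift) %% n) + 1L
      d <- sum((cur[idx, ] - prev)^2)
      if (d < bestd) { bestd <- d; best <- shift }
    }
    idx <- ((seq_len(n) - 1L + best) %% n) + 1L
    rings[[i]]$ring <- cur[idx, , drop = FALSE]
  }
  verts <- do.call(rbind, lapply(rings, function(r) to3d(r$ring, r$pos)))
  faces <- list()
  for (i in seq_len(length(rings) - 1L)) {
    a0 <- (i - 1L) * n
    b0 <- i * n
    for (k in seq_len(n)) {
      k2 <- k %% n + 1L
      faces[[length(faces) + 1L]] <- rbind(
        c(a0 + k, b0 + k, b0 + k2),
        c(a0 + k, b0 + k2, a0 + k2))
    }
  }
  # caps: centroid fans
  c1 <- colMeans(verts[seq_len(n), , drop = FALSE])
  c2 <- colMeans(verts[(nrow(verts) - n + 1L):nrow(verts), , drop = FALSE])
  verts <- rbind(verts, c1, c2)
  i1 <- nrow(verts) - 1L
  i2 <- nrow(verts)
  last0 <- (length(rings) - 1L) * n
  for (k in seq_len(n)) {
    k2 <- k %% n + 1L
    faces[[length(faces) + 1L]] <- rbind(
      c(i1, k2, k),
      c(i2, last0 + k, last0 + k2))
  }
  f <- do.call(rbind, faces)
  # prune any numerically degenerate sliver triangles (tiny rings at caps)
  areas <- triangle_areas(verts, f)
  f <- f[areas > 1e-12, , drop = FALSE]
  surface_mesh(verts, f)
}

#' Fit a thin-plate-spline height-field surface to sketched curves
#'
#' Models an open, sheet-like surface (e.g. a lung fissure) as a single-valued
#' height field over the plane orthogonal to `height_axis`, interpolating
#' points collected from open curves sketched on a few parallel slices. The
#' radial kernel is the thin-plate spline `r^2 log r` with the standard
#' affine augmentation, solved as a pure interpolant by default (optional
#' ridge regularizer for noisy sketches). The model reproduces its sample
#' heights to numerical precision and any affine height field exactly.
#'
#' @param curves List of [contour2d] objects (typically open curves) on
#'   parallel slices, or a single n-by-3 matrix of physical points (mm).
#' @param height_axis `"x"`, `"y"` or `"z"`: the surface is single-valued
#'   along this axis.
#' @param image Optional [image3d] used to convert slice indices to physical
#'   slice positions; without it, slice index is taken as mm (unit spacing).
#' @param ridge Non-negative smoothing parameter added to the kernel diagonal
#'   (0 = exact interpolation).
#' @return An `rbf_surface` model; evaluate with [predict()].
#' @export
fit_rbf_surface <- function(curves, height_axis, image = NULL, ridge = 0) {
  h <- axis_index(height_axis)
  planar <- setdiff(1:3, h)
  pts <- if (is.matrix(curves)) curves else curves_to_points(curves, image)
  if (nrow(pts) < 3L) stop("fit_rbf_surface: need at least 3 sample points")
  centers <- pts[, planar, drop = FALSE]
  heights <- pts[, h]

  # single-valuedness: collapse duplicate planar locations, averaging heights
  key <- paste(round(centers[, 1], 6), round(centers[, 2], 6))
  if (anyDuplicated(key)) {
    warning("fit_rbf_surface: duplicate planar locations; averaging their heights")
    agg_h <- tapply(heights, key, mean)
    first <- !duplicated(key)
    centers <- centers[first, , drop = FALSE]
    heights <- as.numeric(agg_h[key[first]])
  }
  n <- nrow(centers)
  P <- cbind(1, centers)
  if (qr(P)$rank < 3L) {
    stop("fit_rbf_surface: rank-deficient system; sample points are collinear in the height plane")
  }
  K <- tps_kernel_matrix(centers, centers)
  A <- rbind(cbind(K + diag(ridge, n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(heights, rep(0, 3))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop(sprintf("fit_rbf_surface: singular interpolation system: %s",
                 conditionMessage(e)))
  })
  structure(
    list(kernel = "thin_plate_spline", centers = centers, weights = sol[1:n],
         polynomial_terms = sol[(n + 1):(n + 3)],
         height_axis = AXIS_NAMES[h], planar_axes = AXIS_NAMES[planar],
         ridge = ridge),
    class = "rbf_surface"
  )
}

curves_to_points <- function(curves, image = NULL) {
  if (inherits(curves, "contour2d")) curves <- list(curves)
  pts <- lapply(curves, function(ct) {
    ax <- axis_index(ct$plane_axis)
    ip <- inplane_axes(ax)
    pos <- if (is.null(image)) as.numeric(ct$slice_index)
           else axis_coords(image, ax)[ct$slice_index + 1L]
    m <- matrix(0, nrow(ct$vertices), 3)
    m[, ip[1]] <- ct$vertices[, 1]
    m[, ip[2]] <- ct$vertices[, 2]
    m[, ax] <- pos
    m
  })
  do.call(rbind, pts)
}

tps_kernel_matrix <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  k <- matrix(0, nrow(a), nrow(b))
  nz <- d2 > 0
  k[nz] <- 0.5 * d2[nz] * log(d2[nz])  # r^2 log r  ==  d2 * log(sqrt(d2))
  k
}

#' Evaluate a fitted RBF surface
#'
#' @param object An `rbf_surface` from [fit_rbf_surface()].
#' @param newdata n-by-2 matrix of planar coordinates (in the model's
#'   `planar_axes` order), or n-by-3 physical points from which the planar
#'   coordinates are taken.
#' @param ... Unused.
#' @return Numeric vector of heights along the model's `height_axis` (mm).
#' @export
predict.rbf_surface <- function(object, newdata, ...) {
  q <- as.matrix(newdata)
  if (ncol(q) == 3L) {
    planar <- match(object$planar_axes, AXIS_NAMES)
    q <- q[, planar, drop = FALSE]
  }
  if (ncol(q) != 2L) stop("predict.rbf_surface: newdata must have 2 or 3 columns")
  K <- tps_kernel_matrix(q, object$centers)
  as.numeric(K %*% object$weights +
               cbind(1, q) %*% object$polynomial_terms)
}

#' @export
print.rbf_surface <- function(x, ...) {
  cat(sprintf("<rbf_surface> thin-plate spline, %d centers, height axis %s, ridge %g\n",
              nrow(x$centers), x$height_axis, x$ridge))
  invisible(x)
}

#' Triangulate a fitted height-field surface on a regular lattice
#'
#' Evaluates an [fit_rbf_surface()] model on a regular planar lattice clipped
#' to `bounds` and triangulates it, producing an open sheet mesh suitable for
#' export or drag-based proofreading with [apply_drag_mesh()]. Vertex heights
#' equal direct model evaluations exactly.
#'
#' @param model An `rbf_surface`.
#' @param bounds A [bounding_box] clipping the lattice (the two planar axes
#'   are used).
#' @param resolution Lattice step (mm), > 0.
#' @return A [surface_mesh].
#' @export
surface_to_fissure_mesh <- function(model, bounds, resolution) {
  stopifnot(inherits(model, "rbf_surface"), inherits(bounds, "bounding_box"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stop("surface_to_fissure_mesh: resolution must be a single positive number")
  }
  h <- axis_index(model$height_axis)
  planar <- match(model$planar_axes, AXIS_NAMES)
  lo <- bounds$min_corner[planar]
  hi <- bounds$max_corner[planar]
  if (any(hi - lo < resolution)) {
    stop("surface_to_fissure_mesh: bounds too small for the requested resolution")
  }
  us <- seq(lo[1], hi[1], by = resolution)
  vs <- seq(lo[2], hi[2], by = resolution)
  grid <- cbind(rep(us, times = length(vs)), rep(vs, each = length(us)))
  heights <- predict(model, grid)
  verts <- matrix(0, nrow(grid), 3)
  verts[, planar[1]] <- grid[, 1]
  verts[, planar[2]] <- grid[, 2]
  verts[, h] <- heights
  nu <- length(us)
  nv <- length(vs)
  faces <- list()
  for (j in seq_len(nv - 1L)) {
    for (i in seq_len(nu - 1L)) {
      a <- (j - 1L) * nu + i
      faces[[length(faces) + 1L]] <- rbind(
        c(a, a + 1L, a + nu),
        c(a + 1L, a + nu + 1L, a + nu))
    }
  }
  surface_mesh(verts, do.call(rbind, faces))
}

#' Extract voxels passing a threshold inside a region of interest
#'
#' The quantification step of threshold-based analyses (e.g. counting
#' high-susceptibility voxels inside a tumour ROI): selects the voxels that
#' belong to the ROI and whose intensity is above (or below) the threshold,
#' and reports their count and physical volume.
#'
#' @param image An [image3d].
#' @param roi A [label_mask] congruent with `image` (any non-zero label is
#'   inside the ROI).
#' @param threshold Intensity cut-off.
#' @param direction `"above"` (intensity > threshold) or `"below"`
#'   (intensity < threshold).
#' @param label Output label value.
#' @return A `threshold_result`: list with `mask` ([label_mask]),
#'   `voxel_count`, and `volume_mm3 = voxel_count * prod(spacing)`.
#' @export
extract_threshold <- function(image, roi, threshold,
                              direction = c("above", "below"), label = 1L) {
  stopifnot(inherits(image, "image3d"), inherits(roi, "label_mask"))
  direction <- match.arg(direction)
  if (!identical(dim(roi$labels), dim(image$voxels))) {
    stop("extract_threshold: ROI shape does not match the image")
  }
  pass <- if (direction == "above") image$voxels > threshold
          else image$voxels < threshold
  sel <- (roi$labels != 0L) & pass
  labels <- array(0L, dim(image$voxels))
  labels[sel] <- label
  count <- sum(sel)
  structure(
    list(mask = label_mask(labels, image), voxel_count = as.integer(count),
         volume_mm3 = count * prod(image$spacing),
         threshold = threshold, direction = direction),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %d voxels %s %g (%.2f mm^3)\n",
              x$voxel_count, x$direction, x$threshold, x$volume_mm3))
  invisible(x)
}
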