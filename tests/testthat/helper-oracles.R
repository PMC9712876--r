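# Independent oracles, coded naively and separately from the package
# internals so the two routes can disagree.

# Naive tensor-product cubic evaluation: explicit double/triple loop over the
# 4-per-axis neighbourhood with binomial Bernstein weights, locating the cell
# with plain arithmetic on the node coordinate vectors.
naive_ffd_eval <- function(grid, point) {
  dm <- grid$dim
  locate <- function(coord, nodes) {
    h <- nodes[2] - nodes[1]
    if (coord < nodes[1] || coord > nodes[length(nodes)]) return(NULL)
    cell <- floor((coord - nodes[1]) / h)
    cell <- max(0, min(cell, length(nodes) - 2))
    base <- max(0, min(cell - 1, length(nodes) - 4))
    list(base = base, t = (coord - nodes[1] - cell * h) / h)
  }
  locs <- lapply(seq_len(dm), function(a) locate(point[a], grid$axes[[a]]))
  if (any(vapply(locs, is.null, logical(1)))) return(rep(0, dm))
  bw <- function(t, i) choose(3, i) * (1 - t)^(3 - i) * t^i
  out <- rep(0, dm)
  if (dm == 2L) {
    for (i in 0:3) for (j in 0:3) {
      w <- bw(locs[[1]]$t, i) * bw(locs[[2]]$t, j)
      out <- out + w * grid$node_vectors[locs[[1]]$base + i + 1,
                                         locs[[2]]$base + j + 1, ]
    }
  } else {
    for (i in 0:3) for (j in 0:3) for (k in 0:3) {
      w <- bw(locs[[1]]$t, i) * bw(locs[[2]]$t, j) * bw(locs[[3]]$t, k)
      out <- out + w * grid$node_vectors[locs[[1]]$base + i + 1,
                                         locs[[2]]$base + j + 1,
                                         locs[[3]]$base + k + 1, ]
    }
  }
  out
}

# Per-point even-odd crossing test, scalar loop formulation.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py)) {
      xint <- poly[j, 1] +
        (py - poly[j, 2]) * (poly[i, 1] - poly[j, 1]) / (poly[i, 2] - poly[j, 2])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Star-shaped simple polygon: random radii over randomized angles around a
# centre. Angular gaps are kept below pi (each edge then stays inside its
# angular wedge), which guarantees simplicity for any radii.
random_simple_polygon <- function(n, center = c(0, 0), rmin = 3, rmax = 12) {
  gaps <- stats::runif(n, 0.6, 1)
  th <- 2 * pi * cumsum(gaps) / sum(gaps)
  r <- stats::runif(n, rmin, rmax)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Random annotation set of embedded-geometry kinds (no mesh/mask sidecars).
random_annotation_set <- function() {
  n_lm <- sample(0:3, 1)
  n_bx <- sample(0:2, 1)
  n_ct <- sample(1:3, 1)
  n_cv <- sample(0:2, 1)
  rand_contour <- function(closed, kind) {
    if (closed) {
      contour2d(random_simple_polygon(sample(3:12, 1),
                                      center = stats::runif(2, -40, 40)),
                plane_axis = sample(c("x", "y", "z"), 1),
                slice_index = sample(0:50, 1), closed = TRUE)
    } else {
      contour2d(matrix(stats::runif(2 * sample(2:8, 1), -50, 50), ncol = 2),
                plane_axis = sample(c("x", "y", "z"), 1),
                slice_index = sample(0:50, 1), closed = FALSE, kind = kind)
    }
  }
  annotation_set(
    image_ref = paste0("img_", sample(1e6, 1)),
    landmarks = lapply(seq_len(n_lm), function(i) {
      landmark(paste0("lm", i), stats::runif(3, -100, 100))
    }),
    boxes = lapply(seq_len(n_bx), function(i) {
      a <- stats::runif(3, -50, 0); b <- a + stats::runif(3, 0, 50)
      bounding_box(a, b)
    }),
    contours = lapply(seq_len(n_ct), function(i) rand_contour(TRUE, "contour")),
    curves = lapply(seq_len(n_cv), function(i) rand_contour(FALSE, "curve")),
    scribbles = lapply(seq_len(sample(0:2, 1)),
                       function(i) rand_contour(FALSE, "scribble"))
  )
}

expect_annotation_sets_equal <- function(a, b, tol = 1e-9) {
  expect_identical(a$image_ref, b$image_ref)
  expect_length(b$landmarks, length(a$landmarks))
  for (i in seq_along(a$landmarks)) {
    expect_identical(b$landmarks[[i]]$name, a$landmarks[[i]]$name)
    expect_lt(max(abs(b$landmarks[[i]]$position - a$landmarks[[i]]$position),
                  0), tol)
  }
  expect_length(b$boxes, length(a$boxes))
  for (i in seq_along(a$boxes)) {
    expect_lt(max(abs(b$boxes[[i]]$min_corner - a$boxes[[i]]$min_corner),
                  abs(b$boxes[[i]]$max_corner - a$boxes[[i]]$max_corner)), tol)
  }
  for (slot in c("contours", "curves", "scribbles")) {
    expect_length(b[[slot]], length(a[[slot]]))
    for (i in seq_along(a[[slot]])) {
      ca <- a[[slot]][[i]]; cb <- b[[slot]][[i]]
      expect_identical(cb$plane_axis, ca$plane_axis)
      expect_identical(cb$slice_index, ca$slice_index)
      expect_identical(cb$closed, ca$closed)
      expect_identical(cb$kind, ca$kind)
      expect_lt(max(abs(cb$vertices - ca$vertices)), tol)
    }
  }
}

# Nearest-boundary distances recomputed voxel-by-voxel (boundary = foreground
# voxel with a background 6-neighbour, array edge counting as background).
oracle_boundary_distances <- function(idx, ref) {
  d <- dim(ref)
  fg <- which(ref != 0)
  is_boundary <- vapply(fg, function(v) {
    co <- arrayInd(v, d)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- co; nb[ax] <- nb[ax] + s
      if (nb[ax] < 1L || nb[ax] > d[ax]) return(TRUE)
      if (ref[nb[1], nb[2], nb[3]] == 0) return(TRUE)
    }
    FALSE
  }, logical(1))
  bco <- arrayInd(fg[is_boundary], d)
  vapply(idx, function(v) {
    co <- arrayInd(v, d)
    sqrt(min(rowSums(sweep(bco, 2, co)^2)))
  }, numeric(1))
}

# fresh scratch directory per call
withr_tempdir <- function() {
  d <- tempfile("skk")
  dir.create(d)
  d
}

# voxel-centre coordinates along one axis, recomputed from the public fields
axis_coords_pub <- function(img, ax) {
  img$origin[ax] + (seq_len(dim(img$voxels)[ax]) - 1) * img$spacing[ax]
}
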