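#' Specification of a synthetic phantom
#'
#' Describes a reproducible synthetic dataset: same spec (including seed)
#' yields bit-identical output from [make_phantom()]. Intensity noise is
#' additive Gaussian; geometry is never perturbed by noise.
#'
#' @param kind One of `"sphere"`, `"cube"`, `"blobs"`, `"fissure_sheet"`,
#'   `"itss_cube"`.
#' @param size Voxels per axis (isotropic cube volume).
#' @param spacing Voxel size in mm (scalar or length 3).
#' @param noise_sigma Intensity noise standard deviation.
#' @param seed RNG seed.
#' @param ... Kind-specific parameters: `radius` (sphere, in voxels; default
#'   `size/3.2`), `side` (cube, voxels), `bg`/`fg` intensities,
#'   `offset_sigma` (blobs: per-image intensity shift SD, emulating
#'   scanner/sequence variation), `radii_range` (blobs, voxels),
#'   `amplitude` (fissure_sheet).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("sphere", "cube", "blobs", "fissure_sheet",
                                  "itss_cube"),
                         size = 64L, spacing = 1, noise_sigma = 0,
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(kind = kind, size = as.integer(size),
                 spacing = as.numeric(spacing),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed), extra = list(...)),
            class = "phantom_spec")
}

#' Generate a synthetic phantom with analytic ground truth
#'
#' Builds the test substrate for every algorithm in the package: an intensity
#' volume, its ground-truth label mask, and the analytic parameters (centre,
#' radius, counts, surface function ...) that oracle checks need. All
#' randomness is driven by the spec's seed; two calls with the same spec are
#' bit-identical.
#'
#' @param spec A [phantom_spec()] (or the arguments thereof, passed on).
#' @param ... Convenience: if `spec` is a kind string, remaining arguments go
#'   to [phantom_spec()].
#' @return A list with (as applicable) `image` ([image3d]), `mask`
#'   ([label_mask]), `params` (analytic descriptors), and for
#'   `fissure_sheet`: `curves` and `surface_fun`.
#' @export
make_phantom <- function(spec, ...) {
  if (is.character(spec)) spec <- phantom_spec(spec, ...)
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    switch(spec$kind,
           sphere = phantom_sphere(spec),
           cube = phantom_cube(spec),
           blobs = phantom_blob(spec),
           fissure_sheet = phantom_fissure(spec),
           itss_cube = phantom_itss(spec),
           stop(sprintf("make_phantom: unknown kind '%s'", spec$kind)))
  })
}

phantom_canvas <- function(spec, bg) {
  n <- spec$size
  image3d(array(bg, c(n, n, n)), spacing = spec$spacing)
}

# voxel-centre coordinate arrays (mm) of a cubic canvas
coord_arrays <- function(img) {
  d <- dim(img$voxels)
  x <- axis_coords(img, 1)
  y <- axis_coords(img, 2)
  z <- axis_coords(img, 3)
  list(x = array(rep(x, times = d[2] * d[3]), d),
       y = array(rep(rep(y, each = d[1]), times = d[3]), d),
       z = array(rep(z, each = d[1] * d[2]), d))
}

finish_phantom <- function(spec, img, inside, bg, fg, params) {
  vox <- array(bg, dim(img$voxels))
  vox[inside] <- fg
  if (spec$noise_sigma > 0) {
    vox <- vox + array(stats::rnorm(length(vox), 0, spec$noise_sigma), dim(vox))
  }
  image <- image3d(vox, spacing = img$spacing, origin = img$origin)
  mask <- label_mask(array(as.integer(inside), dim(vox)), image)
  list(image = image, mask = mask, params = params)
}

phantom_sphere <- function(spec) {
  e <- spec$extra
  bg <- e$bg %||% 100
  fg <- e$fg %||% 140
  img <- phantom_canvas(spec, bg)
  radius_vox <- e$radius %||% (spec$size / 3.2)
  center <- (spec$size - 1) / 2 * spec$spacing
  radius <- radius_vox * spec$spacing[1]
  cc <- coord_arrays(img)
  inside <- (cc$x - center[1])^2 + (cc$y - center[2])^2 + (cc$z - center[3])^2 <=
    radius^2
  finish_phantom(spec, img, inside, bg, fg,
                 list(center = center, radius = radius, bg = bg, fg = fg))
}

phantom_cube <- function(spec) {
  e <- spec$extra
  bg <- e$bg %||% 100
  fg <- e$fg %||% 140
  side_vox <- e$side %||% (spec$size / 2)
  img <- phantom_canvas(spec, bg)
  center <- (spec$size - 1) / 2 * spec$spacing
  half <- side_vox / 2 * spec$spacing
  cc <- coord_arrays(img)
  inside <- abs(cc$x - center[1]) <= half[1] &
    abs(cc$y - center[2]) <= half[2] & abs(cc$z - center[3]) <= half[3]
  finish_phantom(spec, img, inside, bg, fg,
                 list(center = center, half_side = half, bg = bg, fg = fg))
}

# Random ellipsoid "organ" with a per-image global intensity offset drawn
# from a few discrete levels, emulating images pooled from different
# acquisition protocols. A classifier must have seen a protocol during
# training to place its threshold correctly, which is what gives the
# iterative-annotation loop its learning curve: protocol coverage grows
# monotonically with the labeled pool.
phantom_blob <- function(spec) {
  e <- spec$extra
  bg0 <- e$bg %||% 100
  fg0 <- e$fg %||% 140
  levels <- e$offset_levels %||% c(-30, -10, 10, 30)
  rr <- e$radii_range %||% (spec$size * c(0.18, 0.35))
  offset <- levels[stats::runif(1) * length(levels) + 1]
  bg <- bg0 + offset
  fg <- fg0 + offset
  img <- phantom_canvas(spec, bg)
  extent <- (spec$size - 1) * spec$spacing
  center <- extent * stats::runif(3, 0.4, 0.6)
  radii <- stats::runif(3, rr[1], rr[2]) * spec$spacing
  cc <- coord_arrays(img)
  inside <- ((cc$x - center[1]) / radii[1])^2 +
    ((cc$y - center[2]) / radii[2])^2 +
    ((cc$z - center[3]) / radii[3])^2 <= 1
  finish_phantom(spec, img, inside, bg, fg,
                 list(center = center, radii = radii, bg = bg, fg = fg,
                      offset = offset, bg0 = bg0, fg0 = fg0))
}

# Open sheet z = amplitude * sin(x/20) * cos(y/20), sampled as open curves on
# a few parallel slices -- the shape of a sketched lung-fissure annotation.
phantom_fissure <- function(spec) {
  e <- spec$extra
  amplitude <- e$amplitude %||% 1
  domain <- e$domain %||% 100       # mm, square in x/y
  n_curves <- e$n_curves %||% 5L
  pts_per_curve <- e$pts_per_curve %||% 15L
  fun <- function(x, y) amplitude * sin(x / 20) * cos(y / 20)
  ys <- round(seq(0, domain, length.out = n_curves))
  xs <- seq(0, domain, length.out = pts_per_curve)
  curves <- lapply(seq_along(ys), function(i) {
    # sketched on a plane y = const: in-plane axes (x, z); under the
    # image-free convention slice_index doubles as the mm position
    contour2d(cbind(xs, fun(xs, ys[i])), plane_axis = "y",
              slice_index = as.integer(ys[i]), closed = FALSE, kind = "curve")
  })
  # slice index -> y position map is identity*step for unit tests without an image
  list(curves = curves, surface_fun = fun,
       params = list(amplitude = amplitude, domain = domain,
                     slice_positions = ys, n_curves = n_curves))
}

# Cube ROI with an exactly known number of "hot" voxels, for threshold
# extraction oracles: ROI 10^3 voxels, 5^3 = 125 voxels at `hot` intensity.
phantom_itss <- function(spec) {
  e <- spec$extra
  bg <- e$bg %||% 50
  hot <- e$hot %||% 200
  img <- phantom_canvas(spec, bg)
  vox <- img$voxels
  roi <- array(0L, dim(vox))
  if (spec$size < 10L) stop("make_phantom: itss_cube needs size >= 10")
  # 1-based corner of the 10^3 ROI, centred by default
  r0 <- e$roi_start %||% max(1L, (spec$size - 10L) %/% 2L + 1L)
  roi[r0:(r0 + 9L), r0:(r0 + 9L), r0:(r0 + 9L)] <- 1L
  h0 <- r0 + 2L                      # 5^3 hot block centred in the ROI
  vox[h0:(h0 + 4L), h0:(h0 + 4L), h0:(h0 + 4L)] <- hot
  if (spec$noise_sigma > 0) {
    vox <- vox + array(stats::rnorm(length(vox), 0, spec$noise_sigma), dim(vox))
  }
  image <- image3d(vox, spacing = spec$spacing)
  list(image = image, mask = label_mask(roi, image),
       params = list(n_hot = 125L, bg = bg, hot = hot,
                     roi_voxels = 1000L))
}

#' Regular polygon approximation of a circle as a closed contour
#'
#' @param center Length-2 in-plane centre (mm).
#' @param radius Radius (mm).
#' @param n Number of vertices.
#' @param plane_axis,slice_index Slice anchoring, as in [contour2d()].
#' @return A closed [contour2d].
#' @export
circle_contour <- function(center, radius, n = 64L, plane_axis = "z",
                           slice_index = 0L) {
  th <- 2 * pi * (0:(n - 1L)) / n
  contour2d(cbind(center[1] + radius * cos(th), center[2] + radius * sin(th)),
            plane_axis = plane_axis, slice_index = slice_index, closed = TRUE)
}

#' Circle contours of an analytic sphere on interleaved slices
#'
#' Samples the cross-section circles of a sphere on every `every`-th slice
#' along `axis`, skipping slices whose circle is smaller than `min_radius`
#' (too thin to contour meaningfully). Produces the kind of interleaved
#' annotation [interpolate_roi_surface()] consumes.
#'
#' @param image Parent [image3d] (defines the slice lattice).
#' @param center,radius Sphere centre (mm, length 3) and radius (mm).
#' @param every Slice stride.
#' @param axis Slice axis.
#' @param n Vertices per contour.
#' @param min_radius Smallest circle radius to keep (mm).
#' @return List of closed [contour2d].
#' @export
sphere_slice_contours <- function(image, center, radius, every = 4L,
                                  axis = "z", n = 64L, min_radius = 1.5) {
  ax <- axis_index(axis)
  ip <- inplane_axes(ax)
  pos <- axis_coords(image, ax)
  out <- list()
  for (s in seq(1L, length(pos), by = every)) {
    dz <- pos[s] - center[ax]
    if (abs(dz) >= radius) next
    r <- sqrt(radius^2 - dz^2)
    if (r < min_radius) next
    out[[length(out) + 1L]] <- circle_contour(center[ip], r, n = n,
                                              plane_axis = AXIS_NAMES[ax],
                                              slice_index = s - 1L)
  }
  out
}

#' Triangulated UV sphere mesh
#'
#' @param center Length-3 centre (mm).
#' @param radius Radius (mm).
#' @param n_theta Latitudinal bands (>= 3).
#' @param n_phi Longitudinal steps (>= 3).
#' @return A [surface_mesh] with fan-capped poles.
#' @export
sphere_mesh <- function(center = c(0, 0, 0), radius = 1, n_theta = 16L,
                        n_phi = 32L) {
  thetas <- pi * seq_len(n_theta - 1L) / n_theta   # exclude poles
  phis <- 2 * pi * (0:(n_phi - 1L)) / n_phi
  verts <- matrix(0, 0, 3)
  for (th in thetas) {
    verts <- rbind(verts, cbind(center[1] + radius * sin(th) * cos(phis),
                                center[2] + radius * sin(th) * sin(phis),
                                center[3] + radius * cos(th)))
  }
  north <- center + c(0, 0, radius)
  south <- center - c(0, 0, radius)
  verts <- rbind(verts, north, south)
  ni <- nrow(verts) - 1L
  si <- nrow(verts)
  faces <- list()
  ring <- function(b) (b - 1L) * n_phi
  for (b in seq_len(length(thetas) - 1L)) {
    for (k in seq_len(n_phi)) {
      k2 <- k %% n_phi + 1L
      faces[[length(faces) + 1L]] <- rbind(
        c(ring(b) + k, ring(b + 1L) + k, ring(b + 1L) + k2),
        c(ring(b) + k, ring(b + 1L) + k2, ring(b) + k2))
    }
  }
  for (k in seq_len(n_phi)) {
    k2 <- k %% n_phi + 1L
    faces[[length(faces) + 1L]] <- rbind(
      c(ni, ring(1L) + k2, ring(1L) + k),
      c(si, ring(length(thetas)) + k, ring(length(thetas)) + k2))
  }
  surface_mesh(verts, do.call(rbind, faces))
}

#' Dent a sphere mesh inside an angular cap
#'
#' Moves every vertex within angular distance `cap_angle` of direction `dir`
#' (from the sphere centre) radially inward by a smooth cosine bump of depth
#' `depth` at the cap centre, creating the kind of local segmentation error a
#' proofreading drag should fix.
#'
#' @param mesh A sphere-like [surface_mesh].
#' @param center Sphere centre (mm).
#' @param dir Length-3 cap direction (normalized internally).
#' @param cap_angle Cap half-angle (radians).
#' @param depth Radial dent depth at the cap centre (mm).
#' @return The dented [surface_mesh].
#' @export
dent_sphere_mesh <- function(mesh, center, dir, cap_angle, depth) {
  stopifnot(inherits(mesh, "surface_mesh"))
  dir <- dir / vnorm(dir)
  rel <- sweep(mesh$vertices, 2, center)
  r <- sqrt(rowSums(rel^2))
  unit <- rel / r
  ang <- acos(pmin(pmax(as.numeric(unit %*% dir), -1), 1))
  w <- ifelse(ang < cap_angle, 0.5 * (1 + cos(pi * ang / cap_angle)), 0)
  newr <- r - depth * w
  mesh$vertices <- sweep(unit * newr, 2, center, "+")
  mesh
}

#' Perturb a closed contour with a smooth local bump
#'
#' Displaces a contiguous arc of the contour radially (from its centroid) by
#' a smooth squared-sine bump whose apex displacement is exactly
#' `magnitude_mm`, emulating an inaccurate segmentation boundary. The arc
#' location is seed-deterministic. The perturbation descriptor (apex vertex
#' index, affected indices, per-vertex displacement) is attached as attribute
#' `"perturbation"` for error accounting.
#'
#' @param contour A closed [contour2d].
#' @param arc_fraction Fraction of vertices in the bump, in (0, 1).
#' @param magnitude_mm Apex displacement (mm); positive = outward.
#' @param seed RNG seed picking the arc location.
#' @return The perturbed [contour2d].
#' @export
perturb_contour <- function(contour, arc_fraction, magnitude_mm, seed = 1L) {
  stopifnot(inherits(contour, "contour2d"))
  if (!contour$closed) stop("perturb_contour: contour must be closed")
  if (arc_fraction <= 0 || arc_fraction >= 1) {
    stop("perturb_contour: arc_fraction must be in (0, 1)")
  }
  n <- nrow(contour$vertices)
  n_arc <- max(3L, round(arc_fraction * n))
  if (n_arc %% 2L == 0L) n_arc <- n_arc + 1L   # odd so the apex is a vertex
  start <- with_seed(seed, sample.int(n, 1L))
  idx <- ((start - 1L + 0:(n_arc - 1L)) %% n) + 1L
  t <- (0:(n_arc - 1L)) / (n_arc - 1L)
  bump <- magnitude_mm * sin(pi * t)^2
  centroid <- colMeans(contour$vertices)
  out <- contour
  rel <- sweep(contour$vertices[idx, , drop = FALSE], 2, centroid)
  unit <- rel / sqrt(rowSums(rel^2))
  out$vertices[idx, ] <- contour$vertices[idx, , drop = FALSE] + unit * bump
  attr(out, "perturbation") <- list(
    indices = idx, apex_index = idx[(n_arc + 1L) / 2L],
    displacement_mm = bump, magnitude_mm = magnitude_mm)
  out
}
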