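test_that("two identical square contours extrude to an exact prism mask", {
  img <- image3d(array(0, c(16, 16, 16)))
  sq <- rbind(c(0.5, 0.5), c(10.5, 0.5), c(10.5, 10.5), c(0.5, 10.5))
  cts <- list(contour2d(sq, slice_index = 2L), contour2d(sq, slice_index = 12L))
  res <- interpolate_roi_surface(cts, img)
  expect_equal(sum(res$mask$labels), 100 * 11)   # 100 per slice x 11 slices
  expect_equal(sum(res$mask$labels[, , 1:2]), 0) # nothing outside the range
  expect_equal(sum(res$mask$labels[, , 14:16]), 0)
})

test_that("interleaved circle contours recover a sphere and are exact on drawn slices", {
  ph <- make_phantom(phantom_spec("sphere", size = 64, seed = 2))
  cts <- sphere_slice_contours(ph$image, ph$params$center, ph$params$radius,
                               every = 4)
  res <- interpolate_roi_surface(cts, ph$image)
  expect_gte(dice(res$mask, ph$mask), 0.95)
  for (ct in cts[c(2, 5, 8)]) {
    direct <- rasterize_contours(list(ct), ph$image)
    s <- ct$slice_index + 1L
    expect_identical(res$mask$labels[, , s], direct$labels[, , s])
  }
  expect_gt(nrow(res$mesh$faces), 100)   # a closed lofted boundary came out
})

test_that("reconstruction Dice does not decrease with annotation density", {
  ph <- make_phantom(phantom_spec("sphere", size = 48, seed = 3, radius = 15))
  d <- sapply(c(8, 4, 2), function(ev) {
    cts <- sphere_slice_contours(ph$image, ph$params$center, ph$params$radius,
                                 every = ev)
    dice(interpolate_roi_surface(cts, ph$image)$mask, ph$mask)
  })
  expect_true(all(diff(d) >= 0))
})

test_that("degenerate contour inputs are rejected", {
  img <- image3d(array(0, c(8, 8, 8)))
  one <- circle_contour(c(3.5, 3.5), 2, n = 16, slice_index = 2L)
  expect_error(interpolate_roi_surface(list(one), img), "at least 2")
  same_slice <- list(one, circle_contour(c(3.5, 3.5), 1, n = 16, slice_index = 2L))
  expect_error(interpolate_roi_surface(same_slice, img), "distinct slices")
  mixed <- list(one, circle_contour(c(3.5, 3.5), 2, n = 16,
                                    plane_axis = "x", slice_index = 5L))
  expect_error(interpolate_roi_surface(mixed, img), "mix plane axes")
  open_ct <- contour2d(rbind(c(0, 0), c(2, 2)), closed = FALSE, slice_index = 5L)
  expect_error(interpolate_roi_surface(list(one, open_ct), img), "closed")
})

test_that("thin-plate spline reproduces samples and affine height fields", {
  set.seed(13)
  pts <- cbind(runif(25, 0, 100), runif(25, 0, 100))
  z <- 2 * pts[, 1] + 3 * pts[, 2] + 1
  model <- fit_rbf_surface(cbind(pts, z), height_axis = "z")
  q <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  expect_lt(max(abs(predict(model, q) - (2 * q[, 1] + 3 * q[, 2] + 1))), 1e-6)
  expect_lt(max(abs(predict(model, pts) - z)), 1e-6)
})

test_that("thin-plate spline recovers a smooth analytic surface from 5 slice curves", {
  ph <- make_phantom(phantom_spec("fissure_sheet"))
  model <- fit_rbf_surface(ph$curves, height_axis = "z")
  pts <- cbind(rep(seq(0, 100, by = 5), times = 21),
               rep(seq(0, 100, by = 5), each = 21))
  err <- predict(model, pts) - ph$surface_fun(pts[, 1], pts[, 2])
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("collinear centres raise a rank error and duplicates are averaged", {
  line <- cbind(1:5, 2 * (1:5), rnorm(5))
  expect_error(fit_rbf_surface(line, height_axis = "z"), "collinear")
  dup <- rbind(c(0, 0, 1), c(0, 0, 3), c(10, 0, 1), c(0, 10, 1), c(10, 10, 2))
  expect_warning(model <- fit_rbf_surface(dup, height_axis = "z"), "duplicate")
  expect_equal(predict(model, rbind(c(0, 0)))[1], 2, tolerance = 1e-6)
})

test_that("height-field meshing evaluates the model exactly on the lattice", {
  pts <- cbind(c(0, 40, 0, 40, 20), c(0, 0, 40, 40, 20))
  model <- fit_rbf_surface(cbind(pts, 0.5 * pts[, 1] - 0.25 * pts[, 2] + 2),
                           height_axis = "z")
  bounds <- bounding_box(c(0, 0, -100), c(40, 40, 100))
  mesh <- surface_to_fissure_mesh(model, bounds, resolution = 4)
  expect_equal(nrow(mesh$vertices), 11 * 11)
  direct <- predict(model, mesh$vertices[, 1:2])
  expect_lt(max(abs(mesh$vertices[, 3] - direct)), 1e-12)
  # affine model -> planar mesh: unit normals of all faces agree
  v <- mesh$vertices; f <- mesh$faces
  n1 <- v[f[, 2], ] - v[f[, 1], ]; n2 <- v[f[, 3], ] - v[f[, 1], ]
  nrm <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
               n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
               n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  expect_lt(max(abs(sweep(nrm, 2, nrm[1, ]))), 1e-9)
  # halving the resolution roughly quadruples the vertex count
  mesh2 <- surface_to_fissure_mesh(model, bounds, resolution = 2)
  expect_equal(nrow(mesh2$vertices), 21 * 21)
  expect_error(surface_to_fissure_mesh(model, bounds, resolution = 0),
               "positive")
})

test_that("threshold extraction counts exactly and reports physical volume", {
  ph <- make_phantom(phantom_spec("itss_cube", size = 32, spacing = c(1, 1, 2)))
  res <- extract_threshold(ph$image, ph$mask, 100, "above")
  expect_identical(res$voxel_count, 125L)
  expect_equal(res$volume_mm3, 125 * 2)
  expect_true(all(ph$mask$labels[res$mask$labels != 0L] != 0L))

  # above the maximum -> empty; below the minimum -> the whole ROI
  expect_identical(extract_threshold(ph$image, ph$mask, 1e9, "above")$voxel_count, 0L)
  whole <- label_mask(array(1L, dim(ph$image$voxels)), ph$image)
  expect_identical(extract_threshold(ph$image, whole, -1e9, "above")$voxel_count,
                   as.integer(prod(dim(ph$image))))
  wrong <- image3d(array(0, c(8, 8, 8)))
  expect_error(extract_threshold(ph$image,
                                 label_mask(array(0L, c(8, 8, 8)), wrong), 1),
               "shape")
})

test_that("threshold counts equal a brute-force triple loop on noisy phantoms", {
  for (s in 1:3) {
    ph <- make_phantom(phantom_spec("itss_cube", size = 16, noise_sigma = 30,
                                    seed = s, roi_start = 4L))
    res <- extract_threshold(ph$image, ph$mask, 100, "above")
    cnt <- 0L
    v <- ph$image$voxels; r <- ph$mask$labels
    for (i in 1:16) for (j in 1:16) for (k in 1:16) {
      if (r[i, j, k] != 0L && v[i, j, k] > 100) cnt <- cnt + 1L
    }
    expect_identical(res$voxel_count, cnt)
  }
})
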