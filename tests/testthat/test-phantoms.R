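test_that("sphere phantom mask matches the analytic volume and a brute-force count", {
  ph <- make_phantom(phantom_spec("sphere", size = 64, radius = 20, seed = 1))
  n <- sum(ph$mask$labels)
  expect_lt(abs(n - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.01)
  # brute-force centre-inclusion count from the analytic descriptor
  co <- ph$params$center
  cnt <- 0L
  x <- axis_coords_pub(ph$image, 1)
  for (i in seq_along(x)) {
    dx2 <- (x[i] - co[1])^2
    for (j in seq_along(x)) {
      dy2 <- (x[j] - co[2])^2
      if (dx2 + dy2 > ph$params$radius^2) next
      cnt <- cnt + sum(dx2 + dy2 + (x - co[3])^2 <= ph$params$radius^2)
    }
  }
  expect_identical(n, as.integer(cnt))
})

test_that("phantoms are bit-reproducible from their spec", {
  for (kind in c("sphere", "blobs", "itss_cube")) {
    a <- make_phantom(phantom_spec(kind, size = 16, noise_sigma = 8, seed = 42))
    b <- make_phantom(phantom_spec(kind, size = 16, noise_sigma = 8, seed = 42))
    expect_identical(a$image$voxels, b$image$voxels)
    expect_identical(a$mask$labels, b$mask$labels)
  }
  a <- make_phantom(phantom_spec("sphere", size = 16, seed = 1))
  b <- make_phantom(phantom_spec("sphere", size = 16, seed = 2))
  expect_identical(a$image$voxels, b$image$voxels)  # noise-free: seed moot
})

test_that("the hot-block phantom records exactly its constructed voxel count", {
  ph <- make_phantom(phantom_spec("itss_cube", size = 32))
  expect_identical(ph$params$n_hot, 125L)
  expect_identical(sum(ph$image$voxels == 200), 125L)
  expect_identical(sum(ph$mask$labels), 1000L)
})

test_that("contour perturbation is exact at the apex, seeded, and bounded", {
  circ <- circle_contour(c(5, -3), 30, n = 96)
  expect_identical(perturb_contour(circ, 0.3, 0, seed = 9)$vertices,
                   circ$vertices)
  p1 <- perturb_contour(circ, 0.3, 3, seed = 9)
  p2 <- perturb_contour(circ, 0.3, 3, seed = 9)
  expect_identical(p1$vertices, p2$vertices)
  desc <- attr(p1, "perturbation")
  radial <- sqrt(rowSums(sweep(p1$vertices, 2, c(5, -3))^2)) - 30
  expect_equal(max(radial), 3, tolerance = 1e-6)
  expect_equal(radial[desc$apex_index], 3, tolerance = 1e-6)
  untouched <- setdiff(seq_len(96), desc$indices)
  expect_lt(max(abs(radial[untouched])), 1e-9)
  expect_error(perturb_contour(circ, 1.2, 3), "arc_fraction")
  expect_error(perturb_contour(circ, 0, 3), "arc_fraction")
})

test_that("unknown phantom kinds are rejected", {
  expect_error(phantom_spec("wedge"), "arg")
})
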