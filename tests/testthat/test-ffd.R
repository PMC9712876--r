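test_that("control grid construction places the drag start centrally", {
  g <- drag_gesture(c(0, 0), c(1, 2))
  gr <- build_grid(g, spacing = 10, dim = 2)
  expect_equal(prod(dim(gr$node_vectors)[1:2]), 36)
  # start sits at the centre of the central cell: node coordinates symmetric
  expect_equal(gr$axes[[1]], c(-25, -15, -5, 5, 15, 25))
  g3 <- drag_gesture(c(1, 2, 3), c(0, 0, 1))
  gr3 <- build_grid(g3, spacing = 4)
  expect_equal(prod(dim(gr3$node_vectors)[1:3]), 216)
  expect_error(build_grid(g, spacing = 0), "positive")
  expect_error(build_grid(g, spacing = -2), "positive")
})

test_that("inverse interpolation reproduces the drag exactly and is minimum-norm", {
  set.seed(21)
  for (rep in 1:40) {
    d <- sample(2:3, 1)
    g <- drag_gesture(runif(d, -40, 40), runif(d, -8, 8))
    gr <- solve_grid_vectors(build_grid(g, spacing = runif(1, 1, 12)), g)
    expect_lt(max(abs(evaluate_grid(gr, g$start) - g$motion)), 1e-8)
  }
  # Moore-Penrose check via an independent svd pseudo-inverse of the
  # 1-constraint system in the 16 active 2D basis weights
  g <- drag_gesture(c(3, -2), c(2.5, -1))
  gr <- solve_grid_vectors(build_grid(g, spacing = 6), g)
  bw <- function(t, i) choose(3, i) * (1 - t)^(3 - i) * t^i
  # start is at local (0.5, 0.5) of the central cell; active nodes 2..5 (1-based)
  w <- as.numeric(outer(sapply(0:3, bw, t = 0.5), sapply(0:3, bw, t = 0.5)))
  A <- matrix(w, nrow = 1)
  pinv <- svd(A)
  x_ref <- outer(as.numeric(pinv$v %*% (1 / pinv$d) %*% t(pinv$u)), g$motion)
  x_impl <- cbind(as.numeric(gr$node_vectors[2:5, 2:5, 1]),
                  as.numeric(gr$node_vectors[2:5, 2:5, 2]))
  expect_lt(max(abs(x_impl - x_ref)), 1e-12)
  # all other nodes stay zero
  nv <- gr$node_vectors; nv[2:5, 2:5, ] <- 0
  expect_true(all(nv == 0))
})

test_that("zero drag solves to an all-zero grid", {
  g <- drag_gesture(c(5, 5), c(0, 0))
  gr <- solve_grid_vectors(build_grid(g, spacing = 3), g)
  expect_true(all(gr$node_vectors == 0))
  expect_equal(evaluate_grid(gr, c(5, 5)), c(0, 0))
})

test_that("drag start outside the lattice interior is rejected", {
  g <- drag_gesture(c(0, 0), c(1, 0))
  gr <- build_grid(g, spacing = 2)
  far <- drag_gesture(c(100, 0), c(1, 0))
  expect_error(solve_grid_vectors(gr, far), "outside the grid interior")
})

test_that("field evaluation matches the naive tensor-product oracle", {
  set.seed(33)
  for (rep in 1:30) {
    d <- sample(2:3, 1)
    g <- drag_gesture(runif(d, -20, 20), runif(d, -5, 5))
    gr <- build_grid(g, spacing = runif(1, 2, 9), dim = d)
    gr$node_vectors[] <- rnorm(length(gr$node_vectors))
    for (k in 1:10) {
      p <- g$start + runif(d, -2.4, 2.4) * gr$spacing
      expect_lt(max(abs(evaluate_grid(gr, p) - naive_ffd_eval(gr, p))), 1e-12)
    }
  }
})

test_that("constant node vectors reproduce the constant (partition of unity)", {
  g <- drag_gesture(c(0, 0, 0), c(1, 0, 0))
  gr <- build_grid(g, spacing = 7)
  gr$node_vectors[, , , 1] <- 1.5
  gr$node_vectors[, , , 2] <- -2.25
  gr$node_vectors[, , , 3] <- 0.5
  set.seed(5)
  for (k in 1:20) {
    p <- runif(3, -17, 17)
    expect_equal(evaluate_grid(gr, p), c(1.5, -2.25, 0.5), tolerance = 1e-12)
  }
})

test_that("at a cell corner the field degenerates to one node vector", {
  g <- drag_gesture(c(0, 0), c(1, 1))
  gr <- build_grid(g, spacing = 10)
  gr$node_vectors[] <- rnorm(length(gr$node_vectors))
  # point exactly on node (0-based) 2 along x, 3 along y: cell (2,3),
  # local coordinate (0,0), neighbourhood base (1,2) -> its (0,0) node
  p <- c(gr$axes[[1]][3], gr$axes[[2]][4])
  expect_equal(evaluate_grid(gr, p), as.numeric(gr$node_vectors[2, 3, ]),
               tolerance = 1e-12)
})

test_that("deformation is exactly zero outside the grid support", {
  g <- drag_gesture(c(0, 0), c(4, -3))
  gr <- solve_grid_vectors(build_grid(g, spacing = 5), g)
  for (p in list(c(26, 0), c(0, -26), c(100, 100))) {
    expect_identical(evaluate_grid(gr, p), c(0, 0))
  }
})

test_that("the solved field is linear in the drag vector", {
  set.seed(8)
  g <- drag_gesture(c(2, -1), c(3, 1))
  gr1 <- solve_grid_vectors(build_grid(g, spacing = 6), g)
  g2 <- drag_gesture(g$start, 2.5 * g$motion)
  gr2 <- solve_grid_vectors(build_grid(g2, spacing = 6), g2)
  pts <- matrix(runif(40, -12, 12), ncol = 2)
  expect_lt(max(abs(evaluate_grid(gr2, pts) - 2.5 * evaluate_grid(gr1, pts))),
            1e-10)
})

test_that("contour drag preserves structure and is the bitwise identity at zero motion", {
  circ <- circle_contour(c(0, 0), 20, n = 48)
  idg <- drag_gesture(c(20, 0), c(0, 0))
  expect_identical(apply_drag_contour(circ, idg), circ)
  g <- drag_gesture(c(20, 0), c(3, 0))
  out <- apply_drag_contour(circ, g, spacing = 5)
  expect_identical(dim(out$vertices), dim(circ$vertices))
  expect_true(out$closed)
  # vertices beyond the lattice support are bitwise unchanged
  far <- sqrt(rowSums(sweep(circ$vertices, 2, g$start)^2)) > 2.5 * 5 * sqrt(2)
  expect_identical(out$vertices[far, ], circ$vertices[far, ])
  # and the grabbed vertex moves by the full motion
  expect_equal(out$vertices[1, ], c(23, 0), tolerance = 1e-8)
})

test_that("an edit that introduces self-intersection warns and flags the contour", {
  xs <- seq(0, 30, by = 2)
  rect <- rbind(cbind(xs, 0), c(30, 4), cbind(rev(xs), 4), c(0, 2))
  sq <- contour2d(rect[!duplicated(rect), ])
  g <- drag_gesture(c(15, 0), c(0, 18))   # push bottom edge through the top
  expect_warning(out <- apply_drag_contour(sq, g, spacing = 3),
                 "self-intersection")
  expect_true(isTRUE(attr(out, "self_intersecting")))
})

test_that("a corrective drag pulls a bumped circle back toward the true circle", {
  circ <- circle_contour(c(0, 0), 30, n = 128)
  pert <- perturb_contour(circ, arc_fraction = 0.25, magnitude_mm = 3, seed = 4)
  desc <- attr(pert, "perturbation")
  mean_err <- function(ct) mean(abs(sqrt(rowSums(ct$vertices^2)) - 30))
  apex <- pert$vertices[desc$apex_index, ]
  g <- drag_gesture(apex, -3 * apex / sqrt(sum(apex^2)))
  fixed <- apply_drag_contour(pert, g)
  expect_lt(mean_err(fixed), mean_err(pert))
})

test_that("mesh drag fixes a dented sphere and zero/far drags are identities", {
  mesh <- sphere_mesh(c(0, 0, 0), 30, n_theta = 24, n_phi = 48)
  expect_identical(apply_drag_mesh(mesh, drag_gesture(c(30, 0, 0), c(0, 0, 0))),
                   mesh)
  farg <- drag_gesture(c(500, 0, 0), c(2, 0, 0))
  moved <- apply_drag_mesh(mesh, farg, spacing = 5)
  expect_identical(moved$vertices, mesh$vertices)
  dent <- dent_sphere_mesh(mesh, c(0, 0, 0), c(1, 0, 0), 0.5, 4)
  g <- drag_gesture(c(26, 0, 0), c(4, 0, 0))
  fixed <- apply_drag_mesh(dent, g)
  expect_identical(fixed$faces, dent$faces)
  rad_err <- function(m) mean(abs(sqrt(rowSums(m$vertices^2)) - 30))
  expect_lt(rad_err(fixed), rad_err(dent))
})

test_that("the B-spline basis option also reproduces constants and stays local", {
  g <- drag_gesture(c(0, 0), c(2, 0))
  gr <- build_grid(g, spacing = 8)
  gr$node_vectors[, , 1] <- 3
  gr$node_vectors[, , 2] <- -1
  expect_equal(evaluate_grid(gr, c(1.3, -2.2), basis = "bspline"), c(3, -1),
               tolerance = 1e-12)
  gs <- solve_grid_vectors(build_grid(g, spacing = 8), g, basis = "bspline")
  expect_lt(max(abs(evaluate_grid(gs, g$start, basis = "bspline") - g$motion)),
            1e-8)
  expect_identical(evaluate_grid(gs, c(50, 0), basis = "bspline"), c(0, 0))
})
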