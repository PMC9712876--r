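small_pool <- function(n, seed = 1L) make_blob_pool(n, seed = seed, size = 16L)

test_that("simulated proofreading is exact at full effort and a no-op at zero", {
  p1 <- make_phantom(phantom_spec("sphere", size = 16, radius = 4, seed = 1))
  p2 <- make_phantom(phantom_spec("sphere", size = 16, radius = 6, seed = 1))
  full <- simulate_proofread(p1$mask, p2$mask, effort = 1)
  expect_identical(full$mask$labels != 0L, p2$mask$labels != 0L)
  expect_equal(full$dice_after, 1)
  none <- simulate_proofread(p1$mask, p2$mask, effort = 0)
  expect_identical(none$mask$labels, p1$mask$labels)
  expect_identical(none$n_flipped, 0L)
  wrong <- make_phantom(phantom_spec("sphere", size = 12, radius = 4, seed = 1))
  expect_error(simulate_proofread(p1$mask, wrong$mask, 1), "shapes differ")
  expect_error(simulate_proofread(p1$mask, p2$mask, 2), "effort")
})

test_that("half effort flips exactly half the discrepant voxels, worst first", {
  ph <- make_phantom(phantom_spec("sphere", size = 20, radius = 6, seed = 2))
  ref <- ph$mask
  set.seed(99)
  flip_idx <- sample(which(array(TRUE, dim(ref$labels))), 100)
  pred <- ref
  pred$labels[flip_idx] <- 1L - (ref$labels[flip_idx] != 0L)
  disc <- which((pred$labels != 0L) != (ref$labels != 0L))
  expect_length(disc, 100)
  half <- simulate_proofread(pred, ref, effort = 0.5)
  expect_identical(half$n_flipped, 50L)
  flipped <- which(half$mask$labels != pred$labels)
  # oracle ranking: descending boundary distance, ascending index tie-break
  d <- oracle_boundary_distances(disc, ref$labels)
  expected <- disc[order(-d, disc)][1:50]
  expect_setequal(flipped, expected)
  expect_equal(half$mean_correction_mm, mean(sort(d, decreasing = TRUE)[1:50]),
               tolerance = 1e-9)
})

test_that("proofread Dice is non-decreasing in effort", {
  set.seed(7)
  for (case in 1:3) {
    a <- make_phantom(phantom_spec("blobs", size = 16, seed = case))
    b <- make_phantom(phantom_spec("blobs", size = 16, seed = case + 100))
    prev <- -1
    for (e in c(0, 0.2, 0.5, 0.8, 1)) {
      r <- simulate_proofread(a$mask, b$mask, effort = e)
      expect_gte(r$dice_after, prev)
      prev <- r$dice_after
    }
  }
})

test_that("iteration bookkeeping: pools stay disjoint and the labeled pool grows", {
  pool <- small_pool(14, seed = 3)
  st <- aid_state(labeled = pool[1:2], unlabeled = pool[-(1:2)])
  ad <- reference_adapter()
  for (it in 1:2) {
    n_before <- length(st$labeled_pool)
    st <- run_iteration(st, ad, oracle_proofreader(), batch = 5)
    expect_identical(length(st$labeled_pool), n_before + 5L)
    ids_l <- vapply(st$labeled_pool, `[[`, "", "id")
    ids_u <- vapply(st$unlabeled_pool, `[[`, "", "id")
    expect_length(intersect(ids_l, ids_u), 0)
    expect_length(unique(c(ids_l, ids_u)), 14)
  }
  expect_identical(st$iteration, 2L)
  expect_identical(st$metrics[[1]]$n_train, 2L)
  expect_identical(st$metrics[[2]]$n_train, 7L)
  # exhausting the unlabeled pool is a warning no-op
  st$unlabeled_pool <- list()
  expect_warning(st2 <- run_iteration(st, ad, oracle_proofreader()), "empty")
  expect_identical(st2$iteration, st$iteration)
})

test_that("accepting predictions unchanged still grows the pool with zero correction", {
  pool <- small_pool(8, seed = 4)
  st <- aid_state(labeled = pool[1:2], unlabeled = pool[-(1:2)])
  st <- run_iteration(st, reference_adapter(), identity_proofreader(), batch = 4)
  expect_length(st$labeled_pool, 6)
  expect_identical(st$metrics[[1]]$mean_correction_mm, 0)
  expect_false(is.na(st$metrics[[1]]$mean_dice))
})

test_that("duplicate pool ids and an empty seed pool are rejected", {
  pool <- small_pool(4, seed = 5)
  expect_error(aid_state(labeled = pool[1], unlabeled = pool[c(1, 2)]),
               "unique")
  st <- aid_state(labeled = list(), unlabeled = pool)
  expect_error(run_iteration(st, reference_adapter(), oracle_proofreader()),
               "labeled pool is empty")
})

test_that("the loop runs with the adapter as external programs via the disk protocol", {
  train_p <- system.file("extdata/plugins/aid_train.R", package = "sketchkit")
  pred_p <- system.file("extdata/plugins/aid_predict.R", package = "sketchkit")
  ad <- plugin_adapter(train_p, pred_p, root = withr_tempdir())
  pool <- small_pool(6, seed = 6)
  st <- aid_state(labeled = pool[1:2], unlabeled = pool[-(1:2)])
  st <- run_iteration(st, ad, oracle_proofreader(), batch = 2)
  expect_length(st$labeled_pool, 4)
  expect_identical(st$iteration, 1L)
  # the externally trained model makes non-degenerate predictions
  expect_false(is.na(st$metrics[[1]]$mean_dice))
  expect_gt(st$metrics[[1]]$mean_dice, 0.2)
})

test_that("run_aid stops when the unlabeled pool is exhausted", {
  pool <- small_pool(7, seed = 8)
  st <- aid_state(labeled = pool[1:3], unlabeled = pool[-(1:3)])
  st <- run_aid(st, reference_adapter(), oracle_proofreader(),
                iterations = 10, batch = 2, epsilon = -1)
  expect_length(st$unlabeled_pool, 0)
  expect_identical(st$iteration, 2L)
})
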