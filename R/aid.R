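#' State of the annotation-by-iterative-learning loop
#'
#' Tracks one human-in-the-loop annotation campaign: a labeled pool of
#' (image, mask) pairs that only ever grows, an unlabeled pool of images
#' waiting for prediction and proofreading, the current model, and
#' per-iteration metrics. Every image is in exactly one pool.
#'
#' @param labeled List of `list(id =, image =, mask =)` seed annotations
#'   (non-empty before the first iteration).
#' @param unlabeled List of `list(id =, image =, mask = <optional reference>)`;
#'   a reference mask, when present, is only ever consulted by a simulated
#'   proofreader, never by the model.
#' @return An `aid_state` with `iteration = 0`.
#' @export
aid_state <- function(labeled = list(), unlabeled = list()) {
  ids <- c(vapply(labeled, `[[`, "", "id"), vapply(unlabeled, `[[`, "", "id"))
  if (anyDuplicated(ids)) {
    stop("aid_state: image ids must be unique across both pools")
  }
  structure(list(iteration = 0L, labeled_pool = labeled,
                 unlabeled_pool = unlabeled, model = NULL, models = list(),
                 metrics = list()),
            class = "aid_state")
}

#' @export
print.aid_state <- function(x, ...) {
  cat(sprintf("<aid_state> iteration %d: %d labeled, %d unlabeled\n",
              x$iteration, length(x$labeled_pool), length(x$unlabeled_pool)))
  invisible(x)
}

#' Run one iteration of the iterative-annotation loop
#'
#' One turn of the crank: (1) train the adapter on the full labeled pool,
#' (2) predict masks for the next batch of unlabeled images (FIFO order —
#' no active-learning ranking), (3) hand each prediction to the proofreader
#' for correction, (4) move the corrected pairs into the labeled pool, and
#' (5) record metrics. The labeled pool grows monotonically; an empty
#' unlabeled pool is a warning no-op.
#'
#' @param state An [aid_state].
#' @param adapter A model adapter: `list(train = function(labeled) -> model,
#'   predict = function(model, images) -> list of label_mask)`. See
#'   [reference_adapter()] and [plugin_adapter()].
#' @param proofreader Correction policy:
#'   `function(prediction, item) -> list(mask, n_flipped, mean_correction_mm,
#'   dice_before)`. See [oracle_proofreader()] and [identity_proofreader()].
#' @param batch Maximum number of unlabeled images to annotate this
#'   iteration.
#' @return The updated `aid_state`; per-iteration metrics in
#'   `state$metrics[[iteration]]` (`n_train`, `n_proofread`, `mean_dice`,
#'   `mean_correction_mm`).
#' @export
run_iteration <- function(state, adapter, proofreader, batch = 10L) {
  stopifnot(inherits(state, "aid_state"))
  if (!length(state$labeled_pool)) {
    stop("run_iteration: labeled pool is empty; seed it before iterating")
  }
  if (!length(state$unlabeled_pool)) {
    warning("run_iteration: unlabeled pool is empty; nothing to do")
    return(state)
  }
  n_train <- length(state$labeled_pool)
  model <- adapter$train(state$labeled_pool)
  take <- seq_len(min(batch, length(state$unlabeled_pool)))
  items <- state$unlabeled_pool[take]
  preds <- adapter$predict(model, lapply(items, `[[`, "image"))
  corrections <- vector("list", length(items))
  for (i in seq_along(items)) {
    corrections[[i]] <- proofreader(preds[[i]], items[[i]])
  }
  for (i in seq_along(items)) {
    state$labeled_pool[[length(state$labeled_pool) + 1L]] <- list(
      id = items[[i]]$id, image = items[[i]]$image,
      mask = corrections[[i]]$mask)
  }
  state$unlabeled_pool <- state$unlabeled_pool[-take]
  state$iteration <- state$iteration + 1L
  state$model <- model
  state$models[[state$iteration]] <- model
  num <- function(key) {
    v <- vapply(corrections, function(c0) as.numeric(c0[[key]] %||% NA_real_),
                numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  state$metrics[[state$iteration]] <- list(
    n_train = n_train, n_proofread = length(items),
    mean_dice = num("dice_before"),
    mean_correction_mm = num("mean_correction_mm"))
  state
}

#' Run several iterations with a stopping rule
#'
#' Iterates [run_iteration()] until `iterations` have run, the unlabeled
#' pool is exhausted, or the improvement in mean prediction Dice between
#' consecutive iterations falls below `epsilon` (whichever happens first).
#'
#' @inheritParams run_iteration
#' @param iterations Maximum iteration count.
#' @param epsilon Dice-improvement stopping threshold (default 0.005);
#'   only applied when the proofreader reports Dice.
#' @return The final `aid_state`.
#' @export
run_aid <- function(state, adapter, proofreader, iterations = 3L,
                    batch = 10L, epsilon = 0.005) {
  for (it in seq_len(iterations)) {
    if (!length(state$unlabeled_pool)) break
    state <- run_iteration(state, adapter, proofreader, batch = batch)
    m <- state$metrics
    if (length(m) >= 2L) {
      d_now <- m[[length(m)]]$mean_dice
      d_prev <- m[[length(m) - 1L]]$mean_dice
      if (!is.na(d_now) && !is.na(d_prev) && d_now - d_prev < epsilon &&
          it < iterations) break
    }
  }
  state
}

#' Simulate human proofreading of a predicted mask
#'
#' Moves a predicted mask toward a reference by flipping a fraction of the
#' mislabeled voxels, worst errors first: mislabeled voxels are ranked by
#' their distance to the reference boundary (descending, ties broken by
#' ascending linear voxel index) and the first `round(effort * n)` are set to
#' the reference value. `effort = 1` reproduces the reference exactly;
#' `effort = 0` is a no-op. This emulates an expert who fixes the most
#' glaring boundary errors first and stops after a given effort budget.
#'
#' @param prediction,reference Congruent [label_mask]s (binary occupancy is
#'   used).
#' @param effort Fraction of mislabeled voxels corrected, in `[0, 1]`.
#' @return List: `mask` (corrected [label_mask]), `n_flipped`,
#'   `mean_correction_mm` (mean boundary distance of the flipped voxels; 0
#'   when none), `dice_before`, `dice_after`.
#' @export
simulate_proofread <- function(prediction, reference, effort = 1) {
  stopifnot(inherits(prediction, "label_mask"), inherits(reference, "label_mask"))
  if (!identical(dim(prediction$labels), dim(reference$labels))) {
    stop("simulate_proofread: prediction and reference shapes differ")
  }
  if (effort < 0 || effort > 1) stop("simulate_proofread: effort must be in [0, 1]")
  p <- prediction$labels != 0L
  r <- reference$labels != 0L
  disc <- which(p != r)
  dice_before <- dice(p, r)
  if (!length(disc) || effort == 0) {
    return(list(mask = prediction, n_flipped = 0L, mean_correction_mm = 0,
                dice_before = dice_before, dice_after = dice_before))
  }
  d <- boundary_distance_mm(disc, r, dim(r), prediction$spacing)
  ord <- order(-d, disc)
  n_flip <- as.integer(floor(effort * length(disc) + 0.5))
  flip <- disc[ord[seq_len(n_flip)]]
  lab <- prediction$labels
  lab[flip] <- ifelse(r[flip], max(1L, max(reference$labels)), 0L)
  out <- prediction
  out$labels <- lab
  list(mask = out, n_flipped = n_flip,
       mean_correction_mm = if (n_flip) mean(d[ord[seq_len(n_flip)]]) else 0,
       dice_before = dice_before, dice_after = dice(lab != 0L, r))
}

# Distance (mm) from the voxels at linear indices `idx` to the nearest
# boundary voxel centre of mask `r` (boundary = foreground voxel with a
# 6-neighbour background or on the array edge). Exact nearest-neighbour by
# chunked brute force; the discrepancy sets this serves are small.
boundary_distance_mm <- function(idx, r, dims, spacing) {
  b <- mask_boundary(r)
  bidx <- which(b)
  if (!length(bidx)) return(rep(0, length(idx)))
  pc <- (arrayInd(idx, dims) - 1) %*% diag(spacing)
  bc <- (arrayInd(bidx, dims) - 1) %*% diag(spacing)
  out <- numeric(length(idx))
  chunk <- max(1L, floor(2e6 / nrow(bc)))
  for (s in seq(1L, length(idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(idx))
    d2 <- outer(rowSums(pc[s:e, , drop = FALSE]^2), rowSums(bc^2), "+") -
      2 * pc[s:e, , drop = FALSE] %*% t(bc)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

mask_boundary <- function(r) {
  d <- dim(r)
  shift_miss <- function(ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by == 1L) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1L) }
    else { idx_dst[[ax]] <- 1:(n - 1L); idx_src[[ax]] <- 2:n }
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(!do.call(`[`, c(list(r), idx_src)))))
    out
  }
  nb_bg <- array(FALSE, d)
  for (ax in 1:3) {
    for (by in c(1L, -1L)) nb_bg <- nb_bg | shift_miss(ax, by)
  }
  edge <- array(FALSE, d)
  for (ax in 1:3) {
    edge <- edge | do.call(`[<-`, c(list(array(FALSE, d)),
                                    slice_indexer(d, ax, 1L), list(TRUE)))
    edge <- edge | do.call(`[<-`, c(list(array(FALSE, d)),
                                    slice_indexer(d, ax, d[ax]), list(TRUE)))
  }
  r & (nb_bg | edge)
}

#' Reference weak-classifier model adapter
#'
#' A deliberately simple intensity-plus-smoothing classifier for desk-scale
#' experiments with the iterative-annotation loop. Training keeps, for each
#' labeled image, its background level (the image median — background
#' dominates the volume) and its optimal intensity threshold (midpoint of
#' the foreground/background class means under the mask). Prediction
#' estimates the new image's background level, looks up the threshold of the
#' nearest-background training image, thresholds the image, and cleans the
#' mask with a 3x3x3 majority filter. With pooled multi-protocol data (see
#' the blob phantoms' discrete intensity offsets) the model is only accurate
#' on protocols represented in its training set; since the labeled pool only
#' grows, protocol coverage — and hence accuracy — improves monotonically
#' across iterations, the learning curve real model adapters exhibit.
#' Training is deterministic (no RNG).
#'
#' @return An adapter usable with [run_iteration()].
#' @export
reference_adapter <- function() {
  list(
    name = "reference_intensity_classifier",
    train = function(labeled) {
      bg <- vapply(labeled, function(it) stats::median(it$image$voxels),
                   numeric(1))
      th <- vapply(labeled, function(it) {
        v <- it$image$voxels
        fg <- it$mask$labels != 0L
        (mean(v[fg]) + mean(v[!fg])) / 2
      }, numeric(1))
      list(bg_levels = bg, thresholds = th, n_train = length(labeled))
    },
    predict = function(model, images) {
      lapply(images, function(img) {
        j <- which.min(abs(stats::median(img$voxels) - model$bg_levels))
        raw <- img$voxels > model$thresholds[j]
        label_mask(array(as.integer(majority_filter3(raw)), dim(img$voxels)),
                   img)
      })
    }
  )
}

# 3x3x3 majority vote on a logical array (separable box sums; edge
# neighbourhoods are normalized by their actual size).
majority_filter3 <- function(x) {
  cnt <- box_sum3(array(as.numeric(x), dim(x)))
  tot <- box_sum3(array(1, dim(x)))
  cnt > tot / 2
}

box_sum3 <- function(a) {
  for (ax in 1:3) {
    d <- dim(a)
    n <- d[ax]
    lo <- do.call(`[`, c(list(a), slice_shift_index(d, ax, -1L)))
    hi <- do.call(`[`, c(list(a), slice_shift_index(d, ax, 1L)))
    a <- a + lo + hi
  }
  a
}

# index list shifting along `ax` by one voxel with edge replication (the
# replicated slice appears in both the count and the normalizer, so edge
# majorities stay consistent)
slice_shift_index <- function(d, ax, by) {
  idx <- lapply(d, seq_len)
  n <- d[ax]
  idx[[ax]] <- if (by > 0) c(2:n, n) else c(1L, 1:(n - 1L))
  idx
}

#' Model adapter backed by external programs
#'
#' Wraps a pair of external train/predict programs behind the in-process
#' adapter contract, exchanging all data through files on disk (no shared
#' state). For each call a fresh workdir is created containing
#' `img_NNN.nii.gz` (and `msk_NNN.nii.gz` when training) plus `params.json`
#' (`mode`, `n`, and the model file name); the train program must write
#' `model.json`, the predict program `prd_NNN.nii.gz` for each image. The
#' programs are invoked with the workdir as their single argument, exactly
#' like any other plugin.
#'
#' @param train_program,predict_program Program paths (dispatched by
#'   extension as in [run_plugin()]).
#' @param root Parent directory for exchange workdirs.
#' @param timeout Per-invocation wall-clock limit (seconds).
#' @return An adapter usable with [run_iteration()].
#' @export
plugin_adapter <- function(train_program, predict_program, root = tempdir(),
                           timeout = 600) {
  stage_images <- function(wd, images, masks = NULL) {
    for (i in seq_along(images)) {
      write_image(images[[i]], file.path(wd, sprintf("img_%03d.nii.gz", i)))
      if (!is.null(masks)) {
        write_image(masks[[i]], file.path(wd, sprintf("msk_%03d.nii.gz", i)))
      }
    }
  }
  check <- function(run, what) {
    if (!is.null(run$error_class)) {
      plugin_abort(run$error_class, "%s program failed (status %s)\n%s",
                   what, run$status, run$log_tail)
    }
  }
  list(
    name = "external_program_adapter",
    train = function(labeled) {
      wd <- plugin_workdir(root)
      stage_images(wd, lapply(labeled, `[[`, "image"),
                   lapply(labeled, `[[`, "mask"))
      writeLines(jsonlite::toJSON(list(mode = "train", n = length(labeled)),
                                  auto_unbox = TRUE),
                 file.path(wd, "params.json"))
      check(run_program(train_program, wd, timeout), "train")
      model_file <- file.path(wd, "model.json")
      if (!file.exists(model_file)) {
        plugin_abort("plugin_output_error",
                     "train program wrote no model.json in %s", wd)
      }
      list(model_file = model_file)
    },
    predict = function(model, images) {
      wd <- plugin_workdir(root)
      stage_images(wd, images)
      file.copy(model$model_file, file.path(wd, "model.json"))
      writeLines(jsonlite::toJSON(list(mode = "predict", n = length(images)),
                                  auto_unbox = TRUE),
                 file.path(wd, "params.json"))
      check(run_program(predict_program, wd, timeout), "predict")
      lapply(seq_along(images), function(i) {
        p <- file.path(wd, sprintf("prd_%03d.nii.gz", i))
        if (!file.exists(p)) {
          plugin_abort("plugin_output_error",
                       "predict program wrote no %s", basename(p))
        }
        img <- read_image(p)
        label_mask(array(as.integer(round(img$voxels)), dim(img$voxels)), img)
      })
    }
  )
}

#' Correction policies for simulated proofreading
#'
#' `oracle_proofreader(effort)` corrects predictions toward each item's
#' reference mask via [simulate_proofread()]; `identity_proofreader()`
#' accepts every prediction unchanged (zero correction), the degenerate
#' policy.
#'
#' @param effort Correction effort passed to [simulate_proofread()].
#' @return A proofreader function for [run_iteration()].
#' @export
oracle_proofreader <- function(effort = 1) {
  function(prediction, item) {
    if (is.null(item$mask)) {
      stop("oracle_proofreader: pool item carries no reference mask")
    }
    simulate_proofread(prediction, item$mask, effort = effort)
  }
}

#' @rdname oracle_proofreader
#' @export
identity_proofreader <- function() {
  function(prediction, item) {
    db <- if (!is.null(item$mask)) dice(prediction, item$mask) else NA_real_
    list(mask = prediction, n_flipped = 0L, mean_correction_mm = 0,
         dice_before = db, dice_after = db)
  }
}

#' Mean held-out Dice of a trained model
#'
#' @param adapter The adapter whose `predict` is used.
#' @param model A model returned by the adapter's `train`.
#' @param heldout List of `list(image =, mask =)` evaluation pairs.
#' @return Mean Dice over the held-out pairs.
#' @export
aid_evaluate <- function(adapter, model, heldout) {
  preds <- adapter$predict(model, lapply(heldout, `[[`, "image"))
  mean(vapply(seq_along(heldout), function(i) {
    dice(preds[[i]], heldout[[i]]$mask)
  }, numeric(1)))
}

#' Build a synthetic image pool for loop experiments
#'
#' Generates `n` blob phantoms (random ellipsoid "organs", each with one of
#' a few discrete acquisition-protocol intensity offsets) with consecutive
#' seeds derived from `seed`, as `list(id, image, mask)` items.
#'
#' @param n Number of images.
#' @param seed Base seed; image `i` uses `seed * 1000 + i`.
#' @param size,noise_sigma Passed to [phantom_spec()].
#' @param ... Further blob parameters (`bg`, `fg`, `offset_levels`, ...).
#' @return List of pool items.
#' @export
make_blob_pool <- function(n, seed = 1L, size = 32L, noise_sigma = 12, ...) {
  lapply(seq_len(n), function(i) {
    ph <- make_phantom(phantom_spec("blobs", size = size,
                                    noise_sigma = noise_sigma,
                                    seed = as.integer((as.numeric(seed) * 1000 + i) %%
                                                        .Machine$integer.max), ...))
    list(id = sprintf("blob_%d_%03d", seed, i), image = ph$image,
         mask = ph$mask)
  })
}
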