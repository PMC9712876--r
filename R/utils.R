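#' @keywords internal
"_PACKAGE"

# Axis name <-> index helpers. Internal axis order is fixed to (x, y, z),
# matching the array dimensions of an Image3D.
AXIS_NAMES <- c("x", "y", "z")

axis_index <- function(axis) {
  if (is.numeric(axis)) {
    axis <- as.integer(axis)
    if (axis < 1L || axis > 3L) stop("axis index must be 1, 2 or 3")
    return(axis)
  }
  i <- match(match.arg(as.character(axis), AXIS_NAMES), AXIS_NAMES)
  i
}

# The two in-plane axes (ascending order) for a slice orthogonal to `axis`.
inplane_axes <- function(axis) setdiff(1:3, axis_index(axis))

vnorm <- function(v) sqrt(sum(v^2))

is_finite_vec <- function(v, n = NULL) {
  is.numeric(v) && all(is.finite(v)) && (is.null(n) || length(v) == n)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All phantom generators route randomness through this
# so that a spec + seed is bit-reproducible regardless of ambient RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Dice overlap coefficient between two masks
#'
#' Computes `2|A n B| / (|A| + |B|)` over the non-zero voxels of two congruent
#' arrays (or [label_mask] objects). Two empty masks have Dice 1 by convention.
#'
#' @param a,b Logical/integer arrays of identical shape, or `label_mask`s.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_mask_array(a)
  b <- as_mask_array(b)
  if (!identical(dim(a), dim(b))) stop("dice: mask shapes differ")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

as_mask_array <- function(x) {
  if (inherits(x, "label_mask")) x <- x$labels
  if (inherits(x, "threshold_result")) x <- x$mask$labels
  x != 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
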