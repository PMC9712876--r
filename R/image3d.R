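#' 3D image volume with physical-space metadata
#'
#' The substrate of all annotation: a 3D voxel array together with the affine
#' map from 0-based voxel indices to physical coordinates in millimetres.
#' The internal axis order is the array order `(x, y, z)` and is treated as an
#' RAS-like canonical frame; readers reorient on load. Voxel centres sit at
#' `origin + index * spacing`, so all annotation coordinates can be stored in
#' physical mm and survive resampling.
#'
#' @param voxels Numeric 3D array.
#' @param spacing Length-3 positive numeric, physical step per axis (mm).
#' @param origin Length-3 numeric, physical coordinate of voxel (0,0,0) (mm).
#' @return An object of class `image3d` with fields `voxels`, `spacing`,
#'   `origin`, `axis_order`.
#' @examples
#' img <- image3d(array(0, c(8, 8, 4)), spacing = c(1, 1, 2.5))
#' index_to_phys(img, c(1, 2, 3))
#' @export
image3d <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("image3d: voxels must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (!is_finite_vec(spacing, 3L) || any(spacing <= 0)) {
    stop("image3d: spacing must be three strictly positive finite numbers")
  }
  if (!is_finite_vec(origin, 3L)) stop("image3d: origin must be finite length 3")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         axis_order = "xyz"),
    class = "image3d"
  )
}

#' @export
print.image3d <- function(x, ...) {
  cat(sprintf("<image3d> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image3d <- function(x) dim(x$voxels)

#' Voxel-index / physical-coordinate transforms
#'
#' `index_to_phys` maps 0-based voxel indices to physical mm coordinates;
#' `phys_to_index` is its exact inverse (returning fractional indices).
#' Both accept a single length-3 vector or an n-by-3 matrix.
#'
#' @param image An [image3d].
#' @param idx,pos Length-3 vector or n-by-3 matrix.
#' @return Same shape as the input.
#' @export
index_to_phys <- function(image, idx) {
  stopifnot(inherits(image, "image3d"))
  if (is.matrix(idx)) {
    sweep(sweep(idx, 2, image$spacing, "*"), 2, image$origin, "+")
  } else {
    image$origin + as.numeric(idx) * image$spacing
  }
}

#' @rdname index_to_phys
#' @export
phys_to_index <- function(image, pos) {
  stopifnot(inherits(image, "image3d"))
  if (is.matrix(pos)) {
    sweep(sweep(pos, 2, image$origin, "-"), 2, image$spacing, "/")
  } else {
    (as.numeric(pos) - image$origin) / image$spacing
  }
}

# Physical coordinates of all voxel centres along one axis.
axis_coords <- function(image, axis) {
  a <- axis_index(axis)
  image$origin[a] + (seq_len(dim(image$voxels)[a]) - 1) * image$spacing[a]
}

#' Read a volume from a NIfTI file
#'
#' Loads a NIfTI-1 file into an [image3d], reorienting the voxel data to the
#' canonical RAS axis order so that spacing is positive on every axis. The
#' original on-disk orientation string is kept in the `source_orientation`
#' attribute for provenance.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return An [image3d].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_image: no such file: %s", path))
  ext <- tolower(path)
  if (!grepl("\\.nii(\\.gz)?$", ext)) {
    stop(sprintf("read_image: unsupported format (expect .nii/.nii.gz): %s", path))
  }
  nii <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop(sprintf(
                    "read_image: failed to parse '%s' as NIfTI: %s",
                    path, conditionMessage(e))))
  src_orient <- tryCatch(RNifti::orientation(nii), error = function(e) NA_character_)
  if (!is.na(src_orient) && !identical(src_orient, "RAS")) {
    RNifti::orientation(nii) <- "RAS"
  }
  if (length(dim(nii)) == 4L && dim(nii)[4] == 1L) {
    dim(nii) <- dim(nii)[1:3]
  }
  if (length(dim(nii)) != 3L) {
    stop(sprintf("read_image: expected a 3D volume, got %d dimensions",
                 length(dim(nii))))
  }
  xfm <- RNifti::xform(nii)
  spacing <- sqrt(colSums(xfm[1:3, 1:3]^2))
  # Require an axis-aligned transform: off-diagonal terms must vanish.
  offdiag <- abs(xfm[1:3, 1:3]) - diag(abs(diag(xfm[1:3, 1:3])))
  if (any(abs(offdiag) > 1e-6 * max(spacing))) {
    stop("read_image: oblique (non axis-aligned) orientations are not supported")
  }
  origin <- xfm[1:3, 4]
  img <- image3d(array(as.numeric(nii), dim = dim(nii)),
                 spacing = spacing, origin = origin)
  attr(img, "source_orientation") <- src_orient
  img
}

#' Write a volume to a NIfTI file
#'
#' @param image An [image3d] (or [label_mask], written as an integer volume).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "label_mask")) {
    image <- image3d(array(as.numeric(image$labels), dim = dim(image$labels)),
                     spacing = image$spacing, origin = image$origin)
  }
  stopifnot(inherits(image, "image3d"))
  xfm <- diag(4)
  diag(xfm)[1:3] <- image$spacing
  xfm[1:3, 4] <- image$origin
  nii <- RNifti::asNifti(image$voxels)
  RNifti::pixdim(nii) <- image$spacing  # before the xforms: scale lives here
  RNifti::qform(nii) <- structure(xfm, code = 2L)
  RNifti::sform(nii) <- structure(xfm, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}
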