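# Volume masks live on a voxel grid with a 4x4 affine mapping ZERO-BASED
# voxel indices (i, j, k, 1) to world mm coordinates. Array storage in R is
# one-based; all public functions return one-based indices and the helpers
# below do the conversion in one place.

#' Construct a volume mask
#'
#' @param values Logical (or coercible) 3-D array.
#' @param affine 4x4 invertible matrix mapping zero-based voxel indices to mm.
#' @param source_threshold Threshold applied if the source volume was
#'   non-binary (kept for provenance).
#' @return An object of class `cbma_volume_mask`.
#' @export
volume_mask <- function(values, affine, source_threshold = 0) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    cbma_abort("mask values must form a 3-D array", "cbma_not_a_volume")
  }
  storage.mode(values) <- "logical"
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps) {
    cbma_abort("affine must be an invertible 4x4 matrix", "cbma_bad_arguments")
  }
  structure(
    list(values = values, affine = affine, shape = dim(values),
         source_threshold = source_threshold),
    class = "cbma_volume_mask")
}

#' @export
print.cbma_volume_mask <- function(x, ...) {
  cat(sprintf("<volume mask> %s voxels, %d in mask, voxel size %s mm\n",
              paste(x$shape, collapse = "x"), sum(x$values),
              paste(signif(voxel_size(x), 3), collapse = "x")))
  invisible(x)
}

voxel_size <- function(m) {
  sqrt(colSums(m$affine[1:3, 1:3]^2))
}

#' Read a NIfTI volume as a boolean mask
#'
#' Non-binary volumes are binarized with a strict `value > threshold` rule
#' (threshold 0 by default, matching the convention for region-of-interest
#' masks in coordinate-based meta-analysis). A warning is raised when the
#' voxel size is not the expected 2 x 2 x 2 mm Talairach grid; any
#' user-defined segmented mask is still accepted.
#'
#' @param path Path to a 3-D NIfTI file (`.nii` or `.nii.gz`).
#' @param threshold Binarization threshold; voxels strictly greater are in
#'   the mask.
#' @return A [volume_mask()].
#' @export
read_mask <- function(path, threshold = 0) {
  if (!file.exists(path)) {
    cbma_abort(sprintf("file not found: '%s'", path), "cbma_file_not_found")
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    cbma_abort(sprintf("cannot read NIfTI file '%s': %s",
                                       path, conditionMessage(e)),
                               "cbma_unreadable_file")
                  })
  dm <- dim(img)
  if (length(dm) > 3L) {
    if (all(dm[-(1:3)] == 1L)) {
      img2 <- array(as.numeric(img), dim = dm[1:3])
    } else {
      cbma_abort(sprintf("expected a 3-D volume, got %d-D", length(dm)),
                 "cbma_not_a_volume")
    }
  } else if (length(dm) < 3L) {
    cbma_abort(sprintf("expected a 3-D volume, got %d-D", length(dm)),
               "cbma_not_a_volume")
  } else {
    img2 <- array(as.numeric(img), dim = dm)
  }
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  m <- volume_mask(img2 > threshold, affine, source_threshold = threshold)
  vs <- voxel_size(m)
  if (any(abs(vs - 2) > 1e-4)) {
    cbma_warn(sprintf(
      "voxel size is %s mm, not the expected 2x2x2 mm Talairach grid",
      paste(signif(vs, 4), collapse = "x")), "cbma_grid_warning")
  }
  m
}

#' Write a mask (or scalar volume) as NIfTI
#'
#' @param v A [volume_mask()] or `cbma_scalar_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, c("cbma_volume_mask", "cbma_scalar_volume")))
  arr <- v$values
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  vs <- sqrt(colSums(v$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vs
  img <- RNifti::`qform<-`(img, structure(v$affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Continuous zero-based voxel coordinates for a matrix of mm positions.
mm_to_continuous_index <- function(m, xyz) {
  xyz <- as_foci_matrix(xyz)
  inv <- solve(m$affine)
  h <- cbind(xyz, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

#' Map mm coordinates to voxel indices
#'
#' Applies the inverse affine and rounds each continuous index to the
#' nearest voxel (ties rounded half away from zero, a fixed and documented
#' rule so boundary foci are handled deterministically). Coordinates whose
#' nearest voxel falls off the grid map to `NA`.
#'
#' @param m A [volume_mask()].
#' @param xyz Numeric vector `c(x, y, z)` in mm, or an n x 3 matrix.
#' @return An n x 3 integer matrix of one-based voxel indices; rows are
#'   all-`NA` for positions outside the grid. For a single coordinate a
#'   length-3 vector is returned.
#' @export
mm_to_voxel <- function(m, xyz) {
  single <- is.vector(xyz) && length(xyz) == 3L
  cont <- mm_to_continuous_index(m, xyz)
  idx0 <- round_half_away(cont)
  inside <- idx0[, 1] >= 0 & idx0[, 1] < m$shape[1] &
            idx0[, 2] >= 0 & idx0[, 2] < m$shape[2] &
            idx0[, 3] >= 0 & idx0[, 3] < m$shape[3]
  out <- idx0 + 1
  out[!inside, ] <- NA_real_
  storage.mode(out) <- "integer"
  colnames(out) <- c("i", "j", "k")
  if (single) out[1, ] else out
}

#' Test foci for mask membership
#'
#' A focus is in the mask iff its nearest voxel (see [mm_to_voxel()]) lies
#' on the grid and that voxel is `TRUE`.
#'
#' @param m A [volume_mask()].
#' @param foci Numeric n x 3 matrix of mm coordinates (or a single
#'   `c(x, y, z)`).
#' @return Logical vector of length n.
#' @export
foci_in_mask <- function(m, foci) {
  idx <- mm_to_voxel(m, foci)
  if (is.vector(idx)) idx <- matrix(idx, ncol = 3L)
  ok <- !is.na(idx[, 1])
  res <- logical(nrow(idx))
  if (any(ok)) res[ok] <- m$values[idx[ok, , drop = FALSE]]
  res
}

#' @rdname foci_in_mask
#' @export
focus_in_mask <- function(m, foci) foci_in_mask(m, foci)

# mm position of the centers of given one-based voxel indices.
voxel_to_mm <- function(m, ijk) {
  ijk <- as.matrix(ijk)
  if (ncol(ijk) != 3L) ijk <- matrix(ijk, ncol = 3L)
  h <- cbind(ijk - 1, 1) %*% t(m$affine)
  h[, 1:3, drop = FALSE]
}
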