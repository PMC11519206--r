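# Modeled-activation (MA) maps, ALE union maps, and the voxel-wise
# robustness index used to summarize post hoc validation runs.

#' Construct a scalar volume
#'
#' A real-valued grid sharing the geometry conventions of [volume_mask()]
#' (4x4 affine over zero-based voxel indices). MA/ALE values lie in [0, 1];
#' robustness indices are non-negative integer counts.
#'
#' @param values Numeric 3-D array.
#' @param affine 4x4 invertible voxel-to-mm matrix.
#' @return An object of class `cbma_scalar_volume`.
#' @export
scalar_volume <- function(values, affine) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    cbma_abort("values must form a 3-D array", "cbma_not_a_volume")
  }
  storage.mode(values) <- "double"
  affine <- as.matrix(affine)
  structure(list(values = values, affine = affine, shape = dim(values)),
            class = "cbma_scalar_volume")
}

#' @export
print.cbma_scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar volume> %s voxels, range [%.4g, %.4g]\n",
              paste(x$shape, collapse = "x"), min(x$values), max(x$values)))
  invisible(x)
}

#' Sample-size-dependent Gaussian kernel specification
#'
#' The MA kernel width shrinks as the sample size grows, reflecting the
#' lower spatial uncertainty of larger studies. The mapping from subject
#' count to full width at half maximum (FWHM) is pluggable; the packaged
#' default, `sqrt(5.7^2 + 11.6^2 / n)` mm, is a smooth strictly decreasing
#' stand-in with a realistic scale (about 7 mm at n = 10) and is not a
#' replica of any specific ALE implementation — supply your own `fwhm`
#' function to match one.
#'
#' @param fwhm Function mapping a subject count to an FWHM in mm; must be
#'   positive and non-increasing.
#' @param truncate Truncation radius as a multiple of the FWHM (kernel
#'   contributions beyond `truncate * FWHM` are set to zero, bounding
#'   compute).
#' @return An object of class `cbma_kernel_spec`.
#' @export
kernel_spec <- function(fwhm = default_fwhm, truncate = 3) {
  stopifnot(is.function(fwhm), is.numeric(truncate), truncate > 0)
  probe <- vapply(c(5, 20, 80, 160), fwhm, numeric(1))
  if (any(!is.finite(probe)) || any(probe <= 0) ||
      any(diff(probe) > 1e-12)) {
    cbma_abort("fwhm(n) must be positive and non-increasing in n",
               "cbma_kernel_undefined")
  }
  structure(list(fwhm = fwhm, truncate = truncate),
            class = "cbma_kernel_spec")
}

#' @rdname kernel_spec
#' @param n Subject count.
#' @export
default_fwhm <- function(n) sqrt(5.7^2 + 11.6^2 / n)

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Modeled-activation map of one experiment
#'
#' Each focus contributes an isotropic 3-D Gaussian, peak-normalized to 1
#' at the focus position, with sigma = FWHM / (2 * sqrt(2 * ln 2)) where the
#' FWHM depends on the experiment's sample size via the kernel
#' specification. Contributions are truncated at the kernel's truncation
#' radius. Per voxel, foci of the same experiment are combined by taking
#' the MAXIMUM, so MA values stay interpretable as probabilities in [0, 1].
#'
#' @param e An [experiment()] with at least one focus.
#' @param grid A [volume_mask()] or `cbma_scalar_volume` defining the
#'   output geometry (values are ignored).
#' @param kernel A [kernel_spec()].
#' @return A [scalar_volume()] on `grid`'s geometry.
#' @export
ma_map <- function(e, grid, kernel = kernel_spec()) {
  stopifnot(inherits(e, "cbma_experiment"),
            inherits(kernel, "cbma_kernel_spec"))
  if (nrow(e$foci) == 0L) {
    cbma_abort("experiment has no foci", "cbma_no_foci")
  }
  fw <- kernel$fwhm(e$n_subjects)
  if (!is.finite(fw) || fw <= 0) {
    cbma_abort(sprintf("kernel undefined for n = %d subjects",
                       e$n_subjects), "cbma_kernel_undefined")
  }
  sigma <- fw * FWHM_TO_SIGMA
  radius <- kernel$truncate * fw
  shape <- grid$shape
  affine <- grid$affine
  inv <- solve(affine)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  out <- array(0, dim = shape)
  for (f in seq_len(nrow(e$foci))) {
    xyz <- e$foci[f, ]
    c0 <- (inv %*% c(xyz, 1))[1:3]
    lo <- pmax(ceiling(c0 - radius / vs), 0)
    hi <- pmin(floor(c0 + radius / vs), shape - 1)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    idx0 <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    mm <- cbind(idx0, 1) %*% t(affine)
    d2 <- (mm[, 1] - xyz[1])^2 + (mm[, 2] - xyz[2])^2 +
      (mm[, 3] - xyz[3])^2
    g <- exp(-d2 / (2 * sigma^2))
    g[d2 > radius^2] <- 0
    lin <- 1L + idx0[, 1] + shape[1] * (idx0[, 2] + shape[2] * idx0[, 3])
    out[lin] <- pmax(out[lin], g)
  }
  scalar_volume(out, affine)
}

check_same_grid <- function(vols) {
  if (length(vols) == 0L) {
    cbma_abort("need at least one volume", "cbma_empty_list")
  }
  ref <- vols[[1]]
  for (v in vols[-1]) {
    if (!identical(v$shape, ref$shape) ||
        max(abs(v$affine - ref$affine)) > 1e-6) {
      cbma_abort("volumes do not share the same grid", "cbma_grid_mismatch")
    }
  }
  ref
}

#' ALE map as the probabilistic union of MA maps
#'
#' Voxel-wise union of independent activation probabilities:
#' `ALE = 1 - prod(1 - MA_i)`. Commutative in its inputs, bounded in
#' [0, 1], and the identity for a single map.
#'
#' @param mas List of [scalar_volume()] MA maps on a shared grid.
#' @return A [scalar_volume()].
#' @export
ale_union <- function(mas) {
  ref <- check_same_grid(mas)
  acc <- array(1, dim = ref$shape)
  for (v in mas) acc <- acc * (1 - v$values)
  scalar_volume(1 - acc, ref$affine)
}

#' Full ALE pipeline over a dataset
#'
#' Convenience wrapper: one MA map per experiment, combined with
#' [ale_union()]. Statistical thresholding of the resulting map is out of
#' scope; feed the map to dedicated inference tools.
#'
#' @param foci A [foci_dataset()] or path to a foci file.
#' @param grid A [volume_mask()] defining the output geometry.
#' @param kernel A [kernel_spec()].
#' @return A [scalar_volume()] ALE map.
#' @export
compute_ale <- function(foci, grid, kernel = kernel_spec()) {
  d <- as_foci_dataset(foci)
  if (n_experiments(d) == 0L) {
    cbma_abort("dataset contains no experiments", "cbma_empty_dataset")
  }
  ale_union(lapply(d$experiments, ma_map, grid = grid, kernel = kernel))
}

#' Voxel-wise robustness index
#'
#' Given thresholded (binary) significance maps from repeated analyses on
#' different partitions of a dataset — e.g. the leave-one-experiment-out or
#' subset runs prepared by this package — the robustness index counts, for
#' each voxel, in how many of the tested conditions a significant effect
#' was found. Greater values mean stronger generalizability and
#' replicability across subsamples. Thresholding itself is performed by
#' external inference tools; this function only aggregates their binary
#' outputs.
#'
#' @param significance_maps List of [volume_mask()] or binary
#'   [scalar_volume()] objects on a shared grid.
#' @return A [scalar_volume()] of integer counts (0 .. number of maps).
#' @export
robustness_index <- function(significance_maps) {
  ref <- check_same_grid(significance_maps)
  acc <- array(0, dim = ref$shape)
  for (v in significance_maps) {
    vals <- v$values
    if (is.logical(vals)) vals <- as.numeric(vals)
    if (any(!(vals %in% c(0, 1)))) {
      cbma_abort("significance maps must be binary (0/1 or logical)",
                 "cbma_bad_arguments")
    }
    acc <- acc + vals
  }
  scalar_volume(acc, ref$affine)
}
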