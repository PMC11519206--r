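# Shared fixture builders; everything is generated in code.

make_exp <- function(key = "SmithJ,2001", n = 12L,
                     foci = c(10, 20, 30), detail = NULL) {
  experiment(key, n, foci,
             metadata_lines = c(paste0(key, ":",
                                       if (is.null(detail)) "" else
                                         paste0(" ", detail)),
                                paste0("Subjects=", n)))
}

# A dataset of `n` single-focus experiments with distinct keys.
simple_dataset <- function(n, years = NULL, subjects = NULL) {
  if (is.null(years)) years <- 2000L + seq_len(n)
  if (is.null(subjects)) subjects <- 10L + seq_len(n)
  exps <- lapply(seq_len(n), function(i) {
    make_exp(sprintf("Author%02d,%d", i, years[i]), subjects[i],
             c(i, -i, 2 * i))
  })
  foci_dataset(exps)
}

# Small centered 2 mm grid with a spherical mask; guaranteed to contain
# both in-mask and off-mask voxels.
small_mask <- function(shape = c(10L, 10L, 10L), radius = 5) {
  generate_mask(shape, c(0, 0, 0), radius)
}

# Brute-force mask membership: nearest voxel center by exhaustive search
# over every voxel of the grid (independent of the package's affine math).
brute_force_in_mask <- function(mask, foci) {
  idx <- which(array(TRUE, dim = mask$shape), arr.ind = TRUE)
  centers <- cbind(idx - 1, 1) %*% t(mask$affine)
  apply(matrix(foci, ncol = 3), 1, function(f) {
    d2 <- (centers[, 1] - f[1])^2 + (centers[, 2] - f[2])^2 +
      (centers[, 3] - f[3])^2
    mask$values[matrix(idx[which.min(d2), ], ncol = 3)]
  })
}
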