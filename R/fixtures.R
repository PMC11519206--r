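# Synthetic-data generation: random foci datasets with controllable
# duplicate/same-paper structure, toy spherical masks on a 2 mm grid, and a
# deterministic synthetic stand-in for a published-style example dataset.
# Everything is built in code so the package is testable without downloads.

#' Specification for a synthetic foci dataset
#'
#' @param n_experiments Total number of experiments in the file.
#' @param n_duplicate_pairs Number of byte-identical experiment pairs
#'   (each pair counts as two of `n_experiments`).
#' @param same_paper_groups Integer vector of group sizes (>= 2); each group
#'   shares one author-year key but differs in foci and subjects.
#' @param subjects_range,years_range,foci_per_experiment Integer intervals
#'   `c(lo, hi)` sampled uniformly. Defaults emulate a typical CBMA
#'   dataset: sample sizes 5-160, years 1995-2020, 3-12 foci per
#'   experiment.
#' @param in_mask_fraction Fraction of each experiment's foci placed at
#'   in-mask voxel centers when a companion mask is supplied.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `cbma_fixture_spec`.
#' @export
fixture_spec <- function(n_experiments = 30L, n_duplicate_pairs = 0L,
                         same_paper_groups = integer(0),
                         subjects_range = c(5L, 160L),
                         years_range = c(1995L, 2020L),
                         foci_per_experiment = c(3L, 12L),
                         in_mask_fraction = 0.8, seed = 1L) {
  n <- as.integer(n_experiments)
  ndup <- as.integer(n_duplicate_pairs)
  groups <- as.integer(same_paper_groups)
  if (length(groups) > 0L && any(groups < 2L)) {
    cbma_abort("same-paper group sizes must be >= 2", "cbma_inconsistent_spec")
  }
  n_single <- n - 2L * ndup - sum(groups)
  if (n < 1L || ndup < 0L || n_single < 0L) {
    cbma_abort(
      "counts inconsistent: duplicates + grouped + singletons must equal n",
      "cbma_inconsistent_spec")
  }
  if (in_mask_fraction < 0 || in_mask_fraction > 1) {
    cbma_abort("in_mask_fraction must lie in [0, 1]", "cbma_inconsistent_spec")
  }
  structure(
    list(n_experiments = n, n_duplicate_pairs = ndup,
         same_paper_groups = groups, n_singletons = n_single,
         subjects_range = as.integer(subjects_range),
         years_range = as.integer(years_range),
         foci_per_experiment = as.integer(foci_per_experiment),
         in_mask_fraction = in_mask_fraction, seed = as.integer(seed)),
    class = "cbma_fixture_spec")
}

SURNAME_POOL <- c(
  "Smith", "Jones", "Brown", "Garcia", "Miller", "Davis", "Lopez", "Wilson",
  "Martin", "Clark", "Lewis", "Walker", "Hall", "Young", "King", "Wright",
  "Scott", "Green", "Baker", "Adams", "Nelson", "Hill", "Campbell", "Rossi",
  "Ferrari", "Bianchi", "Moreau", "Fischer", "Weber", "Tanaka", "Suzuki",
  "Kim", "Chen", "Costa", "Silva", "Novak", "Kowalski", "Olsen", "Lindberg",
  "Virtanen")

#' Generate a synthetic foci dataset
#'
#' Produces a dataset that passes strict parsing, with exactly the requested
#' number of byte-identical duplicate pairs and same-paper groups, subject
#' counts and years drawn from the spec's ranges, and (when a companion mask
#' is given) the requested fraction of each experiment's foci placed exactly
#' at in-mask voxel centers — the remainder at off-mask voxel centers — so
#' mask membership is unambiguous under any reasonable rounding rule.
#'
#' @param spec A [fixture_spec()].
#' @param mask Optional [volume_mask()] with both in-mask and off-mask
#'   voxels.
#' @return A [foci_dataset()].
#' @export
generate_dataset <- function(spec, mask = NULL) {
  stopifnot(inherits(spec, "cbma_fixture_spec"))
  with_seed(spec$seed, {
    n_papers <- spec$n_duplicate_pairs + length(spec$same_paper_groups) +
      spec$n_singletons
    keys <- make_unique_keys(n_papers, spec$years_range)
    paper_sizes <- c(rep(1L, spec$n_duplicate_pairs),
                     spec$same_paper_groups,
                     rep(1L, spec$n_singletons))
    is_dup_paper <- seq_len(n_papers) <= spec$n_duplicate_pairs

    experiments <- list()
    for (pp in seq_len(n_papers)) {
      for (memb in seq_len(paper_sizes[pp])) {
        e <- random_experiment(keys[pp], spec, mask,
                               detail = if (paper_sizes[pp] > 1L)
                                 sprintf("contrast %d", memb) else NULL)
        experiments <- c(experiments, list(e))
        if (is_dup_paper[pp]) {
          experiments <- c(experiments, list(e))  # byte-identical copy
        }
      }
    }
    ord <- sample.int(length(experiments))
    foci_dataset(experiments[ord], source_name = "synthetic")
  })
}

make_unique_keys <- function(n_papers, years_range) {
  keys <- character(0)
  while (length(keys) < n_papers) {
    name <- paste0(sample_one(SURNAME_POOL), sample_one(LETTERS))
    year <- sample_int_range(years_range[1], years_range[2])
    key <- paste0(name, ",", year)
    if (!(key %in% keys)) keys <- c(keys, key)
  }
  keys
}

random_experiment <- function(key, spec, mask, detail = NULL) {
  nf <- sample_int_range(spec$foci_per_experiment[1],
                         spec$foci_per_experiment[2])
  n_subj <- sample_int_range(spec$subjects_range[1], spec$subjects_range[2])
  if (is.null(mask)) {
    foci <- matrix(sample(seq(-40L, 40L), 3L * nf, replace = TRUE),
                   ncol = 3L)
  } else {
    n_in <- round(spec$in_mask_fraction * nf)
    foci <- rbind(mask_voxel_centers(mask, n_in, inside = TRUE),
                  mask_voxel_centers(mask, nf - n_in, inside = FALSE))
  }
  first <- paste0(key, ":", if (is.null(detail)) "" else paste0(" ", detail))
  experiment(key, n_subj, foci,
             metadata_lines = c(first, paste0("Subjects=", n_subj)))
}

# mm coordinates of `n` randomly chosen voxel centers with the requested
# membership status.
mask_voxel_centers <- function(mask, n, inside = TRUE) {
  if (n <= 0L) return(as_foci_matrix(NULL))
  pool <- which(mask$values == inside, arr.ind = TRUE)
  if (nrow(pool) == 0L) {
    cbma_abort(sprintf("mask has no %s voxels",
                       if (inside) "in-mask" else "off-mask"),
               "cbma_inconsistent_spec")
  }
  pick <- pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
  voxel_to_mm(mask, pick)
}

#' Generate a spherical toy mask on a 2 mm grid
#'
#' The mask is the union of voxel-center-in-sphere tests; the affine places
#' voxel centers on a regular `voxel_size` grid centered on the origin.
#'
#' @param shape Grid dimensions (3 positive integers).
#' @param centers Matrix (or single vector) of sphere centers in mm.
#' @param radii Vector of radii in mm (recycled against centers).
#' @param voxel_size Edge length in mm (default 2, the Talairach
#'   convention).
#' @return A [volume_mask()].
#' @export
generate_mask <- function(shape, centers, radii, voxel_size = 2) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.vector(centers)) centers <- matrix(centers, ncol = 3L)
  centers <- as.matrix(centers)
  radii <- rep_len(radii, nrow(centers))
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  mm_lo <- affine[1:3, 4] - voxel_size / 2
  mm_hi <- affine[1:3, 4] + voxel_size * (shape - 1) + voxel_size / 2
  for (s in seq_len(nrow(centers))) {
    if (any(centers[s, ] - radii[s] < mm_lo) ||
        any(centers[s, ] + radii[s] > mm_hi)) {
      cbma_abort(sprintf("sphere %d (radius %.1f mm) does not fit the grid",
                         s, radii[s]), "cbma_out_of_grid")
    }
  }
  idx0 <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                                k = 0:(shape[3] - 1)))
  mm <- cbind(idx0, 1) %*% t(affine)
  inside <- rep(FALSE, nrow(mm))
  for (s in seq_len(nrow(centers))) {
    d2 <- (mm[, 1] - centers[s, 1])^2 + (mm[, 2] - centers[s, 2])^2 +
      (mm[, 3] - centers[s, 3])^2
    inside <- inside | (d2 <= radii[s]^2)
  }
  volume_mask(array(inside, dim = shape), affine)
}

#' Foci on voxel midplanes
#'
#' Emits mm positions exactly halfway between adjacent voxel centers along
#' the x axis — the worst case for any mm-to-voxel rounding rule — to test
#' that tie handling is deterministic and documented.
#'
#' @param mask A [volume_mask()].
#' @param n Number of boundary foci (taken from the first voxels in storage
#'   order).
#' @return An n x 3 matrix of mm coordinates.
#' @export
boundary_foci <- function(mask, n = 10L) {
  vx <- voxel_size(mask)[1]
  idx <- which(array(TRUE, dim = mask$shape), arr.ind = TRUE)
  idx <- idx[idx[, 1] < mask$shape[1], , drop = FALSE]
  idx <- idx[seq_len(min(n, nrow(idx))), , drop = FALSE]
  ctr <- voxel_to_mm(mask, idx)
  ctr[, 1] <- ctr[, 1] + vx / 2
  ctr
}

#' Deterministic synthetic example dataset
#'
#' A fully synthetic stand-in for a typical published CBMA example dataset,
#' built without randomness so every downstream count is reproducible. It
#' contains 34 experiments from 30 papers (one paper contributes three
#' experiments and two papers contribute two each, so enforcing within-paper
#' independence always retains 30); seven papers report foci exclusively
#' outside the companion gray-matter mask (so tissue filtering of the
#' independence-cleaned dataset always retains 23 experiments); sample
#' sizes range 5-160 with mean 25, and publication years span 1995-2020
#' with median 2007. Five singleton papers place one focus inside the
#' companion region-of-interest sphere.
#'
#' @return A list with elements `dataset` (a [foci_dataset()] of 34
#'   experiments), `gm_mask` (spherical gray-matter stand-in mask) and
#'   `roi` (small spherical region of interest), all on a shared
#'   24x24x24-voxel 2 mm grid.
#' @export
synthetic_example_dataset <- function() {
  shape <- c(24L, 24L, 24L)
  gm <- generate_mask(shape, c(0, 0, 0), 16)
  roi <- generate_mask(shape, c(9, 9, 9), 3)

  surnames <- paste0(SURNAME_POOL[1:30], "T")
  group_sizes <- c(3L, 2L, 2L, rep(1L, 27L))
  years <- c(2007L, 2007L, 2007L, 2007L, 1995:2006, 1999L, 2008:2020)
  subjects <- c(5:36, 34L, 160L)

  gm_coord <- function(i, j) {
    # odd mm in [-7, 7]: well inside the radius-16 gray-matter sphere
    v <- c(-7, -5, -3, -1, 1, 3, 5, 7)
    c(v[(i * 3 + j) %% 8 + 1], v[(i * 5 + 2 * j) %% 8 + 1],
      v[(i + 7 * j) %% 8 + 1])
  }
  wm_coord <- function(i, j) {
    # odd mm in [17, 23]: inside the grid, outside the gray-matter sphere
    v <- c(17, 19, 21, 23)
    c(v[(i + j) %% 4 + 1], v[(i * 3 + j) %% 4 + 1], v[(i + 2 * j) %% 4 + 1])
  }

  experiments <- list()
  e_idx <- 0L
  for (p in seq_len(30L)) {
    for (memb in seq_len(group_sizes[p])) {
      e_idx <- e_idx + 1L
      key <- paste0(surnames[p], ",", years[p])
      nf <- 3L + (e_idx %% 4L)
      wm_only <- p >= 24L  # seven papers without gray-matter foci
      foci <- t(vapply(seq_len(nf), function(j) {
        if (wm_only) wm_coord(e_idx, j) else gm_coord(e_idx, j)
      }, numeric(3)))
      if (!wm_only) {
        # one out-of-tissue focus per experiment exercises the focus-level
        # filter without changing the experiment-level count
        foci <- rbind(foci, wm_coord(e_idx + 11L, 2L))
      }
      if (p %in% 4:8 && memb == 1L) {
        foci <- rbind(foci, c(9, 9, 9))  # region-of-interest hit
      }
      detail <- if (group_sizes[p] > 1L) sprintf(" contrast %d", memb) else ""
      experiments <- c(experiments, list(experiment(
        key, subjects[e_idx], foci,
        metadata_lines = c(paste0(key, ":", detail),
                           paste0("Subjects=", subjects[e_idx])))))
    }
  }
  list(dataset = foci_dataset(experiments, space = "Talairach",
                              source_name = "synthetic_example"),
       gm_mask = gm, roi = roi)
}
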