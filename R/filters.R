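# Dataset-preparation filters. Each returns the filtered dataset together
# with p, the number of experiments remaining, mirroring the return variable
# conventions familiar to users of CBMA preparation tools.

#' Enforce within-paper sample independence
#'
#' Coordinate-based meta-analysis assumes the included experiments draw on
#' independent samples. Experiments are grouped by paper of origin, i.e. by
#' the first-author-and-year key (case-insensitively, whitespace-trimmed;
#' text after the colon is ignored). One experiment per group is retained:
#' with `mode = 1` the one with the largest sample size (ties broken at
#' random), with `mode = 2` a uniformly random group member. Keys that
#' differ by a trailing letter after the year (e.g. `AndersonT,2023a` vs
#' `AndersonT,2023b`) are distinct groups — the documented escape hatch for
#' within-paper experiments known to use independent samples.
#'
#' @param foci A [foci_dataset()] or path to a foci file.
#' @param mode 1 (largest sample size) or 2 (random member).
#' @param seed Optional integer controlling the random selection. When
#'   omitted, a fresh seed is drawn and reported via a message so the run
#'   can be replayed.
#' @return A list with elements `dataset`, `p` (number of retained
#'   experiments), `retained` (indices into the input), and `seed`.
#' @export
remove_multiple <- function(foci, mode, seed = NULL) {
  d <- as_foci_dataset(foci)
  if (n_experiments(d) == 0L) {
    cbma_abort("dataset contains no experiments", "cbma_empty_dataset")
  }
  if (!is.numeric(mode) || length(mode) != 1L || !(mode %in% c(1, 2))) {
    cbma_abort("mode must be 1 (largest sample) or 2 (random)",
               "cbma_bad_mode")
  }
  announced <- !is.null(seed)
  seed <- resolve_seed(seed)
  if (!announced) message(sprintf("remove_multiple: using seed %d", seed))

  keys <- tolower(trimws(experiment_keys(d)))
  subj <- experiment_subjects(d)
  groups <- split(seq_along(keys), factor(keys, levels = unique(keys)))

  retained <- with_seed(seed, {
    vapply(groups, function(idx) {
      if (length(idx) == 1L) return(idx)
      if (mode == 1) {
        best <- idx[subj[idx] == max(subj[idx])]
        sample_one(best)
      } else {
        sample_one(idx)
      }
    }, integer(1))
  })
  retained <- sort(unname(retained))
  list(dataset = dataset_subset(d, retained), p = length(retained),
       retained = retained, seed = seed)
}

#' Retain only foci inside a tissue mask
#'
#' Each experiment's focus list is reduced to the foci located inside the
#' mask (typically a gray- or white-matter template on the Talairach 2 mm
#' grid). Experiments left without any in-mask focus are dropped from the
#' output; all metadata, including subject counts, are unchanged.
#'
#' @param foci A [foci_dataset()] or path to a foci file.
#' @param tissue A [volume_mask()] or path to a NIfTI mask.
#' @return A list with elements `dataset`, `p` (number of retained
#'   experiments) and `retained` (indices into the input).
#' @export
filter_by_tissue <- function(foci, tissue) {
  d <- as_foci_dataset(foci)
  m <- if (inherits(tissue, "cbma_volume_mask")) tissue else read_mask(tissue)
  if (n_experiments(d) == 0L) {
    cbma_abort("dataset contains no experiments", "cbma_empty_dataset")
  }
  exps <- lapply(d$experiments, function(e) {
    keep <- foci_in_mask(m, e$foci)
    e$foci <- e$foci[keep, , drop = FALSE]
    e
  })
  retained <- which(vapply(exps, function(e) nrow(e$foci) > 0L, logical(1)))
  out <- foci_dataset(exps[retained], space = d$space,
                      source_name = d$source_name)
  list(dataset = out, p = length(retained), retained = retained)
}

#' Select experiments for meta-analytic connectivity modeling
#'
#' An experiment is retained, with its complete focus list, iff at least one
#' of its foci falls inside the region of interest. This differs from
#' [filter_by_tissue()]: foci outside the ROI are kept as long as the
#' experiment has one hit, because MACM interprets all peaks co-reported
#' with an ROI hit as coactivation with that region.
#'
#' @param foci A [foci_dataset()] or path to a foci file.
#' @param roi A [volume_mask()] or path to a NIfTI region of interest
#'   (non-binary volumes are binarized at 0).
#' @return A list with elements `dataset`, `p` and `retained`, as in
#'   [filter_by_tissue()].
#' @export
prepare_macm <- function(foci, roi) {
  d <- as_foci_dataset(foci)
  m <- if (inherits(roi, "cbma_volume_mask")) roi else read_mask(roi)
  if (n_experiments(d) == 0L) {
    cbma_abort("dataset contains no experiments", "cbma_empty_dataset")
  }
  hit <- vapply(d$experiments, function(e) {
    nrow(e$foci) > 0L && any(foci_in_mask(m, e$foci))
  }, logical(1))
  retained <- which(hit)
  list(dataset = dataset_subset(d, retained), p = length(retained),
       retained = retained)
}
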