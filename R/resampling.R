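# Resampling schemes for post hoc validation: leave-one-experiment-out
# (standard and incremental) and random subset/split-half generation.

new_subsample_set <- function(subsamples, scheme, provenance, excluded,
                              seed = NULL) {
  structure(
    list(subsamples = subsamples,
         scheme = scheme,
         seed = seed,
         provenance = provenance,
         excluded = excluded,
         p = length(subsamples)),
    class = "cbma_subsample_set")
}

#' @export
print.cbma_subsample_set <- function(x, ...) {
  sizes <- vapply(x$subsamples, n_experiments, integer(1))
  cat(sprintf("<subsample set> scheme=%s, p=%d, sizes=[%s]%s\n",
              x$scheme, x$p, paste(sizes, collapse = ","),
              if (is.null(x$seed)) "" else sprintf(", seed=%d", x$seed)))
  invisible(x)
}

#' Leave-one-experiment-out partitions
#'
#' With `add = FALSE` (standard jackknife), a dataset of n experiments
#' yields n subsamples of n - 1 experiments each; subsample k omits exactly
#' experiment k, so each experiment is excluded once. With `add = TRUE`
#' (incremental), iteration k omits experiments 1..k in file order, yielding
#' n - 1 subsamples whose sizes decrease from n - 1 down to 1; the empty
#' n-th iteration is suppressed.
#'
#' @param foci A [foci_dataset()] or path to a foci file with at least two
#'   experiments.
#' @param add If `TRUE`, use the incremental scheme.
#' @return A `cbma_subsample_set` with fields `subsamples`, `provenance`
#'   (retained source indices per subsample), `excluded` and `p`.
#' @export
create_loeo <- function(foci, add = FALSE) {
  d <- as_foci_dataset(foci)
  add <- as.logical(add)
  stopifnot(is_flag(add))
  n <- n_experiments(d)
  if (n < 2L) {
    cbma_abort("leave-one-experiment-out requires at least 2 experiments",
               "cbma_too_few_experiments")
  }
  if (!add) {
    excluded <- lapply(seq_len(n), identity)
  } else {
    excluded <- lapply(seq_len(n - 1L), seq_len)
  }
  provenance <- lapply(excluded, function(ex) setdiff(seq_len(n), ex))
  subs <- lapply(provenance, function(idx) dataset_subset(d, idx))
  new_subsample_set(subs, if (add) "loeo_incremental" else "loeo",
                    provenance, excluded)
}

#' Random subsets for split-half and bootstrap-style validation
#'
#' With `rep = TRUE`, `ns` subsamples are drawn, each containing `nexp`
#' distinct experiments sampled uniformly; an experiment may appear in more
#' than one subsample. With `rep = FALSE`, the experiments are partitioned
#' at random into `ns` disjoint subsamples of equal size; `nexp` is
#' automatically adjusted to `floor(n / ns)` when `ns * nexp != n`, and if
#' the adjusted size does not divide n an extra subsample holds the
#' remaining experiments (so `p` is `ns` or `ns + 1`). Within each
#' subsample, experiments keep their original file order.
#'
#' @param foci A [foci_dataset()] or path to a foci file.
#' @param ns Number of subsamples to create.
#' @param nexp Size of each subsample.
#' @param rep If `TRUE`, experiments may be reused across subsamples.
#' @param seed Optional integer for reproducible selection; when omitted a
#'   fresh seed is drawn and reported.
#' @return A `cbma_subsample_set`; its `p` field gives the number of
#'   subsamples generated.
#' @export
create_subsets <- function(foci, ns, nexp, rep = FALSE, seed = NULL) {
  d <- as_foci_dataset(foci)
  rep <- as.logical(rep)
  stopifnot(is_flag(rep))
  n <- n_experiments(d)
  ns <- as.integer(ns); nexp <- as.integer(nexp)
  if (is.na(ns) || ns < 1L || is.na(nexp) || nexp < 1L) {
    cbma_abort("ns and nexp must be positive integers", "cbma_bad_arguments")
  }
  announced <- !is.null(seed)
  seed <- resolve_seed(seed)
  if (!announced) message(sprintf("create_subsets: using seed %d", seed))

  if (rep) {
    if (nexp > n) {
      cbma_abort(sprintf("nexp (%d) cannot exceed n (%d) when sampling %s",
                         nexp, n, "distinct experiments per subsample"),
                 "cbma_bad_arguments")
    }
    provenance <- with_seed(seed, {
      lapply(seq_len(ns), function(k) sort(sample.int(n, nexp)))
    })
  } else {
    size <- nexp
    if (ns * size != n) size <- as.integer(floor(n / ns))
    if (size < 1L) {
      cbma_abort(sprintf(
        "cannot create %d non-overlapping subsamples from %d experiments",
        ns, n), "cbma_bad_arguments")
    }
    perm <- with_seed(seed, sample.int(n))
    provenance <- lapply(seq_len(ns), function(k) {
      sort(perm[((k - 1L) * size + 1L):(k * size)])
    })
    if (ns * size < n) {
      provenance <- c(provenance, list(sort(perm[(ns * size + 1L):n])))
    }
  }
  subs <- lapply(provenance, function(idx) dataset_subset(d, idx))
  new_subsample_set(subs, if (rep) "subsets_rep" else "subsets",
                    provenance,
                    excluded = lapply(provenance, function(idx)
                      setdiff(seq_len(n), idx)),
                    seed = seed)
}

#' Write a subsample set to disk
#'
#' Emits one Sleuth-compatible foci file per subsample
#' (`LOEO_<k>.txt` for the leave-one-out schemes, `sub_sample_<k>.txt` for
#' subsets) plus a plain-text manifest recording the scheme, the seed and
#' the source experiments of every file.
#'
#' @param ss A `cbma_subsample_set`.
#' @param outdir Output directory (created if missing).
#' @param prefix Optional file-name prefix overriding the scheme default.
#' @return Character vector of the foci file paths, invisibly.
#' @export
write_subsamples <- function(ss, outdir = ".", prefix = NULL) {
  stopifnot(inherits(ss, "cbma_subsample_set"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(prefix)) {
    prefix <- if (ss$scheme %in% c("loeo", "loeo_incremental")) "LOEO_"
              else "sub_sample_"
  }
  paths <- character(ss$p)
  for (k in seq_len(ss$p)) {
    paths[k] <- file.path(outdir, paste0(prefix, k, ".txt"))
    write_foci_file(ss$subsamples[[k]], paths[k])
  }
  manifest <- file.path(outdir, paste0(prefix, "manifest.txt"))
  lines <- c(
    sprintf("scheme: %s", ss$scheme),
    sprintf("seed: %s", if (is.null(ss$seed)) "none" else ss$seed),
    sprintf("subsamples: %d", ss$p),
    unlist(lapply(seq_len(ss$p), function(k) {
      keys <- experiment_keys(ss$subsamples[[k]])
      sprintf("%s%d.txt: %s", prefix, k, paste(keys, collapse = "; "))
    })))
  writeLines(lines, manifest)
  invisible(paths)
}
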