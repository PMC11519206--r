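#' Construct a single experiment
#'
#' An experiment is one contrast/analysis contributing a set of peak
#' coordinates (foci) and a sample size to a coordinate-based meta-analysis.
#' Several experiments may come from one paper; the author-year key encodes
#' the paper of origin (an optional trailing letter after the year marks
#' within-paper experiments known to use independent samples).
#'
#' @param author_year_key String of the form `"Author,yyyy"` with an optional
#'   single trailing letter, e.g. `"AndersonT,2023a"`.
#' @param n_subjects Positive integer sample size.
#' @param foci Numeric matrix with three columns (x, y, z in mm), one row per
#'   focus. May have zero rows only transiently (a written dataset never
#'   contains an experiment without foci).
#' @param metadata_lines Character vector of raw metadata lines (without the
#'   leading `//`). If `NULL`, a minimal two-line block (author-year line and
#'   `Subjects=` line) is built.
#' @return An object of class `cbma_experiment`.
#' @export
experiment <- function(author_year_key, n_subjects, foci,
                       metadata_lines = NULL) {
  if (!grepl(KEY_REGEX, author_year_key)) {
    cbma_abort(
      sprintf("author-year key '%s' does not match 'Author,yyyy[letter]'",
              author_year_key),
      "cbma_malformed_metadata")
  }
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) {
    cbma_abort("n_subjects must be a positive integer",
               "cbma_malformed_metadata")
  }
  foci <- as_foci_matrix(foci)
  if (is.null(metadata_lines)) {
    metadata_lines <- c(paste0(author_year_key, ":"),
                        paste0("Subjects=", n_subjects))
  }
  structure(
    list(author_year_key = author_year_key,
         metadata_lines = as.character(metadata_lines),
         n_subjects = n_subjects,
         foci = foci),
    class = "cbma_experiment")
}

KEY_REGEX <- "^\\s*(\\S[^,]*?)\\s*,\\s*([0-9]{4})([A-Za-z]?)\\s*$"

as_foci_matrix <- function(foci) {
  if (is.null(foci)) foci <- matrix(numeric(0), ncol = 3L)
  if (is.vector(foci) && is.numeric(foci) && length(foci) == 3L) {
    foci <- matrix(foci, ncol = 3L)
  }
  foci <- as.matrix(foci)
  if (ncol(foci) != 3L) {
    cbma_abort("foci must have three columns (x, y, z)",
               "cbma_bad_coordinate")
  }
  storage.mode(foci) <- "double"
  if (nrow(foci) > 0L && any(!is.finite(foci))) {
    cbma_abort("all coordinates must be finite reals", "cbma_bad_coordinate")
  }
  dimnames(foci) <- list(NULL, c("x", "y", "z"))
  foci
}

#' Construct a foci dataset
#'
#' An ordered collection of experiments together with a declared stereotactic
#' reference space. Experiment order is preserved from the source file by
#' every operation in the package.
#'
#' @param experiments List of [experiment()] objects.
#' @param space Reference space label: `"Talairach"`, `"MNI"` or
#'   `"unspecified"`.
#' @param source_name Provenance string used when naming output files.
#' @return An object of class `cbma_foci_dataset`.
#' @export
foci_dataset <- function(experiments, space = "unspecified",
                         source_name = "dataset") {
  if (!is.list(experiments) ||
      !all(vapply(experiments, inherits, logical(1), "cbma_experiment"))) {
    cbma_abort("experiments must be a list of cbma_experiment objects",
               "cbma_bad_arguments")
  }
  space <- match.arg(space, c("Talairach", "MNI", "unspecified"))
  structure(
    list(experiments = experiments, space = space,
         source_name = as.character(source_name)),
    class = "cbma_foci_dataset")
}

#' Number of experiments in a dataset
#' @param d A [foci_dataset()].
#' @return Integer count.
#' @export
n_experiments <- function(d) {
  stopifnot(inherits(d, "cbma_foci_dataset"))
  length(d$experiments)
}

# Subset a dataset by experiment index, preserving order of `idx`.
dataset_subset <- function(d, idx) {
  foci_dataset(d$experiments[idx], space = d$space,
               source_name = d$source_name)
}

experiment_keys <- function(d) {
  vapply(d$experiments, function(e) e$author_year_key, character(1))
}

experiment_subjects <- function(d) {
  vapply(d$experiments, function(e) e$n_subjects, integer(1))
}

#' Publication years of a dataset's experiments
#'
#' Extracts the four-digit year token from each author-year key (any trailing
#' independence letter is ignored).
#'
#' @param d A [foci_dataset()].
#' @return Integer vector of years, one per experiment.
#' @export
experiment_years <- function(d) {
  keys <- experiment_keys(d)
  m <- regmatches(keys, regexpr(",\\s*[0-9]{4}", keys))
  if (length(m) != length(keys)) {
    cbma_abort("could not parse a publication year from every key",
               "cbma_unparseable_year")
  }
  as.integer(sub(",\\s*", "", m))
}

#' @export
print.cbma_experiment <- function(x, ...) {
  cat(sprintf("<experiment> %s  Subjects=%d  foci=%d\n",
              x$author_year_key, x$n_subjects, nrow(x$foci)))
  invisible(x)
}

#' @export
print.cbma_foci_dataset <- function(x, ...) {
  cat(sprintf("<foci dataset> '%s': %d experiment(s), space=%s, %d foci\n",
              x$source_name, length(x$experiments), x$space,
              sum(vapply(x$experiments, function(e) nrow(e$foci),
                         integer(1)))))
  invisible(x)
}

# Order-insensitive equality of the foci rows (multiset comparison).
foci_signature <- function(foci) {
  if (nrow(foci) == 0L) return("")
  rows <- apply(foci, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = " "))
  paste(sort(rows), collapse = "\n")
}

# Full normalized signature used by duplicate detection: whole metadata block
# (whitespace-trimmed) plus the focus multiset.
experiment_signature <- function(e) {
  paste(paste(trimws(e$metadata_lines), collapse = "\n"),
        foci_signature(e$foci), sep = "\n--\n")
}

#' Test two datasets for equality
#'
#' Structural equality: same number of experiments in the same order, each
#' with identical metadata (after whitespace trimming), the same sample size
#' and bitwise-identical foci in the same order.
#'
#' @param a,b Datasets to compare.
#' @return Logical scalar.
#' @export
foci_datasets_equal <- function(a, b) {
  if (n_experiments(a) != n_experiments(b)) return(FALSE)
  for (i in seq_along(a$experiments)) {
    ea <- a$experiments[[i]]; eb <- b$experiments[[i]]
    if (ea$author_year_key != eb$author_year_key) return(FALSE)
    if (ea$n_subjects != eb$n_subjects) return(FALSE)
    if (!identical(trimws(ea$metadata_lines), trimws(eb$metadata_lines)))
      return(FALSE)
    if (!identical(dim(ea$foci), dim(eb$foci))) return(FALSE)
    if (nrow(ea$foci) > 0L && !all(ea$foci == eb$foci)) return(FALSE)
  }
  TRUE
}
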