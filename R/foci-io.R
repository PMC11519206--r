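# Sleuth-compatible foci text layout:
#   - metadata lines begin with //
#   - first metadata line of each block: author,yyyy:  (optional letter after
#     the year; free text after the colon is ignored)
#   - last metadata line of each block: Subjects=<integer>
#   - one focus per line: three space-separated numbers, '.' decimal separator
#   - >=1 blank line between experiments; no file header in the strict
#     dialect, an optional leading "// Reference=<space>" line in the lenient
#     (Sleuth) dialect.

FIRST_META_REGEX <- "^\\s*(\\S[^,]*?)\\s*,\\s*([0-9]{4})([A-Za-z]?)\\s*:"
NUM_TOKEN_REGEX <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$"

#' Parse foci text in the Sleuth-compatible layout
#'
#' @param text A single string (or character vector of lines) holding the
#'   file content. Both `\n` and `\r\n` line endings are accepted.
#' @param strict If `TRUE`, the file must follow the layout exactly: no
#'   header of any kind and `Subjects=<integer>` spelled exactly. If `FALSE`
#'   (lenient, the default), a single leading `// Reference=<space>` line is
#'   accepted and recorded as the dataset's reference space, and the
#'   `Subjects=` line tolerates case differences and spaces around `=`.
#' @param source_name Provenance string stored on the returned dataset.
#' @return A [foci_dataset()], one experiment per metadata+foci block, in
#'   file order.
#' @export
parse_foci_text <- function(text, strict = FALSE, source_name = "text") {
  stopifnot(is_flag(strict))
  if (length(text) == 0L || all(!nzchar(trimws(text)))) {
    cbma_abort("input text is empty", "cbma_empty_input")
  }
  lines <- if (length(text) == 1L) strsplit(text, "\r\n|\n")[[1]] else
    as.character(text)
  blank <- grepl("^\\s*$", lines)

  space <- "unspecified"
  first_content <- which(!blank)[1]
  if (is.na(first_content)) cbma_abort("input text is empty",
                                       "cbma_empty_input")
  ref_rx <- "^//\\s*Reference\\s*=\\s*(\\S.*?)\\s*$"
  if (grepl(ref_rx, lines[first_content], ignore.case = TRUE)) {
    if (strict) {
      cbma_abort("no header line is allowed in strict mode",
                 "cbma_malformed_metadata")
    }
    raw_space <- sub(ref_rx, "\\1", lines[first_content], ignore.case = TRUE)
    space <- if (grepl("tal", raw_space, ignore.case = TRUE)) "Talairach"
             else if (grepl("mni", raw_space, ignore.case = TRUE)) "MNI"
             else "unspecified"
    lines <- lines[-first_content]
    blank <- blank[-first_content]
  }

  # Group contiguous non-blank runs into experiment blocks.
  run_id <- cumsum(blank)
  keep <- !blank
  block_ids <- unique(run_id[keep])
  experiments <- vector("list", length(block_ids))
  for (b in seq_along(block_ids)) {
    experiments[[b]] <- parse_block(lines[keep & run_id == block_ids[b]],
                                    strict = strict)
  }
  if (length(experiments) == 0L) {
    cbma_abort("input text contains no experiment blocks", "cbma_empty_input")
  }
  foci_dataset(experiments, space = space, source_name = source_name)
}

parse_block <- function(block_lines, strict) {
  is_meta <- startsWith(trimws(block_lines), "//")
  if (!is_meta[1]) {
    cbma_abort(
      sprintf("block must start with a '//' metadata line, got: '%s'",
              block_lines[1]),
      "cbma_malformed_metadata")
  }
  n_meta <- match(FALSE, is_meta, nomatch = length(block_lines) + 1L) - 1L
  if (any(is_meta[-seq_len(n_meta)])) {
    cbma_abort("metadata lines must precede all focus lines within a block",
               "cbma_malformed_metadata")
  }
  meta_raw <- trimws(block_lines[seq_len(n_meta)])
  meta <- trimws(sub("^//", "", meta_raw))

  m <- regexec(FIRST_META_REGEX, meta[1])[[1]]
  if (m[1] == -1L) {
    cbma_abort(
      sprintf("first metadata line '%s' does not match 'author,yyyy:'",
              meta[1]),
      "cbma_malformed_metadata")
  }
  parts <- regmatches(meta[1], regexec(FIRST_META_REGEX, meta[1]))[[1]]
  key <- paste0(parts[2], ",", parts[3], parts[4])

  subj_rx <- if (strict) "^Subjects=([0-9]+)$" else
    "^[Ss][Uu][Bb][Jj][Ee][Cc][Tt][Ss]\\s*=\\s*([0-9]+)\\s*$"
  last <- meta[n_meta]
  if (!grepl(subj_rx, last)) {
    cbma_abort(
      sprintf("last metadata line '%s' is not 'Subjects=<integer>'", last),
      "cbma_missing_subjects")
  }
  n_subjects <- as.integer(sub(subj_rx, "\\1", last))
  if (is.na(n_subjects) || n_subjects < 1L) {
    cbma_abort(sprintf("invalid subject count in '%s'", last),
               "cbma_missing_subjects")
  }

  focus_lines <- trimws(block_lines[-seq_len(n_meta)])
  foci <- parse_focus_lines(focus_lines)
  experiment(key, n_subjects, foci, metadata_lines = meta)
}

parse_focus_lines <- function(focus_lines) {
  if (length(focus_lines) == 0L) return(as_foci_matrix(NULL))
  rows <- lapply(focus_lines, function(ln) {
    tokens <- strsplit(ln, "[ \t]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) != 3L || !all(grepl(NUM_TOKEN_REGEX, tokens))) {
      cbma_abort(
        sprintf(paste0("focus line '%s' is not three space-separated ",
                       "numbers with '.' decimal separator"), ln),
        "cbma_bad_coordinate")
    }
    as.numeric(tokens)
  })
  as_foci_matrix(do.call(rbind, rows))
}

#' Remove duplicate experiments
#'
#' Two experiments are duplicates only when their full metadata blocks are
#' identical (after whitespace trimming, including the subject count) and
#' they report the same foci irrespective of listing order. Among duplicates
#' only the first occurrence is retained; relative order is preserved.
#'
#' @param d A [foci_dataset()].
#' @return A list with elements `dataset` (the deduplicated dataset) and
#'   `removed` (integer indices of the dropped experiments in `d`).
#' @export
deduplicate <- function(d) {
  stopifnot(inherits(d, "cbma_foci_dataset"))
  sigs <- vapply(d$experiments, experiment_signature, character(1))
  dup <- duplicated(sigs)
  list(dataset = dataset_subset(d, which(!dup)),
       removed = which(dup))
}

#' Load a foci file
#'
#' Reads a Sleuth-compatible foci text file, parses it and removes duplicate
#' experiments. Called internally by every other dataset-consuming operation,
#' all of which also accept an already-loaded dataset.
#'
#' @param path Path to the `.txt` foci file.
#' @inheritParams parse_foci_text
#' @param quiet If `TRUE`, suppress the duplicate-removal message.
#' @return A [foci_dataset()].
#' @export
load_foci <- function(path, strict = FALSE, quiet = FALSE) {
  if (!file.exists(path)) {
    cbma_abort(sprintf("file not found: '%s'", path), "cbma_file_not_found")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  src <- sub("\\.[^.]*$", "", basename(path))
  d <- parse_foci_text(lines, strict = strict, source_name = src)
  dd <- deduplicate(d)
  if (!quiet && length(dd$removed) > 0L) {
    message(sprintf("Removed %d duplicate experiment(s)", length(dd$removed)))
  }
  dd$dataset
}

# Accept either a path or a loaded dataset; paths go through load_foci so
# duplicates are always excluded first.
as_foci_dataset <- function(foci, strict = FALSE) {
  if (inherits(foci, "cbma_foci_dataset")) return(foci)
  if (is.character(foci) && length(foci) == 1L) {
    return(load_foci(foci, strict = strict, quiet = TRUE))
  }
  cbma_abort("expected a foci_dataset or a file path", "cbma_bad_arguments")
}

#' Serialize a dataset to the Sleuth-compatible layout
#'
#' @param d A [foci_dataset()]; every experiment must have at least one
#'   focus.
#' @param include_reference_header If `TRUE`, emit a leading
#'   `// Reference=<space>` line (Sleuth dialect). Requires the dataset's
#'   space to be declared.
#' @return A single string; lines separated by `\n`, one blank line between
#'   experiments.
#' @export
format_foci_text <- function(d, include_reference_header = FALSE) {
  stopifnot(inherits(d, "cbma_foci_dataset"), is_flag(include_reference_header))
  if (n_experiments(d) == 0L) {
    cbma_abort("dataset contains no experiments", "cbma_empty_dataset")
  }
  empty <- vapply(d$experiments, function(e) nrow(e$foci) == 0L, logical(1))
  if (any(empty)) {
    cbma_abort(
      sprintf("experiment(s) without foci cannot be written: %s",
              paste(experiment_keys(d)[empty], collapse = ", ")),
      "cbma_experiment_without_foci")
  }
  blocks <- vapply(d$experiments, function(e) {
    meta <- paste0("// ", trimws(e$metadata_lines))
    coords <- apply(e$foci, 1L, function(r) paste(format_coord(r),
                                                  collapse = " "))
    paste(c(meta, coords), collapse = "\n")
  }, character(1))
  header <- if (include_reference_header) {
    if (d$space == "unspecified") {
      cbma_abort("cannot write a Reference header for an unspecified space",
                 "cbma_bad_arguments")
    }
    paste0("// Reference=", d$space, "\n")
  } else ""
  paste0(header, paste(blocks, collapse = "\n\n"), "\n")
}

#' Write a dataset to a foci file
#'
#' The emitted text re-parses to an equal dataset (lossless round trip).
#'
#' @inheritParams format_foci_text
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_foci_file <- function(d, path, include_reference_header = FALSE) {
  txt <- format_foci_text(d, include_reference_header)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(txt)), con)
  invisible(path)
}
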