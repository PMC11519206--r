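test_that("a minimal well-formed block parses into one experiment", {
  d <- parse_foci_text("// SmithJ,2001: task\n// Subjects=12\n10 20 30\n")
  expect_equal(n_experiments(d), 1L)
  e <- d$experiments[[1]]
  expect_equal(e$author_year_key, "SmithJ,2001")
  expect_equal(e$n_subjects, 12L)
  expect_equal(unname(e$foci[1, ]), c(10, 20, 30))
})

test_that("blocks separated by blank lines parse in file order", {
  txt <- paste0("// A,2001:\n// Subjects=5\n1 2 3\n\n",
                "// B,2002:\n// Subjects=6\n4 5 6\n7 8 9\n")
  d <- parse_foci_text(txt)
  expect_equal(n_experiments(d), 2L)
  expect_equal(experiment_keys(d), c("A,2001", "B,2002"))
  expect_equal(nrow(d$experiments[[2]]$foci), 2L)
  # multiple blank lines (and \r\n endings) behave the same
  d2 <- parse_foci_text(gsub("\n\n", "\r\n\r\n\r\n", txt))
  expect_true(foci_datasets_equal(d, d2))
})

test_that("a trailing letter after the year marks a distinct key", {
  txt <- paste0("// AndersonT,2023a: task one\n// Subjects=10\n1 2 3\n\n",
                "// AndersonT,2023b: task two\n// Subjects=10\n1 2 3\n")
  d <- parse_foci_text(txt)
  expect_equal(experiment_keys(d), c("AndersonT,2023a", "AndersonT,2023b"))
})

test_that("grammar violations raise classed errors", {
  expect_error(parse_foci_text("// Subjects=10\n1 2 3\n"),
               class = "cbma_malformed_metadata")
  expect_error(parse_foci_text("// A,2001:\n1 2 3\n"),
               class = "cbma_missing_subjects")
  expect_error(parse_foci_text("// A,2001:\n// Subjects=3\n1 2\n"),
               class = "cbma_bad_coordinate")
  expect_error(parse_foci_text("// A,2001:\n// Subjects=3\n1 2,5 3\n"),
               class = "cbma_bad_coordinate")
  expect_error(parse_foci_text("  \n \n"), class = "cbma_empty_input")
  # metadata resuming after foci within one block is malformed
  expect_error(
    parse_foci_text("// A,2001:\n// Subjects=3\n1 2 3\n// stray\n4 5 6\n"),
    class = "cbma_malformed_metadata")
})

test_that("strict mode rejects headers that lenient mode records", {
  txt <- "// Reference=Talairach\n// A,2001:\n// Subjects=3\n1 2 3\n"
  d <- parse_foci_text(txt, strict = FALSE)
  expect_equal(d$space, "Talairach")
  expect_equal(n_experiments(d), 1L)
  expect_error(parse_foci_text(txt, strict = TRUE),
               class = "cbma_malformed_metadata")
  # lenient Subjects dialect vs strict
  loose <- "// A,2001:\n// subjects = 3\n1 2 3\n"
  expect_equal(parse_foci_text(loose)$experiments[[1]]$n_subjects, 3L)
  expect_error(parse_foci_text(loose, strict = TRUE),
               class = "cbma_missing_subjects")
})

test_that("duplicates require identical metadata and an identical focus set", {
  block <- function(n, foci_lines) {
    paste0("// X,2010: task\n// Subjects=", n, "\n",
           paste(foci_lines, collapse = "\n"), "\n")
  }
  # byte-identical blocks collapse to one
  d <- parse_foci_text(paste0(block(12, "1 2 3"), "\n", block(12, "1 2 3")))
  dd <- deduplicate(d)
  expect_equal(n_experiments(dd$dataset), 1L)
  expect_equal(dd$removed, 2L)
  # differing subject counts are not duplicates
  d2 <- parse_foci_text(paste0(block(12, "1 2 3"), "\n", block(14, "1 2 3")))
  expect_equal(n_experiments(deduplicate(d2)$dataset), 2L)
  # same foci in reversed order are duplicates (order-insensitive)
  d3 <- parse_foci_text(paste0(block(12, c("1 2 3", "4 5 6")), "\n",
                               block(12, c("4 5 6", "1 2 3"))))
  expect_equal(n_experiments(deduplicate(d3)$dataset), 1L)
})

test_that("deduplication is idempotent, order-preserving and never grows", {
  set.seed(42)
  for (i in 1:20) {
    spec <- fixture_spec(n_experiments = 10L, n_duplicate_pairs = 2L,
                         same_paper_groups = c(2L), seed = i)
    d <- generate_dataset(spec)
    dd <- deduplicate(d)
    expect_equal(n_experiments(dd$dataset), 8L)
    expect_lte(n_experiments(dd$dataset), n_experiments(d))
    expect_true(foci_datasets_equal(deduplicate(dd$dataset)$dataset,
                                    dd$dataset))
    kept <- setdiff(seq_len(10L), dd$removed)
    expect_equal(experiment_keys(dd$dataset), experiment_keys(d)[kept])
  }
})

test_that("load_foci excludes duplicates and is the parse identity otherwise", {
  f <- withr::local_tempfile(fileext = ".txt")
  d <- simple_dataset(3)
  d$experiments <- c(d$experiments, d$experiments[2])  # exact duplicate
  writeLines(format_foci_text(foci_dataset(d$experiments)), f)
  expect_message(got <- load_foci(f), "duplicate")
  expect_equal(n_experiments(got), 3L)
  # no duplicates: identity with respect to parsing
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_foci_file(simple_dataset(4), f2)
  expect_true(foci_datasets_equal(load_foci(f2), simple_dataset(4)))
  expect_error(load_foci(file.path(tempdir(), "absent.txt")),
               class = "cbma_file_not_found")
})

test_that("write -> parse round trip is lossless, including random reals", {
  set.seed(7)
  for (i in 1:25) {
    exps <- lapply(seq_len(sample(1:5, 1)), function(j) {
      nf <- sample(1:6, 1)
      make_exp(sprintf("Rt%d,%d", j, 1990 + j), sample(5:160, 1),
               matrix(runif(3 * nf, -80, 80), ncol = 3))
    })
    d <- foci_dataset(exps, space = "Talairach")
    d2 <- parse_foci_text(format_foci_text(d))
    expect_true(foci_datasets_equal(d, d2))
    # with the Sleuth-style reference header the space survives too
    d3 <- parse_foci_text(format_foci_text(d, include_reference_header = TRUE))
    expect_equal(d3$space, "Talairach")
    expect_true(foci_datasets_equal(d, d3))
  }
})

test_that("writing enforces dataset invariants", {
  expect_error(format_foci_text(foci_dataset(list())),
               class = "cbma_empty_dataset")
  d <- foci_dataset(list(make_exp(foci = NULL)))
  expect_error(format_foci_text(d), class = "cbma_experiment_without_foci")
  expect_error(
    format_foci_text(simple_dataset(2), include_reference_header = TRUE),
    class = "cbma_bad_arguments")  # space unspecified
})
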