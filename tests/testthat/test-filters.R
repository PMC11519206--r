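test_that("mode 1 keeps the largest sample per paper", {
  d <- foci_dataset(list(
    make_exp("A,2020", 12L, c(1, 2, 3), detail = "task a"),
    make_exp("A,2020", 20L, c(4, 5, 6), detail = "task b"),
    make_exp("B,2019", 15L, c(7, 8, 9))))
  res <- remove_multiple(d, mode = 1, seed = 1)
  expect_equal(res$p, 2L)
  expect_equal(experiment_keys(res$dataset), c("A,2020", "B,2019"))
  expect_equal(experiment_subjects(res$dataset), c(20L, 15L))
})

test_that("suffix letters protect within-paper independent samples", {
  d <- foci_dataset(list(
    make_exp("AndersonT,2023a", 10L, c(1, 2, 3)),
    make_exp("AndersonT,2023b", 11L, c(4, 5, 6))))
  for (mode in 1:2) {
    res <- remove_multiple(d, mode = mode, seed = 5)
    expect_equal(res$p, 2L)
  }
})

test_that("grouping is case-insensitive and ignores text after the colon", {
  d <- foci_dataset(list(
    make_exp("smithj,2001", 8L, c(1, 2, 3), detail = "first run"),
    make_exp("SmithJ,2001", 9L, c(4, 5, 6), detail = "second run")))
  res <- remove_multiple(d, mode = 1, seed = 1)
  expect_equal(res$p, 1L)
  expect_equal(experiment_subjects(res$dataset), 9L)
})

test_that("a fixed seed reproduces the random selection exactly", {
  set.seed(99)
  spec <- fixture_spec(n_experiments = 20L,
                       same_paper_groups = c(3L, 2L, 4L), seed = 4L)
  d <- generate_dataset(spec)
  for (mode in 1:2) {
    a <- remove_multiple(d, mode = mode, seed = 10)
    b <- remove_multiple(d, mode = mode, seed = 10)
    expect_identical(a$retained, b$retained)
    expect_true(foci_datasets_equal(a$dataset, b$dataset))
  }
  # and an unseeded run reports the seed it drew, which replays it
  msgs <- capture_messages(u <- remove_multiple(d, mode = 2))
  expect_match(paste(msgs, collapse = ""), "seed")
  v <- remove_multiple(d, mode = 2, seed = u$seed)
  expect_identical(u$retained, v$retained)
})

test_that("remove_multiple keeps exactly one experiment per paper, the group
           maximum under mode 1, in input order", {
  set.seed(123)
  for (i in 1:15) {
    spec <- fixture_spec(n_experiments = 12L,
                         same_paper_groups = c(2L, 3L), seed = i)
    d <- generate_dataset(spec)
    keys <- tolower(sub(":.*$", "", experiment_keys(d)))
    subj <- experiment_subjects(d)
    res <- remove_multiple(d, mode = 1, seed = i)
    expect_equal(res$p, length(unique(keys)))
    expect_equal(res$p, n_experiments(res$dataset))
    expect_false(is.unsorted(res$retained))
    for (r in res$retained) {
      grp <- which(keys == keys[r])
      expect_equal(subj[r], max(subj[grp]))
    }
    res2 <- remove_multiple(d, mode = 2, seed = i)
    expect_equal(sort(tolower(experiment_keys(res2$dataset))),
                 sort(unique(keys)))
  }
  expect_error(remove_multiple(d, mode = 3), class = "cbma_bad_mode")
  expect_error(remove_multiple(foci_dataset(list()), mode = 1),
               class = "cbma_empty_dataset")
})

test_that("tissue filtering keeps exactly the in-mask foci and drops
           emptied experiments", {
  m <- small_mask(c(10L, 10L, 10L), radius = 5)
  inside <- c(1, 1, 1)    # voxel center near the sphere center
  outside <- c(9, 9, 9)   # voxel center outside radius 5
  expect_true(foci_in_mask(m, inside))
  expect_false(foci_in_mask(m, outside))
  d <- foci_dataset(list(
    make_exp("In,2001", 10L, rbind(inside, c(3, 1, 1), c(-1, 1, 1),
                                   outside, outside - c(2, 0, 0))),
    make_exp("Out,2002", 11L, rbind(outside, -outside))))
  res <- filter_by_tissue(d, m)
  expect_equal(res$p, 1L)
  expect_equal(nrow(res$dataset$experiments[[1]]$foci), 3L)
  expect_true(all(foci_in_mask(m, res$dataset$experiments[[1]]$foci)))
  expect_equal(res$dataset$experiments[[1]]$n_subjects, 10L)
  # identity mask keeps everything
  all_true <- volume_mask(array(TRUE, dim = m$shape), m$affine)
  res2 <- filter_by_tissue(d, all_true)
  expect_equal(res2$p, 2L)
  expect_true(foci_datasets_equal(res2$dataset, d))
})

test_that("tissue filtering agrees with the brute-force membership oracle", {
  set.seed(5)
  m <- small_mask(c(8L, 8L, 8L), radius = 4)
  spec <- fixture_spec(n_experiments = 12L, in_mask_fraction = 0.6, seed = 2L)
  d <- generate_dataset(spec, mask = m)
  res <- filter_by_tissue(d, m)
  oracle_counts <- vapply(d$experiments, function(e)
    sum(brute_force_in_mask(m, e$foci)), numeric(1))
  expect_equal(res$p, sum(oracle_counts > 0))
  got_total <- sum(vapply(res$dataset$experiments,
                          function(e) nrow(e$foci), integer(1)))
  expect_equal(got_total, sum(oracle_counts))
  expect_true(all(vapply(res$dataset$experiments,
                         function(e) nrow(e$foci) > 0L, logical(1))))
})

test_that("MACM selection keeps complete focus lists of hit experiments", {
  m <- small_mask(c(10L, 10L, 10L), radius = 3)
  hit <- c(1, 1, 1); miss <- c(9, 9, 9)
  d <- foci_dataset(list(
    make_exp("Hit,2001", 10L, rbind(hit, miss, miss + c(0, -2, 0),
                                    miss * -1, c(7, 7, 7))),
    make_exp("Miss,2002", 11L, rbind(miss, -miss))))
  res <- prepare_macm(d, m)
  expect_equal(res$p, 1L)
  expect_equal(nrow(res$dataset$experiments[[1]]$foci), 5L)  # all 5 kept
  # empty ROI drops everything; whole-grid ROI is the identity
  none <- volume_mask(array(FALSE, dim = m$shape), m$affine)
  expect_equal(prepare_macm(d, none)$p, 0L)
  full <- volume_mask(array(TRUE, dim = m$shape), m$affine)
  res3 <- prepare_macm(d, full)
  expect_true(foci_datasets_equal(res3$dataset, d))
})
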