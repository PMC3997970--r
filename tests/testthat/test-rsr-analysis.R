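test_that("the code computed from the count table reproduces the published SP1 column", {
  computed <- compute_rsr_code(sp1_assay_counts(), protein = "SP1")
  published <- published_code("SP1")
  expect_identical(computed$ranking$triplet, published$ranking$triplet)
  # the tied pairs resolve in table order
  r <- computed$ranking
  expect_identical(r$triplet[r$rank %in% 9:10], c("TAG", "CCG"))   # 1850
  expect_identical(r$triplet[r$rank %in% 30:31], c("CCT", "CAA"))  # 300
  expect_identical(r$triplet[r$rank %in% 39:40], c("TTT", "CGA"))  # 225
})

test_that("an all-tied table ranks in input order; ranking is always a permutation", {
  flat <- tibble::tibble(triplet = rev(triplets()), p32_count = 7)
  code <- compute_rsr_code(flat)
  expect_identical(code$ranking$triplet, rev(triplets()))
  expect_setequal(code$ranking$triplet, triplets())
})

test_that("ranking agrees with a selection-sort oracle on random count vectors", {
  set.seed(99)
  for (i in 1:10) {
    counts <- sample(0:500, 64, replace = TRUE)
    records <- tibble::tibble(
      triplet = sample(triplets()), p32_count = counts
    )
    code <- compute_rsr_code(records)
    expect_identical(code$ranking$triplet,
                     records$triplet[oracle_rank_order(records$p32_count)])
  }
})

test_that("duplicate triplets are rejected when computing a code", {
  bad <- sp1_assay_counts()
  bad$triplet[5] <- bad$triplet[4]
  expect_error(compute_rsr_code(bad), "duplicate")
})

test_that("stability grouping reproduces the published 26/35/3 split", {
  sizes <- table(stability_grouping(sp1_assay_counts())$group)
  expect_identical(as.integer(sizes[c("strong", "weak", "undetectable")]),
                   c(26L, 35L, 3L))
})

test_that("stability grouping responds to threshold and degenerate input", {
  tab <- sp1_assay_counts()
  sizes1 <- table(stability_grouping(tab, threshold = 1)$group)
  expect_identical(as.integer(sizes1[c("strong", "weak", "undetectable")]),
                   c(61L, 0L, 3L))
  zero <- tibble::tibble(triplet = triplets(), p32_count = 0L)
  sizes0 <- table(stability_grouping(zero)$group)
  expect_identical(as.integer(sizes0[c("strong", "weak", "undetectable")]),
                   c(0L, 0L, 64L))
  # exclusive comparison demotes the boundary triplet (CGC at exactly 500)
  excl <- stability_grouping(tab, threshold = 500, inclusive = FALSE)
  expect_identical(sum(excl$group == "strong"), 25L)
  expect_error(stability_grouping(tab, threshold = 0), "positive")
})

test_that("grouping always partitions the 64 triplets", {
  set.seed(7)
  for (i in 1:5) {
    records <- tibble::tibble(
      triplet = triplets(),
      p32_count = sample(0:1000, 64, replace = TRUE)
    )
    g <- stability_grouping(records, threshold = sample(1:800, 1))
    expect_identical(sum(table(g$group)), 64L)
  }
})

test_that("composition of the published top 26 is 18/6 GC and 8/3 AT", {
  comp <- composition_summary(sp1_assay_counts(), top_k = 26)
  expect_identical(comp$gc_rich, 18L)
  expect_identical(comp$gc_triplet, 6L)
  expect_identical(comp$at_rich, 8L)
  expect_identical(comp$at_triplet, 3L)
})

test_that("composition at top_k 64 is the global 32/8/32/8 for any code", {
  set.seed(11)
  for (code in list(published_code("SP1"), rsr_code(sample(triplets())))) {
    comp <- composition_summary(code, top_k = 64)
    expect_identical(unlist(comp[c("gc_rich", "gc_triplet",
                                   "at_rich", "at_triplet")],
                            use.names = FALSE),
                     c(32L, 8L, 32L, 8L))
  }
  top1 <- composition_summary(published_code("SP1"), top_k = 1)
  expect_identical(top1$gc_rich, 1L) # rank 1 is CGG
  expect_identical(top1$at_rich, 0L)
  expect_error(composition_summary(published_code("SP1"), top_k = 65),
               "between 1 and 64")
})

test_that("code comparison has the expected fixed points and antithesis", {
  sp1 <- published_code("SP1")
  self <- glance(compare_rank_codes(sp1, sp1))
  expect_equal(self$spearman_rho, 1)
  expect_equal(self$kendall_tau, 1)
  expect_identical(self$footrule, 0L)

  rev_code <- rsr_code(rev(sp1$ranking$triplet), protein = "reversed")
  expect_equal(glance(compare_rank_codes(sp1, rev_code))$kendall_tau, -1)
})

test_that("per-triplet shifts match the published rank columns", {
  cmp <- compare_rank_codes(published_code("SP1"), published_code("MQ135"))
  shifts <- tidy(cmp)
  cgg <- shifts[shifts$triplet == "CGG", ]
  expect_identical(cgg$rank_a, 1L)
  expect_identical(cgg$rank_b, 29L)
  expect_identical(cgg$shift, 28L)
})

test_that("rank shift report lays out ranks per protein", {
  report <- rank_shift_report(rank_codes())
  expect_identical(nrow(report), 64L)
  cgg <- report[report$triplet == "CGG", ]
  expect_identical(
    as.integer(cgg[c("SP1", "CB1", "MR14", "MQ91", "MQ135", "MQ151")]),
    c(1L, 17L, 14L, 2L, 29L, 23L)
  )
  expect_identical(report$SP1[report$triplet == "GCG"], 2L)

  twin <- rank_shift_report(list(
    published_code("SP1"),
    rsr_code(published_code("SP1")$ranking$triplet, protein = "copy")
  ))
  expect_identical(twin$SP1, twin$copy)
  expect_error(rank_shift_report(list(published_code("SP1"))), "at least two")
})

test_that("tidy and glance expose the code as tibbles", {
  code <- compute_rsr_code(sp1_assay_counts())
  td <- tidy(code)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 64L)
  gl <- glance(code)
  expect_identical(gl$strongest, "CGG")
  expect_identical(gl$gc_rich_top26, 18L)
})
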