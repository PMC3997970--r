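test_that("exact counting handles overlaps, palindromes and degenerate queries", {
  expect_identical(nrow(count_exact(c(g = "GGGGG"), "GG")), 4L)
  expect_identical(nrow(count_exact(c(g = "GGGGG"), "GG", overlapping = FALSE)),
                   2L)

  pal <- count_exact(c(g = "GAATTC"), "GAATTC", strand = "both")
  expect_identical(nrow(pal), 2L)
  expect_setequal(pal$strand, c("+", "-"))
  expect_identical(unique(pal$start), 0L)

  expect_identical(nrow(count_exact(c(g = "ACGT"), "")), 0L)
  expect_identical(nrow(count_exact(c(g = "ACG"), "ACGTACGT")), 0L)
  expect_error(count_exact(c(g = "ACGT"), "AXG"), "invalid character")
})

test_that("genome N bases never match and record boundaries are respected", {
  g <- c(a = "ACGNACG", b = "TTACGTT")
  hits <- count_exact(g, "ACG")
  expect_identical(nrow(hits), 3L)
  expect_false(any(hits$start == 3 & hits$record == "a"))
  # no match spans the a/b boundary
  expect_identical(nrow(count_exact(g, "ACGTT")), 1L)
  expect_identical(count_exact(g, "ACGTT")$record, "b")
})

test_that("scanner agrees with the naive oracle on random instances", {
  set.seed(2024)
  n_checked <- 0L
  for (i in 1:60) {
    genome <- c(
      r1 = random_genome_chr(sample(20:400, 1)),
      r2 = random_genome_chr(sample(20:400, 1),
                             bases = c("A", "C", "G", "T", "N"))
    )
    k <- sample(1:12, 1)
    query <- random_genome_chr(k)
    for (strand in c("forward", "both")) {
      for (overlapping in c(TRUE, FALSE)) {
        got <- count_exact(genome, query, strand = strand,
                           overlapping = overlapping)
        want <- oracle_scan(genome, query, strand = strand,
                            overlapping = overlapping)
        expect_identical(nrow(got), nrow(want))
        expect_identical(got$start, as.integer(want$start))
        expect_identical(got$strand, want$strand)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("counts in both-strand mode are invariant under genome reverse complement", {
  set.seed(5)
  for (i in 1:10) {
    seq <- random_genome_chr(300)
    query <- random_genome_chr(sample(2:8, 1))
    a <- nrow(count_exact(c(g = seq), query, strand = "both"))
    b <- nrow(count_exact(c(g = dna_revcomp(seq)), query, strand = "both"))
    expect_identical(a, b)
  }
})

test_that("degenerate pattern counting enumerates every instantiation", {
  # one copy of each of the 64 sites, separated by G-free spacers
  sites <- paste0("GGG", triplets(), "GGG")
  genome <- c(g = paste(sites, collapse = "TTAACC"))
  counts <- count_pattern(genome, "GGGNNNGGG")
  expect_identical(nrow(counts), 64L)
  expect_identical(counts$fill, triplets())
  expect_true(all(counts$count == 1L))

  # spot-check against the naive oracle
  cs <- strsplit(genome[[1]], "")[[1]]
  for (t in c("AAA", "CGG", "GGG", "TTT")) {
    expect_identical(
      counts$count[counts$fill == t],
      length(oracle_starts(cs, paste0("GGG", t, "GGG")))
    )
  }
})

test_that("pattern counting reduces to exact counting and respects guards", {
  g <- c(g = random_genome_chr(500))
  exact <- count_pattern(g, "ACGT")
  expect_identical(nrow(exact), 1L)
  expect_identical(exact$count, nrow(count_exact(g, "ACGT")))

  no_g <- c(g = paste(rep("ATC", 100), collapse = ""))
  zero <- count_pattern(no_g, "GGGNNNGGG")
  expect_true(all(zero$count == 0L))
  expect_identical(nrow(zero), 64L)

  expect_error(count_pattern(g, "NNNNNNN"), "max_wildcards")
  expect_identical(nrow(count_pattern(g, "NNNNNNN", max_wildcards = 7)),
                   16384L)
})

test_that("pattern totals equal the degenerate-window count", {
  set.seed(31)
  g <- c(g = random_genome_chr(2000, bases = c("G", "C", "A")))
  counts <- count_pattern(g, "GGNNGG")
  cs <- strsplit(g[[1]], "")[[1]]
  expect_identical(sum(counts$count),
                   length(oracle_starts(cs, "GGNNGG")))
})

test_that("dimer search finds the planted HBB composite under both conventions", {
  g <- simulate_genome(
    5000, planted = c(GGCAGACTTGTGGAGAGGAGTCAG = 1), seed = 42
  )
  hits <- find_dimer_sites(g, "GGCAGACTT", "AGGAGTCAG", 6, 6)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$composite, "GGCAGACTTGTGGAGAGGAGTCAG")
  expect_identical(hits$end - hits$start, 24L)

  opposite <- find_dimer_sites(g, "GGCAGACTT", "CTGACTCCT", 6, 6,
                               convention = "opposite_strand")
  expect_identical(as.data.frame(opposite), as.data.frame(hits))

  none <- find_dimer_sites(g, "AAAAAAAAA", "AGGAGTCAG", 6, 6)
  expect_identical(nrow(none), 0L)
})

test_that("the convention algebra holds on random queries", {
  set.seed(17)
  g <- c(g = random_genome_chr(4000, bases = c("A", "C")))
  for (i in 1:5) {
    left <- random_genome_chr(4, bases = c("A", "C"))
    right <- random_genome_chr(4, bases = c("A", "C"))
    a <- find_dimer_sites(g, left, right, 0, 3,
                          convention = "opposite_strand")
    b <- find_dimer_sites(g, left, dna_revcomp(right), 0, 3)
    expect_identical(as.data.frame(a), as.data.frame(b))
  }
})

test_that("a spacer range is the union of its fixed-spacer searches", {
  set.seed(23)
  g <- c(g = random_genome_chr(3000, bases = c("A", "G")))
  left <- "GAGA"
  right <- "AGAG"
  ranged <- find_dimer_sites(g, left, right, 1, 3)
  fixed <- dplyr::bind_rows(lapply(1:3, function(s) {
    find_dimer_sites(g, left, right, s, s)
  }))
  fixed <- dplyr::arrange(fixed, record, start, spacer_length, strand)
  expect_identical(as.data.frame(ranged), as.data.frame(fixed))
  expect_false(any(duplicated(
    ranged[c("record", "start", "spacer_length", "strand")]
  )))
})

test_that("expected occurrence counts follow the closed form", {
  expect_equal(
    expected_occurrences("AAAAAAAAA", 4^9 + 8),
    1.0
  )
  expect_equal(expected_occurrences("ACGTACGT", 5), 0)
  expect_equal(
    expected_occurrences("AC", 100, c(A = 0.5, C = 0.3, G = 0.1, T = 0.1)),
    99 * 0.5 * 0.3
  )
  expect_error(
    expected_occurrences("AC", 100, c(A = 0.5, C = 0.6, G = -0.05, T = -0.05)),
    "non-negative"
  )
})

test_that("simulated occurrence counts agree with the analytic expectation", {
  set.seed(1234)
  query <- "ACG"
  L <- 300
  counts <- replicate(200, {
    nrow(count_exact(c(g = random_genome_chr(L)), query))
  })
  analytic <- expected_occurrences(query, L)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - analytic), 3 * se)
})

test_that("off-target landscape reproduces the published table from fixtures", {
  land <- offtarget_landscape(sp1_assay_counts(), published_code("SP1"))
  expect_identical(nrow(land), 64L)
  expect_identical(land$rank, 1:64)
  expect_identical(land$triplet[1], "CGG")
  expect_identical(land$occurrences[1], 16697L)
  expect_identical(sum(land$occurrences), 1261301L)
  expect_identical(land$site[1], "GGGCGGGGG")
})

test_that("off-target landscape on a genome matches pattern counting", {
  set.seed(77)
  g <- c(g = random_genome_chr(3000, bases = c("G", "C", "A")))
  land <- offtarget_landscape(g, published_code("SP1"))
  counts <- count_pattern(g, "GGGNNNGGG")
  expect_identical(
    land$occurrences[order(land$triplet)],
    counts$count[order(counts$fill)]
  )

  bare <- offtarget_landscape(g, published_code("SP1"), flank = "")
  cs <- strsplit(g[[1]], "")[[1]]
  for (t in c("GCA", "AAA", "CCC")) {
    expect_identical(bare$occurrences[bare$triplet == t],
                     length(oracle_starts(cs, t)))
  }
})

test_that("FASTA and BED round trips preserve scanning results", {
  g <- simulate_genome(400, planted = c(ACGTACG = 2), seed = 3)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_genome(g, fa)
  back <- read_genome(fa)
  expect_identical(as.character(back), as.character(g))

  hits <- count_exact(g, "ACGTACG")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(hits, bed)
  lines <- strsplit(readLines(bed), "\t")
  expect_length(lines, 2)
  expect_identical(lines[[1]][4], "ACGTACG")
  expect_identical(as.integer(lines[[1]][3]) - as.integer(lines[[1]][2]), 7L)
})
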