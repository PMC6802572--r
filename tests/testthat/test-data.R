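test_that("FASTA and relaxed PHYLIP files round through the reader", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACGT", ">B", "acga"), fa)
  aln <- read_alignment(fa, "fasta")
  expect_equal(aln$site_count, 4)
  expect_equal(aln$sequences, c("ACGT", "ACGA"))  # uppercased

  ph <- tempfile(fileext = ".phy")
  writeLines(c("3 10", "tax1 ACGTACGTAC", "tax2 ACGTA CGTAA",
               "tax3", "ACGTACGTAG"), ph)
  aln2 <- read_alignment(ph, "phylip")
  expect_equal(length(aln2$taxon_names), 3)
  expect_equal(aln2$site_count, 10)
  expect_equal(aln2$sequences[2], "ACGTACGTAA")

  # U -> T mapping
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACGU", ">B", "ACGA"), fa2)
  expect_equal(read_alignment(fa2)$sequences[1], "ACGT")
})

test_that("alignment parse errors name the offender", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACGT", ">B", "ACG"), fa)
  expect_error(read_alignment(fa), "B")
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACGT", ">A", "ACGA"), fa2)
  expect_error(read_alignment(fa2), "duplicate")
  expect_error(alignment(c("A", "B"), c("ACXT", "ACGT")), "site 3")
})

test_that("newick parsing handles rooted, unrooted and round trips", {
  tr <- read_newick("((A:0.1,B:0.1):0.05,C:0.2);", taxa = c("A", "B", "C"))
  expect_equal(tr$n_tips, 3)
  expect_equal(tr$tip_labels, c("A", "B", "C"))
  # trifurcating root: rooted on the first-listed child edge, split equally
  tu <- read_newick("(A:0.1,B:0.1,C:0.2);", taxa = c("A", "B", "C"))
  expect_equal(tu$n_tips, 3)
  expect_equal(sum(tu$edge_length, na.rm = TRUE), 0.4, tolerance = 1e-12)

  cherry <- read_newick("(A:0.1,B:0.1);")
  expect_equal(cherry$n_tips, 2)

  tr128 <- random_tree(128, branch_mean = 0.15, seed = 3)
  rt <- read_newick(write_newick(tr128), taxa = tr128$tip_labels)
  expect_identical(rt$children, tr128$children)
  expect_equal(rt$edge_length, tr128$edge_length, tolerance = 1e-12)

  expect_error(read_newick("((A:1,B:1;"), ".")
  expect_error(read_newick("((A:0.1,B:0.1):0.05,C:0.2);", taxa = c("A", "B", "D")),
               "not in tree")
})

test_that("pattern compression collapses identical columns per subset", {
  aln <- alignment(c("x", "y", "z"), c("AAA", "AAA", "CCT"))
  ps <- compress_patterns(aln)
  expect_equal(ncol(ps$patterns), 2)
  expect_equal(ps$weights, c(2, 1))

  aln2 <- alignment(c("x", "y", "z"),
                    c(strrep("A", 7), strrep("A", 7), strrep("C", 7)))
  ps2 <- compress_patterns(aln2)
  expect_equal(ps2$weights, 7)

  # two subsets over a 6-site toy alignment vs a brute-force column tally
  aln3 <- alignment(c("x", "y"), c("AACCGA", "ATCCGA"))
  sos <- c(1L, 1L, 1L, 2L, 2L, 2L)
  ps3 <- compress_patterns(aln3, sos)
  cols <- vapply(1:6, function(i) paste(substr(aln3$sequences, i, i),
                                        collapse = ""), character(1))
  for (s in 1:2) {
    rg <- ps3$subset_ranges[s, ]
    expect_equal(rg[2] - rg[1] + 1L,
                 length(unique(cols[sos == s])))
    expect_equal(sum(ps3$weights[rg[1]:rg[2]]), sum(sos == s))
  }
  expect_error(compress_patterns(aln3, c(1L, 1L, 1L, 3L, 3L, 3L)), "empty")
})

test_that("compress then expand reproduces the original column multiset", {
  set.seed(21)
  aln <- random_patterns_alignment(6, 40)
  sos <- sample(1:2, 40, replace = TRUE)
  sos <- sort(sos) # keep both subsets nonempty
  ps <- compress_patterns(aln, sos)
  expect_equal(sum(ps$weights), 40)
  cols <- vapply(1:40, function(i) paste(substr(aln$sequences, i, i),
                                         collapse = ""), character(1))
  pats <- apply(ps$patterns, 2, paste, collapse = "")
  # per subset, expanding patterns by weight gives the original columns
  for (s in 1:2) {
    rg <- ps$subset_ranges[s, ]
    expanded <- rep(pats[rg[1]:rg[2]], ps$weights[rg[1]:rg[2]])
    expect_equal(sort(expanded), sort(cols[sos == s]))
  }
  # site-to-pattern map is consistent
  expect_equal(pats[ps$pattern_of_site], cols)
})

test_that("tip encoding: compact codes, IUPAC partials, sentinels", {
  expect_equal(encode_tip("ACGT", "compact"), c(0L, 1L, 2L, 3L))
  expect_equal(encode_tip("ANR-", "compact"), c(0L, 4L, 4L, 4L))
  p <- encode_tip("R", "partial")
  expect_equal(as.numeric(p), c(1, 0, 1, 0))
  expect_equal(as.numeric(encode_tip("-", "partial")), c(1, 1, 1, 1))
  expect_error(encode_tip("AXG", "compact"), "site 2")
})

test_that("partition config files parse 1-based inclusive ranges", {
  f <- tempfile()
  writeLines(c("# comment", "gene1 = 1-4", "gene2 = 5-8, 9-10"), f)
  pc <- read_partition_config(f, 10)
  expect_equal(pc$names, c("gene1", "gene2"))
  expect_equal(pc$subset_of_site, c(rep(1L, 4), rep(2L, 6)))
  f2 <- tempfile()
  writeLines("gene1 = 1-9", f2)
  expect_error(read_partition_config(f2, 10), "site 10")
  f3 <- tempfile()
  writeLines(c("a = 1-5", "b = 5-10"), f3)
  expect_error(read_partition_config(f3, 10), "overlap")
})
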