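test_that("pairwise identity matches the Hamming fraction for equal lengths", {
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  s <- paste(rep("A", 100), collapse = "")
  expect_equal(pairwise_identity(s, s), 1.0)
  t25 <- paste(c(rep("C", 25), rep("A", 75)), collapse = "")
  expect_equal(pairwise_identity(s, t25), 0.75)

  set.seed(31)
  for (i in 1:25) {
    ab <- random_seqs(2, 40)
    expect_equal(pairwise_identity(ab[1], ab[2]),
                 hamming_identity(ab[1], ab[2]))
    expect_equal(pairwise_identity(ab[1], ab[2]),
                 pairwise_identity(ab[2], ab[1]))
  }
  expect_error(pairwise_identity("", "A"), "empty")
})

test_that("unequal lengths use global alignment identity, cross-checked", {
  # one end gap: 3 matching columns of 4
  expect_equal(pairwise_identity("ACGT", "ACG"), 0.75)
  # internal gap placement: ACGT vs AGT aligns A-GT, 3 of 4 columns match
  expect_equal(pairwise_identity("ACGT", "AGT"), 0.75)
  expect_equal(pairwise_identity("A", "AAAA"), 0.25)

  # identity agrees with an independent plain-R alignment oracle, whose
  # optimal score in turn agrees with Biostrings under the same scoring;
  # identities of co-optimal alignments are pinned by the traceback rule
  set.seed(32)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:15) {
    a <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1), TRUE),
               collapse = "")
    ref <- oracle_nw(a, b)
    ali <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(ref$score, Biostrings::score(ali))
    expect_equal(pairwise_identity(a, b), ref$identity, tolerance = 1e-12)
  }
})

test_that("identity matrices are symmetric with unit diagonal", {
  one <- seq_tbl("a", "ACGT")
  expect_equal(identity_matrix(one), matrix(1, 1, 1,
                                            dimnames = list("a", "a")))

  s <- paste(rep("A", 100), collapse = "")
  flip <- function(k) paste(c(rep("C", k), rep("A", 100 - k)), collapse = "")
  m <- identity_matrix(c(s, flip(10), flip(30)))
  expect_equal(sort(m[upper.tri(m)]), c(0.7, 0.8, 0.9))
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(1, 3), rownames(m)))

  set.seed(33)
  recs <- random_records(12, 25)
  m <- identity_matrix(recs)
  expect_equal(unname(m), oracle_identity_matrix(recs$bases))
})

test_that("guide order places high-identity neighbours adjacently", {
  single <- matrix(1, 1, 1, dimnames = list("a", "a"))
  expect_equal(as.integer(guide_order(single)), 1L)

  im <- matrix(c(1, .9, .6, .9, 1, .6, .6, .6, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ord <- guide_order(im)
  expect_equal(abs(diff(match(c(1, 2), ord))), 1) # A and B adjacent

  # all-equal off-diagonals: the tie-break forces the identity permutation
  flat <- matrix(0.8, 5, 5)
  diag(flat) <- 1
  dimnames(flat) <- list(paste0("s", 1:5), paste0("s", 1:5))
  expect_equal(as.integer(guide_order(flat)), 1:5)

  # always a permutation, and invariant to duplicating the computation
  set.seed(34)
  recs <- random_records(15, 30)
  m <- identity_matrix(recs)
  o1 <- guide_order(m)
  expect_setequal(as.integer(o1), 1:15)
  expect_identical(o1, guide_order(m))
})

test_that("UPGMA merge heights agree with hclust on tie-free instances", {
  set.seed(35)
  for (i in 1:5) {
    n <- 8
    # continuous jitter makes ties measure-zero so orderings cannot disagree
    m <- matrix(stats::runif(n * n, 0, 1), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    tree <- agglomerative_merge_tree(m, "avg")
    hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
    expect_equal(sort(tree$merges$identity), sort(1 - hc$height))
  }
})

test_that("staggered order alternates the two ends", {
  expect_equal(staggered_order(1:5), c(1L, 5L, 2L, 4L, 3L))
  expect_equal(staggered_order(1:4), c(1L, 4L, 2L, 3L))
  expect_equal(staggered_order(1L), 1L)
  expect_equal(staggered_order(integer(0)), integer(0))

  set.seed(36)
  for (n in c(2, 7, 10, 31)) {
    p <- sample.int(n)
    st <- staggered_order(p)
    expect_setequal(st, p) # a permutation of its input
    expect_equal(st[1:2], c(p[1], p[n]))
  }
})

test_that("identity matrix and guide order export to text", {
  recs <- seq_tbl(c("a", "b"), c("ACGT", "ACGA"))
  m <- identity_matrix(recs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_identity_tsv(m, f)
  back <- as.matrix(utils::read.delim(f, row.names = 1))
  dimnames(back) <- dimnames(m)
  expect_equal(back, m)

  g <- withr::local_tempfile()
  write_guide_order(guide_order(m), g)
  expect_setequal(readLines(g), c("a", "b"))
})
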