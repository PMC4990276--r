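three_seq_matrix <- function() {
  matrix(c(1, .9, .8, .9, 1, .7, .8, .7, 1), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

test_that("merge trees follow the linkage semantics on the 3-sequence case", {
  im <- three_seq_matrix()
  # single linkage: nearest cross edge A-C = 0.8 joins the rest
  tmin <- agglomerative_merge_tree(im, "min")
  expect_equal(tmin$merges$identity, c(0.9, 0.8))
  # complete linkage: farthest cross edge B-C = 0.7
  tmax <- agglomerative_merge_tree(im, "max")
  expect_equal(tmax$merges$identity, c(0.9, 0.7))
  # UPGMA: mean of 0.8 and 0.7
  tavg <- agglomerative_merge_tree(im, "avg")
  expect_equal(tavg$merges$identity, c(0.9, 0.75))
  expect_equal(tavg$merges$a, c(1L, 1L))
  expect_equal(tavg$merges$b, c(2L, 3L))
  # linkage identity is non-increasing along every merge sequence
  for (t in list(tmin, tmax, tavg)) {
    expect_true(all(diff(t$merges$identity) <= 1e-9))
  }
})

test_that("cutting a tree applies >= cutoff joins, leaving non-joining segments", {
  im <- three_seq_matrix()
  tavg <- agglomerative_merge_tree(im, "avg")
  tmax <- agglomerative_merge_tree(im, "max")
  # a merge at exactly the cutoff applies (identity meeting the cutoff joins)
  expect_equal(cut_at(tavg, 0.75), rep(1L, 3))
  expect_equal(cut_at(tavg, 0.76), c(1L, 1L, 2L))
  # 0.7 < 0.75: C never joins under complete linkage in the displayed range
  expect_equal(cut_at(tmax, 0.75), c(1L, 1L, 2L))

  set.seed(41)
  distinct <- random_records(8, 40, n_mut = 15:20)
  distinct <- dereplicate(distinct)
  t <- agglomerative_merge_tree(identity_matrix(distinct), "min")
  expect_equal(cut_at(t, 1.0), seq_len(nrow(distinct))) # all singletons
})

test_that("agglomerative ladders handle degenerate inputs", {
  one <- assign_groups(seq_tbl("a", "ACGTACGT"))
  lad <- build_agglomerative_ladder(one, "avg")
  expect_equal(nrow(lad$rings), 26L)
  expect_true(all(lad$rings$n_members == 1))

  same <- assign_groups(seq_tbl(paste0("s", 1:100),
                                rep(strrep("ACGGT", 20), 100)))
  lad <- build_agglomerative_ladder(same, "max")
  expect_equal(nrow(lad$rings), 26L) # one cluster per ring
  expect_true(all(lad$rings$n_members == 100))

  set.seed(42)
  recs <- dereplicate(random_records(20, 40))
  lad <- build_agglomerative_ladder(recs, "avg")
  counts <- table(lad$rings$level)
  expect_true(all(diff(as.integer(counts)) >= 0)) # non-decreasing in cutoff
})

test_that("greedy centroid clustering follows the stated assignment rule", {
  # order A, B, C with identities AB = 0.9, AC = 0.8, BC = 0.7 over 20-mers
  a <- strrep("A", 20)
  b <- paste0(strrep("A", 18), "CC")
  c_ <- paste0("GGGG", strrep("A", 16))
  recs <- assign_groups(seq_tbl(c("A", "B", "C"), c(a, b, c_)))
  expect_equal(pairwise_identity(a, b), 0.9)
  expect_equal(pairwise_identity(a, c_), 0.8)
  expect_equal(pairwise_identity(b, c_), 0.7)

  p85 <- greedy_centroid_partition(recs, 0.85)
  expect_equal(p85$members, list(c(1L, 2L), 3L))
  expect_equal(p85$centroid, c(1L, 3L))

  p75 <- greedy_centroid_partition(recs, 0.75)
  expect_equal(nrow(p75), 1L) # B and C both best-match centroid A
  expect_equal(p75$centroid, 1L)
  expect_equal(sort(p75$members[[1]]), 1:3)

  # all pairs >= cutoff: a single cluster whose centroid is the first record
  set.seed(43)
  recs2 <- assign_groups(seq_tbl(paste0("s", 1:6), random_seqs(6, 50, 0:2)))
  pall <- greedy_centroid_partition(recs2, 0.5)
  expect_equal(nrow(pall), 1L)
  expect_equal(pall$centroid, 1L)
})

test_that("divisive ladders refine stepwise and respect degenerate cases", {
  one <- assign_groups(seq_tbl("a", "ACGTACGT"))
  lad <- build_divisive_ladder(one)
  expect_equal(nrow(lad$rings), 26L)
  expect_true(all(lad$rings$n_members == 1))

  same <- dereplicate(assign_groups(
    seq_tbl(paste0("s", 1:10), rep(strrep("ACGGT", 8), 10))))
  lad <- build_divisive_ladder(same)
  expect_equal(nrow(lad$rings), 26L)
  expect_true(all(lad$rings$g1 + lad$rings$g2 == 10))

  set.seed(44)
  gs <- simulate_mutation_lineage(n_seqs = 50, length = 60, iterations = 8,
                                  policy = evening_policy("absolute", 12),
                                  seed = 3)
  recs <- dereplicate(assign_groups(gs$snapshots[[9]]))
  lad <- build_divisive_ladder(recs)
  rings <- lad$rings
  n <- nrow(recs)
  for (l in 2:26) {
    ring <- rings[rings$level == l, ]
    prev <- rings[rings$level == l - 1, ]
    for (k in seq_len(nrow(ring))) { # subset-containment vs recorded parent
      par <- prev$members[[match(ring$parent_id[k], prev$cluster_id)]]
      expect_true(all(ring$members[[k]] %in% par))
    }
  }
  # every ring partitions the record set
  for (l in c(1, 13, 26)) {
    expect_setequal(unname(unlist(rings$members[rings$level == l])),
                    seq_len(n))
  }
  # centroids are members of their clusters
  expect_true(all(mapply(function(c, m) c %in% m,
                         rings$centroid, rings$members)))
})

test_that("abundance-weighted group tallies survive dereplication", {
  r <- seq_tbl(c("w", "x", "y", "z"),
               c("AAAA", "AAAA", "GGGG", "AAAT"))
  r <- assign_groups(r)
  d <- dereplicate(r)
  lad <- build_agglomerative_ladder(d, "min")
  base <- lad$rings[lad$rings$level == 1, ]
  expect_equal(sum(base$g1), 3) # the two collapsed AAAA copies still weigh 2
  expect_equal(sum(base$g2), 1)
  expect_equal(sum(base$g1 + base$g2), sum(r$count))
})

test_that("ladders round-trip through the TSV exchange format", {
  set.seed(45)
  recs <- dereplicate(random_records(12, 30))
  lad <- build_divisive_ladder(recs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ladder_tsv(lad, f)
  back <- read_ladder_tsv(f)
  expect_equal(back$method, "centroid")
  expect_equal(back$rings$cutoff, lad$rings$cutoff)
  expect_equal(back$rings$cluster_id, lad$rings$cluster_id)
  expect_equal(back$rings$parent_id, lad$rings$parent_id)
  expect_equal(back$rings$g1, lad$rings$g1)
  expect_equal(back$rings$g2, lad$rings$g2)
  expect_equal(lapply(back$rings$members, function(m) sort(back$records$id[m])),
               lapply(lad$rings$members, function(m) sort(recs$id[m])))
})
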