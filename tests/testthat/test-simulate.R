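test_that("ancestor construction honours exact GC composition", {
  set.seed(1)
  a <- make_ancestor(100, gc_exact = 0.5)
  expect_equal(gc_fraction(a$bases), 0.5)
  expect_equal(nchar(a$bases), 100L)

  b <- make_ancestor(4, gc_exact = 1.0)
  expect_true(grepl("^[GC]+$", b$bases))

  c_ <- make_ancestor(100)
  expect_true(grepl("^[ACGT]{100}$", c_$bases))

  expect_error(make_ancestor(10, gc_exact = 1 / 3), "whole number")
})

test_that("single substitutions hit one position, uniformly over alternatives", {
  set.seed(2)
  for (i in 1:20) {
    s <- random_seqs(1, 30)
    m <- substitute_once(s)
    expect_equal(sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]]), 1L)
  }

  # "A" must mutate to C, G or T with frequency 1/3 each; 3 sigma band for
  # 30000 binomial draws at p = 1/3 is about +/- 245
  set.seed(3)
  draws <- table(substitute_once(rep("A", 30000)))
  expect_setequal(names(draws), c("C", "G", "T"))
  expect_true(all(abs(draws - 10000) < 245))

  # reversion is possible: two hits on a length-1 sequence can restore it
  set.seed(4)
  twice <- vapply(1:200, function(i) substitute_once(substitute_once("A")),
                  character(1))
  expect_true(any(twice == "A"))
})

test_that("mutation lineage snapshots carry exactly m events each", {
  gs <- simulate_mutation_lineage(n_seqs = 25, length = 60, iterations = 6,
                                  policy = evening_policy("absolute", 9),
                                  seed = 7)
  expect_length(gs$snapshots, 7)
  expect_true(all(vapply(gs$snapshots, nrow, integer(1)) == 25))
  expect_equal(length(unique(gs$snapshots[[1]]$bases)), 1L) # identical at 0
  expect_equal(gc_fraction(gs$ancestor$bases), 0.5)
  for (m in 0:6) {
    snap <- gs$snapshots[[m + 1]]
    expect_true(all(snap$events == m))
    ham <- vapply(snap$bases, function(b) {
      sum(strsplit(b, "")[[1]] != strsplit(gs$ancestor$bases, "")[[1]])
    }, numeric(1))
    expect_true(all(ham <= m)) # reversions can only reduce the distance
  }

  # reproducibility: identical seed and policy give identical runs
  gs2 <- simulate_mutation_lineage(n_seqs = 25, length = 60, iterations = 6,
                                   policy = evening_policy("absolute", 9),
                                   seed = 7)
  expect_identical(gs$snapshots, gs2$snapshots)
})

test_that("population growth doubles each generation, one lineage never mutates", {
  gs <- simulate_population_growth(length = 60, generations = 3, seed = 5)
  expect_equal(vapply(gs$snapshots, nrow, integer(1)), c(1L, 2L, 4L, 8L))
  g1 <- gs$snapshots[[2]]
  expect_equal(sum(g1$bases == gs$ancestor$bases), 1L)
  other <- g1$bases[g1$bases != gs$ancestor$bases]
  expect_equal(sum(strsplit(other, "")[[1]] !=
                     strsplit(gs$ancestor$bases, "")[[1]]), 1L)
  g3 <- gs$snapshots[[4]]
  expect_equal(sum(g3$events == 0), 1L) # exactly one never-mutated copy
  expect_true(all(g3$events <= 3))

  # the multiset of unmutated children equals the parent generation
  g2 <- gs$snapshots[[3]]
  expect_identical(sort(g3$bases[seq(1, 8, by = 2)]), sort(g2$bases))
})

test_that("evening checks pass at the bound and restart beyond it", {
  pol <- evening_policy("absolute", 20)
  expect_true(check_evening(60, 40, pol))  # difference exactly 20 passes
  expect_false(check_evening(61, 39, pol))
  expect_true(check_evening(50, 50, evening_policy("fractional", 0.05)))
  expect_false(check_evening(56, 44, evening_policy("fractional", 0.05)))

  expect_error(evening_policy("absolute", 0.5), "integer")
  expect_error(evening_policy("fractional", 5), "0, 1")

  # an unsatisfiable bound reports attempts and the last imbalance
  tight <- evening_policy("absolute", 1, check_at = "every", max_restarts = 3)
  expect_error(
    simulate_mutation_lineage(n_seqs = 50, length = 30, iterations = 2,
                              policy = tight, seed = 1),
    "3 attempts")

  # returned runs satisfy the policy at the checked snapshot by construction
  gs <- simulate_mutation_lineage(n_seqs = 40, length = 50, iterations = 5,
                                  policy = evening_policy("absolute", 10),
                                  seed = 42)
  final <- tidy(gs)
  expect_true(final$group_diff[nrow(final)] <= 10)
})

test_that("endpoint count is exact arbitrary-precision b^n", {
  expect_equal(endpoint_count(2, 3), "8")
  expect_equal(endpoint_count(4, 2), "16")
  # 4^100, a 61-digit integer, frozen from an independent big-integer oracle
  expect_equal(
    endpoint_count(4, 100),
    "1606938044258990275541962092341162602522202993782792835301376")
  expect_equal(nchar(endpoint_count(4, 100)), 61L)
  expect_error(endpoint_count(1, 5), "b must be")
})

test_that("generation sets serialize to FASTA snapshots plus a manifest", {
  gs <- simulate_population_growth(length = 40, generations = 3, seed = 9)
  dir <- withr::local_tempdir()
  write_generation_set(gs, dir, prefix = "growth")
  expect_true(all(file.exists(file.path(dir, sprintf("growth_%d.fasta", 0:3)))))
  back <- read_fasta(file.path(dir, "growth_3.fasta"))
  expect_equal(back$bases, gs$snapshots[[4]]$bases)
  expect_equal(back$id, gs$snapshots[[4]]$id)
  manifest <- readLines(file.path(dir, "growth_manifest.txt"))
  expect_true(any(grepl("^seed\t9", manifest)))
  expect_true(any(grepl("^3\t8\t", manifest)))
})
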