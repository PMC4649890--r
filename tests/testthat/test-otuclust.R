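test_that("prefix dereplication groups exact prefixes under the longest", {
  recs <- seq_records(c("a_1", "a_2", "a_3"), c("ACGT", "ACGT", "GGGG"))
  d <- dereplicate(recs, "prefix")
  expect_equal(nrow(d), 2L)
  expect_equal(d$abundance[d$seq == "ACGT"], 2L)
  expect_equal(d$abundance[d$seq == "GGGG"], 1L)

  d2 <- dereplicate(seq_records(c("a_1", "a_2"), c("ACGT", "ACGTAA")),
                    "prefix")
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$seq, "ACGTAA")
  expect_equal(d2$abundance, 2L)
  expect_setequal(d2$member_ids[[1L]], c("a_1", "a_2"))
})

test_that("full dereplication merges at gap-ignoring identity 1.0", {
  # ACGT vs ACGGT differ by one indel only -> identity 1.0 -> one derep
  d <- dereplicate(seq_records(c("a_1", "a_2"), c("ACGT", "ACGGT")),
                   "full")
  expect_equal(nrow(d), 1L)
  expect_equal(d$abundance, 2L)
  # a substitution keeps them apart
  d2 <- dereplicate(seq_records(c("a_1", "a_2"), c("ACGTACGT", "ACGAACGT")),
                    "full")
  expect_equal(nrow(d2), 2L)
})

test_that("dereplication conserves reads in both modes", {
  set.seed(41)
  for (mode in c("full", "prefix")) {
    n <- 80L
    base <- replicate(4, random_dna(60))
    recs <- seq_records(sprintf("S%d_%03d", sample(1:2, n, TRUE), 1:n),
                        vapply(sample(base, n, TRUE), function(b) {
                          substr(mutate_seq(b, 0.02), 1,
                                 sample(40:60, 1L))
                        }, character(1L)))
    d <- dereplicate(recs, mode)
    expect_equal(sum(d$abundance), n)
    ids <- unlist(d$member_ids)
    expect_equal(sort(ids), sort(recs$read_id))  # each read exactly once
    expect_equal(d$abundance, lengths(d$member_ids))
    expect_false(is.unsorted(rev(d$abundance)))  # sorted decreasing
  }
})

test_that("search accepts at threshold and stops on the reject counter", {
  set.seed(42)
  seed_seq <- random_dna(100)
  # identity 0.97 (3 substitutions) accepted, 0.80 (20) rejected
  near <- mutate_k(seed_seq, 3L)
  far <- mutate_k(seed_seq, 20L)
  expect_equal(pairwise_identity(global_align(seed_seq, near)), 0.97)
  expect_lte(pairwise_identity(global_align(seed_seq, far)), 0.85)
  db <- make_dereps(c(near, far), c(5L, 4L))
  seed <- make_dereps(seed_seq, 10L, ids = "seed_1")
  got <- search(seed, db, cluster_params())
  expect_equal(got$seq, near)

  # an exact copy is accepted with identity 1
  db2 <- make_dereps(c(seed_seq, far), c(5L, 4L))
  expect_true(seed_seq %in% search(seed, db2, cluster_params())$seq)

  # m+1 consecutive rejections terminate the scan with no accepts
  m <- 5L
  db3 <- make_dereps(replicate(m + 10L, random_dna(100)),
                     rep(1L, m + 10L))
  got3 <- search(seed, db3, cluster_params(reject_limit = m))
  expect_equal(nrow(got3), 0L)
})

test_that("greedy clustering follows abundance seeding and the threshold", {
  set.seed(43)
  a <- random_dna(100)
  b <- mutate_k(a, 2L)            # 98% to a
  c_ <- mutate_k(a, 20L)          # ~80%
  expect_equal(pairwise_identity(global_align(a, b)), 0.98)
  expect_lt(pairwise_identity(global_align(a, c_)), 0.9)
  dereps <- make_dereps(c(a, b, c_), c(5L, 3L, 2L),
                        ids = c("A_1", "B_1", "C_1"))
  cl <- cluster_denovo(dereps, cluster_params())
  expect_equal(nrow(cl$otus), 2L)
  expect_equal(cl$otus$otu_id, c("OTU_1", "OTU_2"))
  expect_equal(cl$otus$centroid_rep_id[1L], "A_1")  # abundance seeds
  expect_setequal(partition_of(cl)[[1L]], c("A_1", "B_1"))

  # two identical dereps collapse into one cluster
  two <- make_dereps(c(a, a), c(3L, 2L), ids = c("X_1", "Y_1"))
  expect_equal(nrow(cluster_denovo(two, cluster_params())$otus), 1L)

  # empty input
  expect_equal(nrow(cluster_denovo(dereps[0, ], cluster_params())$otus),
               0L)
})

test_that("clustering partitions reads exactly once", {
  set.seed(44)
  recs <- local({
    base <- replicate(5, random_dna(80))
    n <- 120L
    seq_records(sprintf("S%d_%03d", sample(1:3, n, TRUE), 1:n),
                vapply(sample(base, n, TRUE), mutate_seq, character(1L),
                       d = 0.01))
  })
  d <- dereplicate(recs, "full")
  cl <- cluster_denovo(d, cluster_params(chimera_filter = FALSE))
  mem <- cluster_membership(cl)
  expect_equal(sort(mem$read_id), sort(recs$read_id))
  expect_equal(sum(cl$otus$n_reads), nrow(recs))
})

test_that("identical input and params give identical clusters", {
  set.seed(45)
  dereps <- make_instance()
  c1 <- cluster_denovo(dereps, cluster_params())
  c2 <- cluster_denovo(dereps, cluster_params())
  expect_identical(c1$otus, c2$otus)
  expect_identical(c1$members, c2$members)
})

test_that("with m = Inf the k-mer scan matches the brute-force greedy", {
  set.seed(46)
  for (i in 1:10) {
    dereps <- make_instance()
    got <- partition_of(cluster_denovo(dereps,
                                       cluster_params(reject_limit = Inf,
                                                      chimera_filter = FALSE)))
    want <- greedy_bruteforce(dereps, 0.97)
    expect_identical(got, want)
  }
})

test_that("reference assignment takes the best hit above threshold", {
  set.seed(47)
  refs <- seq_records(c("R1_1", "R2_1"), replicate(2, random_dna(100)),
                      sample = "ref")
  # exact copy of R1
  recs <- seq_records("q_1", refs$seq[1L])
  got <- assign_reference(recs, refs, cluster_params())
  expect_equal(unname(got), "R1_1")

  # far from everything -> UNASSIGNED
  recs2 <- seq_records("q_2", random_dna(100))
  expect_equal(unname(assign_reference(recs2, refs, cluster_params())),
               "UNASSIGNED")

  # 0.98 to ref1 beats 0.97 to ref2
  base <- random_dna(100)
  r1 <- mutate_k(base, 2L)
  r2 <- mutate_k(base, 3L)
  refs3 <- seq_records(c("R1_1", "R2_1"), c(r1, r2), sample = "ref")
  got3 <- assign_reference(seq_records("q_3", base), refs3,
                           cluster_params())
  expect_equal(unname(got3), "R1_1")
})
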