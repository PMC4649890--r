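make_clusters_fixture <- function(assign) {
  # assign: named list otu -> data.frame(read_id, sample)
  seqs <- vapply(seq_along(assign), function(i) random_dna(60),
                 character(1L))
  dereps <- otukit:::new_derep_set(
    rep_id = paste0("rep", seq_along(assign), "_1"),
    seq = seqs,
    abundance = vapply(assign, nrow, integer(1L)),
    member_ids = lapply(assign, function(df) df$read_id),
    member_samples = lapply(assign, function(df) df$sample))
  structure(list(
    otus = data.frame(otu_id = names(assign),
                      centroid_rep_id = dereps$rep_id,
                      seq = seqs,
                      n_dereps = 1L,
                      n_reads = vapply(assign, nrow, integer(1L)),
                      stringsAsFactors = FALSE),
    members = as.list(seq_along(assign)),
    dereps = dereps,
    params = cluster_params()), class = "otu_clusters")
}

test_that("the OTU table counts reads per sample and OTU", {
  set.seed(61)
  cl <- make_clusters_fixture(list(
    OTU_1 = data.frame(read_id = sprintf("A_%d", 1:5),
                       sample = c("A", "A", "A", "B", "B")),
    OTU_2 = data.frame(read_id = sprintf("C_%d", 1:3),
                       sample = c("C", "C", "C"))))
  tab <- build_otu_table(cl)
  expect_equal(dim(tab$counts), c(3L, 2L))
  expect_equal(unname(rowSums(tab$counts)), c(3, 2, 3))
  expect_equal(unname(tab$counts["C", ]), c(0, 3))
  expect_equal(unname(tab$centroid_map["OTU_1"]), "rep1_1")

  empty <- make_clusters_fixture(list(OTU_1 = data.frame(
    read_id = "x_1", sample = "A")))
  empty$members <- list()
  empty$otus <- empty$otus[0, ]
  expect_equal(dim(build_otu_table(empty)$counts), c(0L, 0L))
})

test_that("rarefy draws exactly depth reads without replacement", {
  counts <- matrix(c(30L, 20L, 10L, 5L, 0L, 5L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), paste0("o", 1:3)))
  tab <- otukit:::new_otu_table(counts)
  r <- rarefy(tab, 10L, seed = 1)
  expect_equal(unname(rowSums(r$counts)), c(10, 10))
  expect_true(all(r$counts <= counts))
  # depth equal to the sample total leaves the row unchanged; the
  # shallower sample is dropped with a warning
  expect_warning(r2 <- rarefy(tab, 60L, seed = 1), "fewer than")
  expect_equal(unname(r2$counts["s1", ]), c(30, 20, 10))
  # determinism
  expect_identical(rarefy(tab, 10L, seed = 7)$counts,
                   rarefy(tab, 10L, seed = 7)$counts)
  expect_error(rarefy(tab, 0L), "depth")
})

test_that("diversity indices match their closed forms", {
  u <- rep(5, 4)
  expect_equal(diversity_index(u, "shannon"), log(4), tolerance = 1e-12)
  expect_equal(diversity_index(u, "simpson"), 0.75, tolerance = 1e-12)
  expect_equal(diversity_index(u, "invsimpson"), 4, tolerance = 1e-12)
  one <- c(7)
  expect_equal(diversity_index(one, "shannon"), 0)
  expect_equal(diversity_index(one, "simpson"), 0)
  expect_equal(diversity_index(one, "invsimpson"), 1)
  expect_equal(diversity_index(c(2, 1, 1), "shannon"),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_error(diversity_index(c(0, 0), "shannon"), "all-zero")
})

test_that("chao1 uses singletons and doubletons with the F2=0 fallback", {
  expect_equal(chao1(c(5, 3, 2)), 3)
  expect_equal(chao1(c(5, 3, 1, 1, 2)), 7)
  expect_equal(chao1(c(1)), 1)
  expect_error(chao1(0), "all-zero")
})

test_that("diversity agrees with vegan on random count vectors", {
  skip_if_not_installed("vegan")
  set.seed(62)
  for (i in 1:20) {
    v <- sample(0:50, sample(3:30, 1L), replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    expect_equal(diversity_index(v, "shannon"),
                 unname(vegan::diversity(v, "shannon")))
    expect_equal(diversity_index(v, "simpson"),
                 unname(vegan::diversity(v, "simpson")))
    expect_equal(diversity_index(v, "invsimpson"),
                 unname(vegan::diversity(v, "invsimpson")))
  }
})

test_that("analytic bounds hold: shannon <= ln S, invsimpson <= S, chao1 >= S", {
  set.seed(63)
  for (i in 1:20) {
    v <- sample(1:40, sample(2:25, 1L), replace = TRUE)
    s <- sum(v > 0)
    expect_lte(diversity_index(v, "shannon"), log(s) + 1e-12)
    expect_lte(diversity_index(v, "invsimpson"), s + 1e-12)
    expect_gte(chao1(v), s)
  }
})

test_that("rarefaction curves behave at the boundary depths", {
  counts <- matrix(c(40L, 30L, 20L, 10L), nrow = 1,
                   dimnames = list("s1", paste0("o", 1:4)))
  tab <- otukit:::new_otu_table(counts)
  rc <- rarefaction_curve(tab, c(1L, 100L), replicates = 1L, seed = 3)
  expect_equal(rc$mean_otus[rc$depth == 1], 1)
  expect_equal(rc$mean_otus[rc$depth == 100], 4)
  rc2 <- rarefaction_curve(tab, c(5L, 20L, 50L, 100L), replicates = 40L,
                           seed = 4)
  expect_true(all(diff(rc2$mean_otus) >= 0))
})

test_that("rarefaction preserves marginal count fractions in expectation", {
  counts <- matrix(c(60L, 30L, 10L), nrow = 1,
                   dimnames = list("s1", paste0("o", 1:3)))
  tab <- otukit:::new_otu_table(counts)
  set.seed(65)
  draws <- replicate(2000, rarefy(tab, 10L)$counts[1L, ])
  est <- rowMeans(draws) / 10
  p <- c(0.6, 0.3, 0.1)
  se <- sqrt(p * (1 - p) / (10 * 2000))  # upper bound on the se of est
  expect_true(all(abs(est - p) < 4 * se))
})
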