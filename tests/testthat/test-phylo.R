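test_that("NJ recovers additive 4-taxon structure exactly", {
  # ((a:1,b:2):1,(c:3,d:1)) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 5
  d["a", "d"] <- d["d", "a"] <- 3
  d["b", "c"] <- d["c", "b"] <- 6
  d["b", "d"] <- d["d", "b"] <- 4
  d["c", "d"] <- d["d", "c"] <- 4
  tr <- nj_tree(d)
  truth <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1));")
  expect_equal(rf_distance(tr, truth), 0)
  # exact branch lengths on an additive matrix
  expect_equal(sort(tr$edge.length), sort(truth$edge.length))
})

test_that("NJ validates its input", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "at least 3")
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3[upper.tri(d3)] <- c(1, 2, 3); d3[lower.tri(d3)] <- c(1, 2, 3)
  d3["b", "a"] <- d3["b", "a"] + 1e-3
  expect_error(nj_tree(d3), "not symmetric")
  d3["b", "a"] <- d3["a", "b"]
  d3["a", "c"] <- d3["c", "a"] <- -1
  expect_error(nj_tree(d3), "negative")
  # 3 taxa resolve to the unique star
  d3["a", "c"] <- d3["c", "a"] <- 2
  expect_equal(length(nj_tree(d3)$tip.label), 3L)
})

test_that("RF distance matches hand-enumerated bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  expect_equal(rf_distance(t1, t1), 0)
  # one NNI away: {d,e} swap to {c,e}
  t2 <- ape::read.tree(text = "((a,b),(d,(c,e)));")
  expect_equal(rf_distance(t1, t2), 2)
  expect_equal(rf_distance(t1, t2, normalize = TRUE), 2 / (2 * (5 - 3)))

  cater <- ape::read.tree(text = "(a,(b,(c,(d,(e,f)))));")
  bal <- ape::read.tree(text = "(((a,b),c),((d,e),f));")
  expect_equal(rf_distance(cater, bal), oracle_rf(cater, bal))

  t3 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_error(rf_distance(t1, t3), "different leaf sets")
})

test_that("pair incompatibility generalizes the four-gamete test", {
  # 3 of 4 gametes: compatible
  expect_equal(pair_incompatibility(c("A", "A", "T", "T"),
                                    c("A", "A", "A", "T")), 0)
  # all 4 gametes present
  expect_equal(pair_incompatibility(c("A", "A", "T", "T"),
                                    c("A", "T", "A", "T")), 1)
  # gapped taxa are dropped pair-wise
  expect_equal(pair_incompatibility(c("A", "A", "T", "T", "-"),
                                    c("A", "T", "A", "T", "C")), 1)
  expect_error(pair_incompatibility(c("A", "-"), c("A", "C")), "fewer than 2 taxa")
})

test_that("incompatibility equals the exhaustive minimal-homoplasy oracle", {
  withr::local_seed(19)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    taxa <- paste0("t", seq_len(n))
    col_i <- setNames(sample(c("A", "C", "G"), n, replace = TRUE), taxa)
    col_j <- setNames(sample(c("A", "C", "T"), n, replace = TRUE), taxa)
    expect_equal(pair_incompatibility(col_i, col_j),
                 oracle_pair_incompat(col_i, col_j),
                 info = paste(paste(col_i, collapse = ""), "/",
                              paste(col_j, collapse = "")))
  }
})

# nested clades -> every site fits one tree with a single change
homoplasy_free_alignment <- function() {
  taxa <- paste0("t", 1:6)
  site_for_clade <- function(members) {
    ifelse(taxa %in% members, "T", "A")
  }
  clades <- list(c("t1", "t2"), c("t1", "t2", "t3"), c("t5", "t6"),
                 c("t4", "t5", "t6"), c("t1", "t2"), c("t5", "t6"))
  cols <- do.call(cbind, lapply(clades, site_for_clade))
  rows <- apply(cols, 1, paste, collapse = "")
  gene_alignment("hf", setNames(rows, taxa))
}

test_that("PHI is null on homoplasy-free alignments and reproducible", {
  aln <- homoplasy_free_alignment()
  res <- phi_test(aln, n_permutations = 200, seed = 3)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res2 <- phi_test(aln, n_permutations = 200, seed = 3)
  expect_identical(res$p_value, res2$p_value)

  # taxon order invariance of the statistic
  perm <- sample(names(aln$seqs))
  aln_perm <- gene_alignment("hf", aln$seqs[perm])
  expect_equal(phi_test(aln_perm, n_permutations = 50, seed = 1)$statistic,
               res$statistic)
})

test_that("PHI handles degenerate alignments gracefully", {
  aln <- gene_alignment("mono", setNames(rep(strrep("ACGT", 5), 4), paste0("t", 1:4)))
  res <- phi_test(aln)
  expect_true(is.na(res$p_value))
  expect_match(res$status, "informative")
  expect_error(phi_test(gene_alignment("g", c(a = "ACGT", b = "ACGT", c = "ACGT"))),
               ">= 4 sequences")
})

test_that("PHI detects a two-topology recombinant concatenate", {
  t1 <- ape::read.tree(text = "(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)));")
  t2 <- ape::read.tree(text = "(((t1,t5),(t3,t7)),((t2,t6),(t4,t8)));")
  g1 <- simulate_on_tree(t1, 400, branch_p = 0.06, seed = 201)
  g2 <- simulate_on_tree(t2, 400, branch_p = 0.06, seed = 202)
  conc <- concatenate_alignments(list(a = g1, b = g2), order = c("a", "b"))
  res <- phi_test(conc, window_w = 40, n_permutations = 500, seed = 5)
  expect_lt(res$p_value, 0.05)

  # single-topology control with the same depth is not flagged
  g3 <- simulate_on_tree(t1, 400, branch_p = 0.06, seed = 203)
  conc2 <- concatenate_alignments(list(a = g1, b = g3), order = c("a", "b"))
  res2 <- phi_test(conc2, window_w = 40, n_permutations = 500, seed = 5)
  expect_gt(res2$p_value, 0.05)
})
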