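test_that("classify_pairs applies the 94/96 rule with closed boundaries", {
  pairs <- tibble::tibble(
    id_a = letters[1:5], id_b = LETTERS[1:5],
    anistt = c(99.51, 93.86, 95.5, 94.0, 96.0),
    anim = c(NA, NA, 94.15, NA, NA))
  out <- classify_pairs(pairs)
  expect_equal(out$category,
               c("intra", "inter", "intermediate", "inter", "intra"))
  expect_equal(out$region_2d[3], "between")
  expect_error(classify_pairs(tibble::tibble(id_a = "a", id_b = "b", anistt = 101)),
               "\\[0,100\\]")
})

test_that("the three categories partition [0,100] and are monotone in ANIstt", {
  x <- sort(c(94, 96, round(runif(200, 0, 100), 3)))
  out <- classify_pairs(tibble::tibble(id_a = "a", id_b = "b", anistt = x))
  expect_true(all(out$category %in% c("intra", "inter", "intermediate")))
  ord <- c(inter = 1, intermediate = 2, intra = 3)
  expect_true(all(diff(ord[out$category]) >= 0))
})

test_that("2D regions follow the strict scatter inequalities", {
  pairs <- tibble::tibble(id_a = "q", id_b = "r",
                          anim = c(96, 92, 94.15, 93, 95),
                          anistt = c(97, 93, 95.5, 93.9, 96.5))
  out <- classify_pairs(pairs)
  expect_equal(out$region_2d,
               c("intra-region", "inter-region", "between", "between", "between"))
})

test_that("audit counts supported pairs and finds merge components", {
  labels <- tibble::tibble(strain_id = c("t1", "t2", "t3"),
                           species = c("s1", "s2", "s3"),
                           is_type_strain = TRUE)
  tab <- ani_tbl(tibble::tibble(id_a = c("t1", "t1", "t2"),
                                id_b = c("t2", "t3", "t3"),
                                ani = c(88, 90, 89.5)), source = "concatenate")
  res <- audit_type_strains(tab, labels)
  expect_equal(res$n_inter_pairs, 3L)
  expect_equal(res$n_below_inter_ceiling, 3L)
  expect_equal(res$n_below_intra_floor, 3L)
  expect_length(res$merge_candidates, 0)

  tab2 <- ani_tbl(tibble::tibble(id_a = c("t1", "t1", "t2"),
                                 id_b = c("t2", "t3", "t3"),
                                 ani = c(97.8, 90, 89.5)), source = "concatenate")
  res2 <- audit_type_strains(tab2, labels)
  expect_equal(res2$n_below_inter_ceiling, 2L)
  expect_length(res2$merge_candidates, 1)
  expect_setequal(res2$merge_candidates[[1]], c("s1", "s2"))

  labels_dup <- labels
  labels_dup$species[2] <- "s1"
  expect_error(audit_type_strains(tab, labels_dup), "duplicate species")
})

test_that("audit counts equal a brute-force recount on random panels", {
  withr::local_seed(55)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    labels <- tibble::tibble(strain_id = sprintf("t%d", 1:n),
                             species = sprintf("s%d", 1:n),
                             is_type_strain = TRUE)
    pairs <- t(utils::combn(labels$strain_id, 2))
    tab <- ani_tbl(tibble::tibble(id_a = pairs[, 1], id_b = pairs[, 2],
                                  ani = round(runif(nrow(pairs), 85, 99), 2)),
                   source = "concatenate")
    res <- audit_type_strains(tab, labels)
    expect_equal(res$n_below_inter_ceiling, sum(tab$ani < 94))
    expect_equal(res$n_below_intra_floor, sum(tab$ani < 96))
    # merge components by brute-force transitive closure
    high <- tab[tab$ani >= 96, ]
    expect_equal(sum(lengths(res$merge_candidates)),
                 length(unique(c(high$id_a, high$id_b))))
  }
})

make_ref_panel <- function() {
  withr::local_seed(61)
  genes <- c("SMc00019", "truA", "thrA")
  ids <- c("T_alpha", "T_beta", "T_gamma")
  base <- lapply(genes, function(g) random_alignment_seqs(1, 300, ids = "r",
                                                          gap_prob = 0, amb_prob = 0)[[1]])
  names(base) <- genes
  mutate_frac <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq_len(k)
    ch[idx] <- ifelse(ch[idx] == "A", "G", "A")
    paste(ch, collapse = "")
  }
  alns <- lapply(genes, function(g) {
    gene_alignment(g, c(
      T_alpha = base[[g]],
      T_beta = mutate_frac(base[[g]], 30),    # ~90% vs alpha
      T_gamma = mutate_frac(base[[g]], 60)))  # ~80% vs alpha
  })
  labels <- tibble::tibble(strain_id = ids,
                           species = c("alpha", "beta", "gamma"),
                           is_type_strain = TRUE)
  strain_panel(labels, alignments = alns)
}

test_that("assign_strain applies the 94/96 verdict rule", {
  panel <- make_ref_panel()
  q_genes <- sapply(panel$alignments, function(a) a$seqs[["T_alpha"]])
  res <- assign_strain(q_genes, panel, query_id = "query1")
  expect_equal(res$verdict, "assigned(alpha)")
  expect_equal(res$best_anistt, 100)
  expect_equal(res$best_type_strain, "T_alpha")
  expect_equal(nrow(res$all_scores), 3L)
  expect_equal(max(res$all_scores$anistt), res$best_anistt)

  # scatter 15 substitutions per 300 bp gene (~95%): ambiguous zone
  mut <- vapply(q_genes, function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq(10, 290, by = 20)
    ch[idx] <- ifelse(ch[idx] == "C", "T", "C")
    paste(ch, collapse = "")
  }, character(1))
  res2 <- assign_strain(mut, panel, query_id = "query2")
  expect_equal(res2$verdict, "ambiguous(intermediate)")

  # ~88% of everything: novel species candidate
  far <- vapply(q_genes, function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq(1, length(ch), by = 4)
    ch[idx] <- ifelse(ch[idx] == "G", "T", "G")
    paste(ch, collapse = "")
  }, character(1))
  res3 <- assign_strain(far, panel, query_id = "query3")
  expect_equal(res3$verdict, "novel-species-candidate")
  expect_lte(res3$best_anistt, 94)

  expect_error(assign_strain(q_genes[1:2][c()], panel), "named by gene")
  expect_error(assign_strain(c(nope = "ACGT"), panel), "lacks gene")
})

test_that("a type strain assigned to another species is flagged as later synonym", {
  panel <- make_ref_panel()
  # make beta's type strain nearly identical to alpha's (conspecific pair)
  for (g in names(panel$alignments)) {
    s <- panel$alignments[[g]]$seqs
    s[["T_beta"]] <- s[["T_alpha"]]
    panel$alignments[[g]] <- gene_alignment(g, s)
  }
  q <- sapply(panel$alignments, function(a) a$seqs[["T_beta"]])
  res <- assign_strain(q, panel, query_id = "T_beta")
  expect_equal(res$verdict, "assigned(alpha)")
  expect_equal(res$flags, "later-synonym-candidate")
  # the query never scores against itself
  expect_false("T_beta" %in% res$all_scores$type_strain)
})
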