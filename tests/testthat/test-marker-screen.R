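labels3 <- tibble::tibble(strain_id = c("a", "b", "c"),
                          species = c("x", "x", "y"),
                          is_type_strain = FALSE)

test_that("species_relation joins labels case-insensitively", {
  labs <- tibble::tibble(strain_id = c("a", "b", "c"),
                         species = c("Rhizobium etli", "rhizobium ETLI ", "R. fabae"))
  expect_equal(species_relation(labs, "a", "b"), "intra")
  expect_equal(species_relation(labs, "a", "c"), "inter")
  expect_error(species_relation(labs, "a", "zz"), "unlabeled")
})

test_that("gap_statistic reports min-intra, max-inter and violations", {
  tab <- ani_tbl(tibble::tibble(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                                ani = c(97, 90, 91)), source = "gene:g")
  g <- gap_statistic(tab, labels3)
  expect_equal(g$min_intra, 97)
  expect_equal(g$max_inter, 91)
  expect_equal(g$gap, 6)
  expect_equal(nrow(g$violating_pairs), 0L)

  tab2 <- ani_tbl(tibble::tibble(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                                 ani = c(97, 95.5, 91)), source = "gene:g")
  g2 <- gap_statistic(tab2, labels3)
  expect_equal(nrow(g2$violating_pairs), 1L)
  expect_equal(g2$violating_pairs$ani, 95.5)
  expect_equal(g2$violating_pairs$expected_relation, "inter")

  one_sp <- tibble::tibble(strain_id = c("a", "b", "c"), species = "x")
  expect_error(gap_statistic(tab, one_sp), "no inter-species pairs")
})

test_that("gap_statistic equals an exhaustive scan on random panels", {
  withr::local_seed(77)
  for (rep in 1:20) {
    pan <- random_labeled_panel(sample(4:8, 1), sample(2:3, 1))
    rel <- with(pan$labels, setNames(species, strain_id))
    is_intra <- rel[pan$table$id_a] == rel[pan$table$id_b]
    if (!any(is_intra) || all(is_intra)) next
    g <- gap_statistic(pan$table, pan$labels)
    expect_equal(g$min_intra, min(pan$table$ani[is_intra]))
    expect_equal(g$max_inter, max(pan$table$ani[!is_intra]))
    cfg <- threshold_config()
    n_viol <- sum(is_intra & pan$table$ani < cfg$intra_floor) +
      sum(!is_intra & pan$table$ani > cfg$inter_ceiling)
    expect_equal(nrow(g$violating_pairs), n_viol)
  }
})

test_that("boundary_concordance finds the smallest working boundary", {
  gene <- ani_tbl(tibble::tibble(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                                 ani = c(97.5, 91, 92)), source = "gene:g")
  genome <- ani_tbl(tibble::tibble(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                                   ani = c(98, 90, 90)), source = "genome")
  res <- boundary_concordance(gene, genome)
  expect_true(res$concordant)
  expect_equal(res$chosen_boundary, 95)

  gene2 <- ani_tbl(tibble::tibble(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                                  ani = c(97.5, 96.5, 92)), source = "gene:g")
  res2 <- boundary_concordance(gene2, genome)
  expect_false(res2$concordant)
  expect_true(is.na(res2$chosen_boundary))
  expect_equal(res2$mismatches$gene_ani, 96.5)

  # a pair resolvable only at the higher candidate boundary
  gene3 <- ani_tbl(tibble::tibble(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                                  ani = c(97.5, 95.5, 92)), source = "gene:g")
  res3 <- boundary_concordance(gene3, genome)
  expect_true(res3$concordant)
  expect_equal(res3$chosen_boundary, 96)

  bad <- ani_tbl(tibble::tibble(id_a = "a", id_b = "b", ani = 97), source = "genome")
  expect_error(boundary_concordance(gene, bad), "same strain pairs")
})

test_that("removing a mismatching pair never breaks concordance (monotonicity)", {
  withr::local_seed(90)
  for (rep in 1:20) {
    pan <- random_labeled_panel(6, 2)
    genome <- pan$table
    gene <- ani_tbl(dplyr::mutate(pan$table, ani = pmin(100, pmax(0, ani + rnorm(nrow(pan$table), 0, 3)))),
                    source = "gene:g")
    res <- boundary_concordance(gene, genome)
    if (nrow(res$mismatches) == 0) next
    drop_key <- paste(res$mismatches$id_a[1], res$mismatches$id_b[1])
    keep <- paste(gene$id_a, gene$id_b) != drop_key
    res2 <- boundary_concordance(gene[keep, ], genome[keep, ])
    expect_lte(nrow(res2$mismatches), nrow(res$mismatches) - 1)
    if (res$concordant) expect_true(res2$concordant)
  }
})

make_screen_panel <- function() {
  # 4 strains, 2 species; intra pairs identical, inter pairs ~10% divergent
  base <- strrep("ACGT", 25)                     # 100 bp
  div <- paste(c(rep("T", 10), strsplit(strrep("ACGT", 25), "")[[1]][-(1:10)]),
               collapse = "")
  seqs_short <- c(a1 = base, a2 = base, b1 = div, b2 = div)
  seqs_long <- vapply(seqs_short, function(s) strrep(s, 2), character(1))
  labels <- tibble::tibble(strain_id = names(seqs_short),
                           species = c("A", "A", "B", "B"),
                           is_type_strain = FALSE)
  genome <- ani_tbl(tibble::tibble(
    id_a = c("a1", "a1", "a1", "a2", "a2", "b1"),
    id_b = c("a2", "b1", "b2", "b1", "b2", "b2"),
    ani = c(99.5, 88, 88, 88, 88, 99.5)), source = "genome")
  list(labels = labels, seqs_short = seqs_short, seqs_long = seqs_long,
       genome = genome)
}

test_that("screen_markers ranks by concordance, gap, then length", {
  p <- make_screen_panel()
  panel <- strain_panel(p$labels, alignments = list(
    gene_alignment("long", p$seqs_long),
    gene_alignment("short", p$seqs_short)))
  rep <- screen_markers(panel, p$genome)
  expect_s3_class(rep, "marker_report")
  # identical ANI structure, so the shorter gene wins the length tie-break
  expect_equal(rep$gene[rep$rank == 1], "short")
  expect_true(all(rep$concordant))
  expect_equal(rep$length_bp, c(100L, 200L))

  # single gene: rank 1 and a complete report
  solo <- strain_panel(p$labels,
                       alignments = list(gene_alignment("short", p$seqs_short)))
  rep1 <- screen_markers(solo, p$genome)
  expect_equal(rep1$rank, 1L)
  expect_equal(rep1$status, "ok")
})

test_that("screening is invariant to gene input order", {
  p <- make_screen_panel()
  a <- gene_alignment("long", p$seqs_long)
  b <- gene_alignment("short", p$seqs_short)
  r1 <- screen_markers(strain_panel(p$labels, alignments = list(a, b)), p$genome)
  r2 <- screen_markers(strain_panel(p$labels, alignments = list(b, a)), p$genome)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("a gene whose statistics fail is screened out with a reason", {
  p <- make_screen_panel()
  broken <- p$seqs_short
  broken[["b1"]] <- strrep("-", 100)   # no compared sites vs anything
  panel <- strain_panel(p$labels, alignments = list(
    gene_alignment("ok", p$seqs_short),
    gene_alignment("broken", broken)))
  rep <- screen_markers(panel, p$genome)
  expect_equal(nrow(rep), 2L)
  expect_match(rep$status[rep$gene == "broken"], "screened-out")
  expect_equal(rep$gene[rep$rank == 1], "ok")
})

test_that("gene length excludes all-gap columns", {
  aln <- gene_alignment("g", c(a = "AC--GT", b = "AG--GT"))
  expect_equal(aniscreen:::ungapped_length(aln), 4L)
})
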