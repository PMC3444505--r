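#' Species-boundary threshold configuration
#'
#' Bundles the ANI boundaries used throughout screening and classification.
#' Defaults are the boundaries for rhizobial species: genome ANI >= 95%
#' means same species; candidate gene-ANI boundaries 95% and 96%; the
#' concatenate classifier uses the observed extremes (highest interspecies
#' ANIstt 94%, lowest intraspecies ANIstt 96%); the two-dimensional scatter
#' regions use ANIm 93/95 with ANIstt 94/96 (strict inequalities).
#'
#' @param genome_species_boundary Genome ANI same-species boundary (percent).
#' @param candidate_gene_boundaries Candidate gene-ANI boundaries tried by
#'   [boundary_concordance()].
#' @param intra_floor Lowest intraspecies concatenate ANI (percent).
#' @param inter_ceiling Highest interspecies concatenate ANI (percent).
#' @param region_genome_low,region_genome_high Genome-ANI bounds of the
#'   interspecies / intraspecies scatter regions.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(genome_species_boundary = 95,
                             candidate_gene_boundaries = c(95, 96),
                             intra_floor = 96, inter_ceiling = 94,
                             region_genome_low = 93, region_genome_high = 95) {
  stopifnot(inter_ceiling < intra_floor,
            region_genome_low < region_genome_high,
            all(c(genome_species_boundary, candidate_gene_boundaries,
                  intra_floor, inter_ceiling,
                  region_genome_low, region_genome_high) > 0),
            all(c(genome_species_boundary, candidate_gene_boundaries,
                  intra_floor, inter_ceiling,
                  region_genome_low, region_genome_high) < 100))
  structure(list(genome_species_boundary = genome_species_boundary,
                 candidate_gene_boundaries = sort(unique(candidate_gene_boundaries)),
                 intra_floor = intra_floor, inter_ceiling = inter_ceiling,
                 region_genome_low = region_genome_low,
                 region_genome_high = region_genome_high),
            class = "threshold_config")
}

#' Intra- vs inter-species relation of strain pairs
#'
#' @param labels Tibble with `strain_id` and `species` columns.
#' @param id_a,id_b Strain ids (vectorized).
#' @return Character vector, `"intra"` where the species labels match
#'   (case-insensitive, trimmed), `"inter"` otherwise.
#' @export
species_relation <- function(labels, id_a, id_b) {
  key <- stats::setNames(tolower(trimws(labels$species)), labels$strain_id)
  miss <- setdiff(unique(c(id_a, id_b)), names(key))
  if (length(miss)) stop("unlabeled strain id(s): ", paste(miss, collapse = ", "))
  unname(ifelse(key[id_a] == key[id_b], "intra", "inter"))
}

#' ANI gap between intra- and inter-species comparisons
#'
#' Computes the margin between the lowest intraspecies ANI and the highest
#' interspecies ANI in a pair table (the "ANI gap"), and lists pairs that
#' violate the configured boundaries (intraspecies pairs below `intra_floor`,
#' interspecies pairs above `inter_ceiling`).
#'
#' @param table An [ani_tbl()] (or tibble with `id_a`, `id_b`, `ani`).
#' @param labels Strain label table (`strain_id`, `species`).
#' @param cfg A [threshold_config()].
#' @return A `gap_report`: list with `source`, `min_intra`, `max_inter`,
#'   `gap` and `violating_pairs` (tibble `id_a`, `id_b`, `ani`,
#'   `expected_relation`).
#' @export
gap_statistic <- function(table, labels, cfg = threshold_config()) {
  rel <- species_relation(labels, table$id_a, table$id_b)
  if (any(is.na(table$ani))) stop("table contains pairs with undefined ANI")
  if (!any(rel == "intra")) stop("no intra-species pairs in table")
  if (!any(rel == "inter")) stop("no inter-species pairs in table")
  min_intra <- min(table$ani[rel == "intra"])
  max_inter <- max(table$ani[rel == "inter"])
  viol <- tibble(id_a = table$id_a, id_b = table$id_b, ani = table$ani,
                 expected_relation = rel)
  viol <- viol[(rel == "intra" & viol$ani < cfg$intra_floor) |
                 (rel == "inter" & viol$ani > cfg$inter_ceiling), ]
  structure(list(source = attr(table, "source") %||% NA_character_,
                 min_intra = min_intra, max_inter = max_inter,
                 gap = min_intra - max_inter, violating_pairs = viol),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report> source:", x$source, "\n  min intra ANI:",
      format(x$min_intra, digits = 6), " max inter ANI:",
      format(x$max_inter, digits = 6), " gap:", format(x$gap, digits = 6), "\n ",
      nrow(x$violating_pairs), "boundary-violating pair(s)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boundary concordance of a gene with genome-level species assignments
#'
#' A gene is concordant when some candidate boundary t exists such that for
#' every strain pair, `gene ANI >= t` agrees with the genome-level call
#' (`genome ANI >= genome_species_boundary`, same-species closed at the
#' boundary). The chosen boundary is the smallest satisfying candidate;
#' when no candidate works, the mismatching pairs at the best candidate
#' (fewest mismatches, ties to the smaller t) are reported.
#'
#' @param gene_table,genome_table [ani_tbl()] objects covering the same pairs.
#' @param labels Strain label table (used only to annotate mismatches).
#' @param cfg A [threshold_config()].
#' @return List with `concordant`, `chosen_boundary` (`NA` if none) and
#'   `mismatches` (tibble `id_a`, `id_b`, `gene_ani`, `genome_ani`,
#'   `genome_same_species`).
#' @export
boundary_concordance <- function(gene_table, genome_table, labels = NULL,
                                 cfg = threshold_config()) {
  key <- function(t) paste(pmin(t$id_a, t$id_b), pmax(t$id_a, t$id_b), sep = "\r")
  kg <- key(gene_table); km <- key(genome_table)
  if (!setequal(kg, km) || anyDuplicated(kg) || anyDuplicated(km)) {
    stop("gene and genome tables do not cover the same strain pairs")
  }
  genome_ani <- genome_table$ani[match(kg, km)]
  if (any(is.na(genome_ani)) || any(is.na(gene_table$ani))) {
    stop("tables contain pairs with undefined ANI")
  }
  genome_same <- genome_ani >= cfg$genome_species_boundary
  cands <- cfg$candidate_gene_boundaries
  n_mis <- vapply(cands, function(t) sum((gene_table$ani >= t) != genome_same),
                  numeric(1))
  best_i <- which.min(n_mis)      # ties resolve to the smaller boundary
  ok <- n_mis == 0
  chosen <- if (any(ok)) cands[which(ok)[1]] else NA_real_
  best_t <- if (any(ok)) chosen else cands[best_i]
  mis_idx <- which((gene_table$ani >= best_t) != genome_same)
  mismatches <- tibble(id_a = gene_table$id_a[mis_idx],
                       id_b = gene_table$id_b[mis_idx],
                       gene_ani = gene_table$ani[mis_idx],
                       genome_ani = genome_ani[mis_idx],
                       genome_same_species = genome_same[mis_idx])
  list(concordant = any(ok), chosen_boundary = chosen, mismatches = mismatches)
}

# Alignment length excluding columns that are gaps in every row ("<1.5 kb"
# refers to gene length, not gapped alignment width).
ungapped_length <- function(aln) {
  gap_rows <- vapply(aln$seqs,
                     function(s) utf8ToInt(s) == utf8ToInt("-"),
                     logical(aln$length))
  sum(!apply(gap_rows, 1, all))
}

#' Screen candidate marker genes against genome-level species structure
#'
#' For every gene alignment in the panel, computes the gene ANI table, its
#' boundary concordance with the genome table, the ANI gap, gene length
#' (all-gap columns excluded) and, when a reference tree is supplied, the
#' normalized Robinson-Foulds distance of the gene's neighbor-joining tree
#' to that reference. Genes are ranked by concordance (concordant first),
#' then descending gap, ascending RF distance, ascending length, with gene
#' name as the deterministic final tie-break. A gene whose statistics cannot
#' be computed is reported as screened-out with its reason, never dropped.
#'
#' @param panel A [strain_panel()] with gene alignments.
#' @param genome_table Genome [ani_tbl()] covering the panel pairs.
#' @param cfg A [threshold_config()].
#' @param max_len_bp Length cut-off used to flag markers short enough for
#'   amplicon work (default 1500).
#' @param ref_tree Optional [ape::phylo] reference species tree.
#' @return A `marker_report` tibble: `gene`, `length_bp`, `len_ok`,
#'   `concordant`, `chosen_boundary`, `min_intra`, `max_inter`, `gap`,
#'   `n_mismatches`, `rf_dist`, `status`, `rank`.
#' @export
screen_markers <- function(panel, genome_table, cfg = threshold_config(),
                           max_len_bp = 1500, ref_tree = NULL) {
  if (!length(panel$alignments)) stop("panel has no gene alignments")
  labels <- panel$strains
  rows <- lapply(panel$alignments, function(aln) {
    gene <- aln$gene_name
    res <- tryCatch({
      gt <- gene_ani_table(aln)
      conc <- boundary_concordance(gt, genome_table, labels, cfg)
      gap <- gap_statistic(gt, labels, cfg)
      rf <- NA_real_
      if (!is.null(ref_tree)) {
        gtree <- nj_tree(100 - ani_matrix(gt))
        rf <- rf_distance(gtree, ref_tree, normalize = TRUE)
      }
      len <- ungapped_length(aln)
      tibble(gene = gene, length_bp = len, len_ok = len <= max_len_bp,
             concordant = conc$concordant,
             chosen_boundary = conc$chosen_boundary,
             min_intra = gap$min_intra, max_inter = gap$max_inter,
             gap = gap$gap, n_mismatches = nrow(conc$mismatches),
             rf_dist = rf, status = "ok")
    }, error = function(e) {
      tibble(gene = gene, length_bp = ungapped_length(aln), len_ok = NA,
             concordant = FALSE, chosen_boundary = NA_real_,
             min_intra = NA_real_, max_inter = NA_real_, gap = NA_real_,
             n_mismatches = NA_integer_, rf_dist = NA_real_,
             status = paste0("screened-out: ", conditionMessage(e)))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  ord <- order(out$status != "ok",              # failures last
               !out$concordant,                  # concordant first
               -ifelse(is.na(out$gap), -Inf, out$gap),
               ifelse(is.na(out$rf_dist), Inf, out$rf_dist),
               out$length_bp,
               out$gene, method = "radix")
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("marker_report", class(out))
  out
}
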