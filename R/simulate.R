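#' Simulation configuration for synthetic strain panels
#'
#' Describes a clade of genomes with known species structure: a star species
#' tree whose species ancestors sit at depths drawn from half the
#' inter-species pairwise divergence range (so species-pair divergences land
#' inside the configured range), strains at depths drawn from half the
#' intra-species range, core genes evolved with gene-specific rate
#' multipliers under a uniform (Jukes-Cantor-like) substitution model,
#' optional inter-lineage gene transfer, and intergenic filler evolved at
#' rate 1. No indels are simulated, so realized divergences are exact.
#'
#' @param n_species Number of species.
#' @param strains_per_species Strains per species.
#' @param intra_divergence Per-site pairwise divergence range within species.
#' @param inter_divergence Per-site pairwise divergence range between species.
#' @param n_genes Number of core genes.
#' @param gene_length Gene length range in bp.
#' @param gene_rate_multipliers Per-gene rate multipliers, recycled to
#'   `n_genes`.
#' @param n_transfer_events Number of inter-species gene transfer events.
#' @param transfer_genes Indices of genes eligible for transfer (default all
#'   genes). When `n_transfer_events` is at least the number of eligible
#'   genes, every eligible gene receives at least one event.
#' @param genome_filler_bp Intergenic filler length added to each genome.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 5L, strains_per_species = 3L,
                       intra_divergence = c(0.00, 0.03),
                       inter_divergence = c(0.06, 0.20),
                       n_genes = 3L, gene_length = c(800L, 1200L),
                       gene_rate_multipliers = 1,
                       n_transfer_events = 0L, transfer_genes = NULL,
                       genome_filler_bp = 10000L, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_species >= 1, strains_per_species >= 1,
            length(intra_divergence) == 2, length(inter_divergence) == 2,
            diff(intra_divergence) >= 0, diff(inter_divergence) >= 0,
            all(intra_divergence >= 0), all(inter_divergence >= 0),
            n_genes >= 1, length(gene_length) == 2, gene_length[1] >= 1,
            all(gene_rate_multipliers >= 0), n_transfer_events >= 0,
            genome_filler_bp >= 0)
  if (n_transfer_events > 0 && n_species < 2) stop("transfers need >= 2 species")
  rates <- rep_len(gene_rate_multipliers, n_genes)
  if (is.null(transfer_genes)) transfer_genes <- seq_len(n_genes)
  stopifnot(all(transfer_genes %in% seq_len(n_genes)))
  structure(list(n_species = as.integer(n_species),
                 strains_per_species = as.integer(strains_per_species),
                 intra_divergence = intra_divergence,
                 inter_divergence = inter_divergence,
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 gene_rate_multipliers = rates,
                 n_transfer_events = as.integer(n_transfer_events),
                 transfer_genes = as.integer(transfer_genes),
                 genome_filler_bp = as.integer(genome_filler_bp),
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Uniform substitution: each site mutates with probability p to a uniformly
# chosen different base.
mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(alt[[b]], 1L), character(1),
                         USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Simulate a strain panel with known divergence truth
#'
#' Generates species and strain sequences per [sim_config()], applies any
#' transfer events (replacing the recipient strain's gene with the donor's
#' copy), assembles genomes as the gene concatenation plus filler, and logs
#' the realized (not nominal) pairwise divergences from the final sequences,
#' so [expected_ani()] is exact.
#'
#' @param cfg A [sim_config()].
#' @return List with `panel` (a [strain_panel()] with aligned genes and
#'   genomes) and `truth` (a `sim_truth`: `divergence` tibble with `id_a`,
#'   `id_b`, `scope` (`"genome"` or a gene name), `divergence`, `sites`;
#'   `labels`; `transfers` tibble; `gene_rates`; `config`).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  n_sp <- cfg$n_species
  n_st <- cfg$strains_per_species
  gene_names <- sprintf("gene%02d", seq_len(cfg$n_genes))
  gene_lens <- as.integer(round(runif_range(cfg$n_genes, cfg$gene_length)))
  sp_depth <- runif_range(n_sp, cfg$inter_divergence) / 2
  labels <- tibble(
    strain_id = sprintf("sp%02d_st%02d", rep(seq_len(n_sp), each = n_st),
                        rep(seq_len(n_st), n_sp)),
    species = sprintf("species%02d", rep(seq_len(n_sp), each = n_st)),
    is_type_strain = rep(seq_len(n_st), n_sp) == 1L
  )
  strain_depth <- runif_range(n_sp * n_st, cfg$intra_divergence) / 2
  evolve_block <- function(len, rate) {
    root <- random_seq(len)
    anc <- vapply(seq_len(n_sp),
                  function(s) mutate_seq(root, min(sp_depth[s] * rate, 0.75)),
                  character(1))
    vapply(seq_len(n_sp * n_st), function(i) {
      s <- (i - 1) %/% n_st + 1
      mutate_seq(anc[s], min(strain_depth[i] * rate, 0.75))
    }, character(1))
  }
  genes <- lapply(seq_len(cfg$n_genes), function(g) {
    stats::setNames(evolve_block(gene_lens[g], cfg$gene_rate_multipliers[g]),
                    labels$strain_id)
  })
  names(genes) <- gene_names
  # transfer events: replace recipient's gene copy with the donor's
  transfers <- tibble(gene = character(0), donor = character(0),
                      recipient = character(0))
  if (cfg$n_transfer_events > 0) {
    elig <- cfg$transfer_genes
    g_seq <- if (cfg$n_transfer_events >= length(elig)) {
      c(elig, elig[sample.int(length(elig), cfg$n_transfer_events - length(elig),
                              replace = TRUE)])
    } else {
      elig[sample.int(length(elig), cfg$n_transfer_events)]
    }
    for (g in g_seq) {
      donor <- sample(labels$strain_id, 1L)
      donor_sp <- labels$species[labels$strain_id == donor]
      recipient <- sample(labels$strain_id[labels$species != donor_sp], 1L)
      genes[[g]][recipient] <- genes[[g]][[donor]]
      transfers <- dplyr::bind_rows(transfers, tibble(
        gene = gene_names[g], donor = donor, recipient = recipient))
    }
  }
  filler <- if (cfg$genome_filler_bp > 0) {
    stats::setNames(evolve_block(cfg$genome_filler_bp, 1), labels$strain_id)
  } else NULL
  genomes <- vapply(labels$strain_id, function(id) {
    paste(c(vapply(genes, function(g) g[[id]], character(1)),
            if (!is.null(filler)) filler[[id]]), collapse = "")
  }, character(1))
  alignments <- lapply(gene_names, function(gn) gene_alignment(gn, genes[[gn]]))
  names(alignments) <- gene_names
  panel <- strain_panel(labels, alignments = alignments, genomes = genomes)
  # realized divergence truth from the final sequences
  idx <- utils::combn(labels$strain_id, 2)
  div_block <- function(seqs, scope) {
    stats <- lapply(seq_len(ncol(idx)), function(k) {
      d <- gene_pair_diff(seqs[[idx[1, k]]], seqs[[idx[2, k]]])
      tibble(id_a = idx[1, k], id_b = idx[2, k], scope = scope,
             divergence = d$diffs / d$sites, sites = d$sites)
    })
    dplyr::bind_rows(stats)
  }
  truth_div <- dplyr::bind_rows(
    div_block(as.list(genomes), "genome"),
    dplyr::bind_rows(lapply(gene_names, function(gn) div_block(as.list(genes[[gn]]), gn)))
  )
  truth <- structure(list(divergence = truth_div, labels = labels,
                          transfers = transfers,
                          gene_rates = stats::setNames(cfg$gene_rate_multipliers,
                                                       gene_names),
                          config = cfg),
                     class = "sim_truth")
  list(panel = panel, truth = truth)
}

#' Ground-truth ANI of a simulated pair
#'
#' `100 * (1 - realized divergence)` from the actual mutated positions of
#' the final simulated sequences (not the nominal rate).
#'
#' @param truth A `sim_truth` from [simulate_panel()].
#' @param id_a,id_b Strain ids.
#' @param scope `"genome"` or a gene name.
#' @return ANI percent.
#' @export
expected_ani <- function(truth, id_a, id_b, scope = "genome") {
  d <- truth$divergence
  row <- d[d$scope == scope &
             ((d$id_a == id_a & d$id_b == id_b) |
                (d$id_a == id_b & d$id_b == id_a)), ]
  if (nrow(row) != 1L) stop("unknown pair or scope: ", id_a, "/", id_b, " ", scope)
  100 * (1 - row$divergence)
}

#' Ground-truth genome ANI table for a simulated panel
#'
#' @param truth A `sim_truth`.
#' @param scope `"genome"` or a gene name.
#' @return An [ani_tbl()] of exact simulated ANI values.
#' @export
truth_ani_table <- function(truth, scope = "genome") {
  d <- truth$divergence[truth$divergence$scope == scope, ]
  ani_tbl(tibble(id_a = d$id_a, id_b = d$id_b, ani = 100 * (1 - d$divergence),
                 sites = d$sites),
          source = if (scope == "genome") "genome" else paste0("gene:", scope))
}

#' Simulate an indel-free diverged sequence pair
#'
#' One ancestor and one descendant mutated at per-site substitution
#' probability `divergence`; useful for validating the genome ANI engine
#' against an exactly known difference count.
#'
#' @param length Sequence length in bp.
#' @param divergence Per-site substitution probability.
#' @param seed Integer seed.
#' @return List with `a`, `b` (sequences), `realized_divergence` and
#'   `expected_ani` (percent, from the realized difference count).
#' @export
simulate_divergent_pair <- function(length, divergence, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  a <- random_seq(length)
  b <- mutate_seq(a, divergence)
  diffs <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  list(a = a, b = b, realized_divergence = diffs / length,
       expected_ani = 100 * (1 - diffs / length))
}

#' Evolve an alignment along a fixed tree
#'
#' Evolves a root sequence down a given topology under the uniform
#' substitution model, with a fixed per-branch substitution probability.
#' Used to build clonal (single-tree) and recombinant (concatenated
#' conflicting-tree) test alignments for the PHI test.
#'
#' @param tree An [ape::phylo] tree; only the topology is used.
#' @param length Sequence length in bp.
#' @param branch_p Per-branch per-site substitution probability.
#' @param seed Optional integer seed.
#' @return A [gene_alignment()] over the tree's tip labels.
#' @export
simulate_on_tree <- function(tree, length, branch_p = 0.05, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("character", n_tip + tree$Nnode)
  seqs[root] <- random_seq(length)
  edges <- tree$edge[rev(seq_len(nrow(tree$edge))), , drop = FALSE]  # preorder
  for (e in seq_len(nrow(edges))) {
    seqs[edges[e, 2]] <- mutate_seq(seqs[edges[e, 1]], branch_p)
  }
  gene_alignment("simulated", stats::setNames(seqs[seq_len(n_tip)], tree$tip.label))
}
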