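#' Classify strain pairs by concatenate ANI
#'
#' Applies the 94/96 rule: a pair is intraspecific when its concatenate ANI
#' (ANIstt) is at or above the intraspecies floor (default 96), interspecific
#' at or below the interspecies ceiling (default 94), and intermediate in the
#' open zone between them (a genetic continuum / ongoing speciation signal).
#' When genome ANI is also supplied, each pair is additionally placed in the
#' two-dimensional scatter regions (strict inequalities): interspecies
#' region ANIm < 93 and ANIstt < 94; intraspecies region ANIm > 95 and
#' ANIstt > 96; otherwise `between`.
#'
#' @param pairs Tibble with columns `id_a`, `id_b`, `anistt` and optionally
#'   `anim`.
#' @param cfg A [threshold_config()].
#' @return The input tibble with `category` (`intra`/`inter`/`intermediate`)
#'   and `region_2d` (`intra-region`/`inter-region`/`between`, or `none`
#'   when `anim` is absent) columns added.
#' @export
classify_pairs <- function(pairs, cfg = threshold_config()) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("anistt") %in% names(pairs)))
  if (any(is.na(pairs$anistt)) || any(pairs$anistt < 0 | pairs$anistt > 100)) {
    stop("anistt values must be in [0,100]")
  }
  pairs$category <- dplyr::case_when(
    pairs$anistt >= cfg$intra_floor ~ "intra",
    pairs$anistt <= cfg$inter_ceiling ~ "inter",
    TRUE ~ "intermediate"
  )
  if ("anim" %in% names(pairs)) {
    pairs$region_2d <- dplyr::case_when(
      is.na(pairs$anim) ~ "none",
      pairs$anim > cfg$region_genome_high & pairs$anistt > cfg$intra_floor ~ "intra-region",
      pairs$anim < cfg$region_genome_low & pairs$anistt < cfg$inter_ceiling ~ "inter-region",
      TRUE ~ "between"
    )
  } else {
    pairs$region_2d <- "none"
  }
  pairs
}

#' Audit a type-strain panel against the concatenate ANI boundaries
#'
#' Every strain must be the type strain of a distinct species, so every pair
#' is a currently-recognized interspecies relationship. The audit counts how
#' many of those relationships are supported at both readings of the
#' boundary (strictly below the interspecies ceiling of 94, and below the
#' intraspecies floor of 96) and identifies candidate species merges as the
#' connected components of the graph linking species whose type strains
#' reach intraspecific ANI (>= 96).
#'
#' @param table An [ani_tbl()] of concatenate ANI over the type strains.
#' @param labels Label table mapping each strain to its species.
#' @param cfg A [threshold_config()].
#' @return List with `n_inter_pairs`, `n_below_inter_ceiling` (< 94),
#'   `n_below_intra_floor` (< 96), `merge_candidates` (list of character
#'   vectors of species names, components of size >= 2) and `pairs` (the
#'   classified pair tibble).
#' @export
audit_type_strains <- function(table, labels, cfg = threshold_config()) {
  sp <- stats::setNames(trimws(labels$species), labels$strain_id)
  miss <- setdiff(unique(c(table$id_a, table$id_b)), names(sp))
  if (length(miss)) stop("unlabeled strain id(s): ", paste(miss, collapse = ", "))
  used <- sp[unique(c(table$id_a, table$id_b))]
  if (anyDuplicated(tolower(used))) {
    stop("duplicate species among type strains: ",
         paste(unique(used[duplicated(tolower(used))]), collapse = ", "))
  }
  if (any(is.na(table$ani))) stop("table contains pairs with undefined ANI")
  classified <- classify_pairs(
    tibble(id_a = table$id_a, id_b = table$id_b, anistt = table$ani), cfg)
  merge_edges <- classified[classified$anistt >= cfg$intra_floor, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = sp[merge_edges$id_a], to = sp[merge_edges$id_b]),
    directed = FALSE, vertices = data.frame(name = unname(used)))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  merge_candidates <- unname(members[lengths(members) >= 2])
  list(n_inter_pairs = nrow(table),
       n_below_inter_ceiling = sum(table$ani < cfg$inter_ceiling),
       n_below_intra_floor = sum(table$ani < cfg$intra_floor),
       merge_candidates = merge_candidates,
       pairs = classified)
}

#' Assign a query strain to a species via type-strain concatenate ANI
#'
#' Computes the marker-concatenate ANI between the query and every type
#' strain in the reference panel (globally aligning each gene pair when the
#' inputs are unaligned) and applies the 94/96 rule to the best score:
#' `assigned` to the best type strain's species at or above the intraspecies
#' floor, `novel-species-candidate` at or below the interspecies ceiling,
#' `ambiguous` in between. A query that is itself a type strain but is
#' assigned to another species is flagged `later-synonym-candidate`.
#'
#' @param query_genes Named character vector (or list) of the query's marker
#'   gene sequences, names are gene names.
#' @param panel A [strain_panel()] of type strains whose alignments (or
#'   per-strain gene sequences) cover the same genes.
#' @param cfg A [threshold_config()].
#' @param query_id Id of the query strain (used for the synonym flag when it
#'   matches a type strain in the panel's label table).
#' @param aligned Set `TRUE` when query and panel rows are already aligned
#'   to a common coordinate system; otherwise each query/type-strain gene
#'   pair is aligned with [align_pair()].
#' @return List with `query`, `best_type_strain`, `best_species`,
#'   `best_anistt`, `verdict`, `flags` and `all_scores` (tibble
#'   `type_strain`, `species`, `anistt`).
#' @export
assign_strain <- function(query_genes, panel, cfg = threshold_config(),
                          query_id = "query", aligned = FALSE) {
  genes <- names(query_genes)
  if (is.null(genes) || !length(genes)) stop("query genes must be named by gene")
  missing <- setdiff(genes, names(panel$alignments))
  if (length(missing)) stop("panel lacks gene(s): ", paste(missing, collapse = ", "))
  type_ids <- panel$strains$strain_id[panel$strains$is_type_strain]
  if (!length(type_ids)) type_ids <- panel$strains$strain_id
  type_ids <- setdiff(type_ids, query_id)   # never score the query against itself
  if (!length(type_ids)) stop("empty reference panel")
  scores <- vapply(type_ids, function(tid) {
    diffs <- 0; sites <- 0
    for (g in genes) {
      ref <- panel$alignments[[g]]$seqs[[tid]]
      if (is.null(ref)) stop("type strain ", tid, " lacks gene ", g)
      if (aligned) {
        d <- gene_pair_diff(query_genes[[g]], ref)
      } else {
        al <- align_pair(gsub("-", "", query_genes[[g]]), gsub("-", "", ref))
        d <- gene_pair_diff(al[["a"]], al[["b"]])
      }
      diffs <- diffs + d$diffs; sites <- sites + d$sites
    }
    100 * (1 - diffs / sites)
  }, numeric(1))
  sp <- stats::setNames(panel$strains$species, panel$strains$strain_id)
  all_scores <- tibble(type_strain = type_ids, species = unname(sp[type_ids]),
                       anistt = unname(scores))
  best <- which.max(scores)
  best_anistt <- scores[[best]]
  verdict <- if (best_anistt >= cfg$intra_floor) {
    paste0("assigned(", sp[[type_ids[[best]]]], ")")
  } else if (best_anistt <= cfg$inter_ceiling) {
    "novel-species-candidate"
  } else {
    "ambiguous(intermediate)"
  }
  flags <- character(0)
  q_row <- panel$strains[panel$strains$strain_id == query_id, ]
  if (nrow(q_row) && isTRUE(q_row$is_type_strain) &&
      startsWith(verdict, "assigned(") &&
      tolower(trimws(sp[[type_ids[[best]]]])) != tolower(trimws(q_row$species))) {
    flags <- "later-synonym-candidate"
  }
  list(query = query_id, best_type_strain = type_ids[[best]],
       best_species = unname(sp[type_ids[[best]]]), best_anistt = best_anistt,
       verdict = verdict, flags = flags, all_scores = all_scores)
}
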