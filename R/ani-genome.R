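#' Parameters for fragment-seeded genome ANI
#'
#' The genome ANI engine approximates whole-genome-alignment ANI (ANIm) with
#' a self-contained fragment algorithm: the query is cut into consecutive
#' non-overlapping fragments, each fragment is seeded on exact k-mer matches
#' against the subject (both strands by default) and extended with a banded
#' global alignment around the best-supported seed diagonal. Fragments
#' passing the Goris-style identity and coverage filters contribute to an
#' aligned-length-weighted mean identity.
#'
#' @param fragment_len Fragment length in bp (default 1020).
#' @param seed_k Exact-match seed length (default 15).
#' @param min_frag_identity Minimum percent identity for a fragment to count
#'   (default 30).
#' @param min_frag_coverage Minimum fraction of the fragment aligned
#'   (default 0.70).
#' @param both_strands Search the reverse complement too (default `TRUE`).
#' @param seed_step Offset between successive seed k-mers within a fragment.
#' @param band Half-width of the alignment band around the seed diagonal.
#' @return A `ani_params` list.
#' @export
ani_params <- function(fragment_len = 1020L, seed_k = 15L,
                       min_frag_identity = 30, min_frag_coverage = 0.70,
                       both_strands = TRUE, seed_step = 16L, band = 32L) {
  stopifnot(seed_k > 0, seed_k < fragment_len, seed_k <= 31,
            min_frag_identity >= 0, min_frag_identity <= 100,
            min_frag_coverage > 0, min_frag_coverage <= 1,
            seed_step >= 1, band >= 1)
  structure(list(fragment_len = as.integer(fragment_len),
                 seed_k = as.integer(seed_k),
                 min_frag_identity = min_frag_identity,
                 min_frag_coverage = min_frag_coverage,
                 both_strands = isTRUE(both_strands),
                 seed_step = as.integer(seed_step),
                 band = as.integer(band)),
            class = "ani_params")
}

genome_ani_dir <- function(query, target, params) {
  frags <- .frag_align_dir(query, target, params$fragment_len, params$seed_k,
                           params$seed_step, params$band, params$both_strands)
  use <- !is.na(frags$identity) &
    frags$identity >= params$min_frag_identity &
    frags$coverage >= params$min_frag_coverage
  if (!any(use)) {
    return(list(ani = NA_real_, aligned_bp = 0L, n_fragments_used = 0L,
                n_fragments = nrow(frags)))
  }
  w <- frags$aligned_cols[use]
  list(ani = sum(frags$identity[use] * w) / sum(w),
       aligned_bp = sum(w),
       n_fragments_used = sum(use),
       n_fragments = nrow(frags))
}

#' Genome-level ANI between two sequences
#'
#' Symmetrized fragment-seeded ANI: the mean of the A-to-B and B-to-A
#' directions (each an aligned-length-weighted mean identity over qualifying
#' fragments). When no fragment passes the filters in either direction the
#' result is "no homology detected" (`ani = NA`, `status = "no_homology"`),
#' which is distinct from an ANI of 0.
#'
#' @param genome_a,genome_b Genome sequences (plain character strings).
#' @param params An [ani_params()] configuration.
#' @return A one-row tibble with `ani`, `aligned_fraction`,
#'   `n_fragments_used` and `status` (`"ok"` or `"no_homology"`).
#' @export
genome_ani <- function(genome_a, genome_b, params = ani_params()) {
  stopifnot(is.character(genome_a), is.character(genome_b))
  if (nchar(genome_a) < params$fragment_len || nchar(genome_b) < params$fragment_len) {
    stop("both genomes must be at least fragment_len (", params$fragment_len, ") bp")
  }
  ab <- genome_ani_dir(genome_a, genome_b, params)
  ba <- genome_ani_dir(genome_b, genome_a, params)
  anis <- c(ab$ani, ba$ani)
  fracs <- c(ab$aligned_bp / nchar(genome_a), ba$aligned_bp / nchar(genome_b))
  if (all(is.na(anis))) {
    return(tibble(ani = NA_real_, aligned_fraction = 0,
                  n_fragments_used = 0L, status = "no_homology"))
  }
  tibble(ani = mean(anis, na.rm = TRUE),
         aligned_fraction = mean(fracs),
         n_fragments_used = ab$n_fragments_used + ba$n_fragments_used,
         status = "ok")
}

#' Genome ANI table for all strain pairs in a panel
#'
#' @param panel A [strain_panel()] with genome sequences.
#' @param params An [ani_params()] configuration.
#' @return An [ani_tbl()] with source `"genome"`; pairs with no detected
#'   homology carry `ani = NA`.
#' @export
genome_ani_table <- function(panel, params = ani_params()) {
  if (is.null(panel$genomes) || length(panel$genomes) < 2L) {
    stop("panel has fewer than 2 genomes")
  }
  ids <- intersect(panel$strains$strain_id, names(panel$genomes))
  pairs <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    r <- genome_ani(panel$genomes[[pairs[1, k]]], panel$genomes[[pairs[2, k]]], params)
    tibble(id_a = pairs[1, k], id_b = pairs[2, k], ani = r$ani,
           aligned_fraction = r$aligned_fraction,
           n_fragments_used = r$n_fragments_used, status = r$status)
  })
  ani_tbl(dplyr::bind_rows(rows), source = "genome")
}
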