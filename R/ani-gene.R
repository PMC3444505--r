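#' Pairwise ANI tables
#'
#' ANI tables are tibbles of unordered strain pairs with class `ani_tbl`.
#' Columns: `id_a`, `id_b`, `ani` (percent, full float precision) and a
#' support measure (`diffs` + `sites` for difference-count ANI,
#' `aligned_bp` for genome ANI). The table's provenance is carried in the
#' `source` attribute (`"genome"`, `"gene:<name>"` or
#' `"concatenate:<names>"`).
#'
#' @param pairs Tibble of pair rows.
#' @param source Source tag.
#' @return An `ani_tbl`.
#' @export
ani_tbl <- function(pairs, source) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("id_a", "id_b", "ani") %in% names(pairs)))
  if (any(pairs$id_a == pairs$id_b)) stop("ani_tbl rows must be distinct-strain pairs")
  bad <- !is.na(pairs$ani) & (pairs$ani < 0 | pairs$ani > 100)
  if (any(bad)) stop("ANI values out of [0,100]")
  structure(pairs, class = c("ani_tbl", class(pairs)), source = source)
}

#' @export
#' @rdname ani_tbl
ani_source <- function(x) attr(x, "source")

#' Count differing sites between two aligned rows
#'
#' Implements the difference-count distance from which gene-level ANI (ANIg)
#' is derived: under pairwise deletion, a column is compared iff both rows
#' carry an unambiguous A/C/G/T there; `diffs` counts compared columns with
#' unequal bases and `ani = 100 * (1 - diffs / sites)`. Comparisons are
#' case-insensitive; gap and IUPAC ambiguity characters are excluded.
#'
#' @param row_a,row_b Aligned sequences of equal length.
#' @return A one-row tibble with `diffs`, `sites`, `ani`.
#' @export
#' @examples
#' gene_pair_diff("AA-A", "AATA")  # gapped column dropped: 3 sites, 0 diffs
gene_pair_diff <- function(row_a, row_b) {
  if (nchar(row_a) != nchar(row_b)) stop("rows have unequal lengths")
  a <- base_codes(row_a)
  b <- base_codes(row_b)
  ok <- !is.na(a) & !is.na(b)
  sites <- sum(ok)
  if (sites == 0L) stop("no compared sites: pair is unreportable under pairwise deletion")
  diffs <- sum(a[ok] != b[ok])
  tibble(diffs = diffs, sites = sites, ani = 100 * (1 - diffs / sites))
}

base_codes <- function(s) {
  codes <- rep(NA_integer_, 256L)
  codes[utf8ToInt("A")] <- 1L; codes[utf8ToInt("a")] <- 1L
  codes[utf8ToInt("C")] <- 2L; codes[utf8ToInt("c")] <- 2L
  codes[utf8ToInt("G")] <- 3L; codes[utf8ToInt("g")] <- 3L
  codes[utf8ToInt("T")] <- 4L; codes[utf8ToInt("t")] <- 4L
  codes[utf8ToInt(s)]
}

#' Gene-level ANI for every strain pair in an alignment
#'
#' Applies [gene_pair_diff()] to each unordered pair of rows. Pairs with zero
#' compared sites are reported with `ani = NA` (and zero `sites`) rather than
#' aborting the whole table.
#'
#' @param aln A [gene_alignment()].
#' @param source Source tag; defaults to `gene:<gene_name>`.
#' @return An [ani_tbl()] with `diffs`, `sites` support columns.
#' @export
gene_ani_table <- function(aln, source = paste0("gene:", aln$gene_name)) {
  m <- aln_code_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("alignment needs >= 2 rows")
  ids <- rownames(m)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    sites <- sum(ok)
    diffs <- if (sites) sum(m[i, ok] != m[j, ok]) else 0L
    c(diffs = diffs, sites = sites)
  })
  res <- do.call(rbind, res)
  out <- tibble(
    id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
    diffs = as.integer(res[, "diffs"]), sites = as.integer(res[, "sites"])
  )
  out$ani <- ifelse(out$sites > 0, 100 * (1 - out$diffs / out$sites), NA_real_)
  ani_tbl(out[, c("id_a", "id_b", "ani", "diffs", "sites")], source)
}

#' Concatenate ANI (ANIstt) for a strain panel
#'
#' Computes the ANI of a marker-gene concatenate, by default the
#' SMc00019-truA-thrA set (ANIstt). Equivalent to counting differences on the
#' concatenated rows, i.e. pooling `diffs` and `sites` across genes
#' (length-weighted, not the unweighted mean of per-gene ANIg values).
#'
#' @param panel A [strain_panel()] whose alignments include all `genes`.
#' @param genes Character vector of gene names to concatenate, in order.
#' @return An [ani_tbl()] with source `concatenate:<genes>`.
#' @export
anistt <- function(panel, genes = c("SMc00019", "truA", "thrA")) {
  missing <- setdiff(genes, names(panel$alignments))
  if (length(missing)) {
    stop("panel lacks gene alignment(s): ", paste(missing, collapse = ", "))
  }
  cat_aln <- concatenate_alignments(panel$alignments[genes], order = genes)
  gene_ani_table(cat_aln, source = paste0("concatenate:", paste(genes, collapse = "-")))
}

#' Convert an ANI pair table to a symmetric matrix
#'
#' @param x An [ani_tbl()] (or any tibble with `id_a`, `id_b`, `ani`).
#' @param ids Optional id ordering for the matrix.
#' @return Symmetric numeric matrix with 100 on the diagonal.
#' @export
ani_matrix <- function(x, ids = NULL) {
  if (is.null(ids)) ids <- unique(c(x$id_a, x$id_b))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  m[cbind(x$id_a, x$id_b)] <- x$ani
  m[cbind(x$id_b, x$id_a)] <- x$ani
  m
}

#' Write / read an ANI matrix as TSV
#'
#' `write_ani_table()` writes the lower triangle of the symmetric ANI matrix
#' (diagonal = 100, upper triangle empty) with strain ids as row and column
#' names; `read_ani_table()` reads that layout (or a full symmetric matrix)
#' back into an [ani_tbl()]. Values round-trip at full precision.
#'
#' @param x An [ani_tbl()].
#' @param path TSV path.
#' @param source Source tag attached on read.
#' @return `write_ani_table()` returns `path` invisibly; `read_ani_table()`
#'   returns an [ani_tbl()].
#' @export
write_ani_table <- function(x, path) {
  m <- ani_matrix(x)
  out <- format(m, digits = 15, trim = TRUE)
  out[upper.tri(out)] <- ""
  df <- data.frame(strain_id = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_ani_table
#' @export
read_ani_table <- function(path, source = "genome") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    strain_id = readr::col_character(), .default = readr::col_double()))
  ids <- df$strain_id
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) stop("ANI table rows/columns disagree: ", path)
  low <- t(m)[upper.tri(m)]            # lower triangle, column-major transpose
  up <- m[upper.tri(m)]
  merged <- ifelse(is.na(up), low, up)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  ani_tbl(tibble(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]], ani = merged),
          source = source)
}

#' Globally align two unaligned gene sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -4,
#' gap extend -1) used to prepare unaligned marker sequences for difference
#' counting. Pre-aligned inputs should be used as-is instead.
#'
#' @param seq_a,seq_b Unaligned nucleotide sequences.
#' @return Named character vector of the two aligned rows.
#' @export
align_pair <- function(seq_a, seq_b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    toupper(seq_a), toupper(seq_b), type = "global",
    substitutionMatrix = mat, gapOpening = 3, gapExtension = 1)
  c(a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)))
}
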