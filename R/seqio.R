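#' @useDynLib aniscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Read nucleotide sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble with one row per record. Sequence
#' whitespace is stripped and case is preserved; all downstream comparisons
#' are case-insensitive. Characters are restricted to IUPAC nucleotide codes
#' plus the gap character `-`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `seq` and `description` (remainder of the header, possibly "").
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a strain A", "ACGT", ">b", "AC", "GT"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA parse error in '", path, "': file contains no records")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA parse error in '", path, "': empty record id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("FASTA parse error in '", path, "': duplicate id(s): ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- gsub("[ \t\r]", "", as.character(set))
  if (any(!nzchar(seqs))) {
    stop("FASTA parse error in '", path, "': empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  validate_iupac(seqs, ids, path)
  tibble(id = ids, seq = unname(seqs), description = unname(desc))
}

# Reject anything outside the IUPAC nucleotide alphabet (+ gap), reporting the
# offending record and 1-based position.
validate_iupac <- function(seqs, ids, path = "<input>") {
  ok_pat <- paste0("^[", paste(IUPAC_CHARS, collapse = ""), "]*$")
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]])
    if (!grepl(ok_pat, s)) {
      bad <- regexpr(paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"), s)
      stop("FASTA parse error in '", path, "': non-IUPAC character '",
           substr(seqs[[i]], bad, bad), "' in record '", ids[[i]],
           "' at sequence position ", as.integer(bad))
    }
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with columns `id` and `seq` (optionally `description`),
#'   or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- tibble(id = names(x), seq = unname(x), description = "")
  if (!"description" %in% names(x)) x$description <- ""
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(x$description[[i]])) paste(x$id[[i]], x$description[[i]]) else x$id[[i]]
    writeLines(paste0(">", hdr), con)
    s <- x$seq[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a gene alignment
#'
#' A gene alignment is a named set of equal-length aligned nucleotide rows
#' (IUPAC codes plus `-`) keyed by strain id.
#'
#' @param gene_name Gene name (non-empty string).
#' @param seqs Named character vector of aligned rows, names are strain ids.
#' @return An object of class `gene_alignment` with fields `gene_name`,
#'   `seqs` and `length` (alignment columns).
#' @export
gene_alignment <- function(gene_name, seqs) {
  stopifnot(is.character(gene_name), length(gene_name) == 1L, nzchar(gene_name))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("alignment rows must be named by strain id")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate strain id(s) in alignment '", gene_name, "': ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  if (length(seqs) < 2L) stop("alignment '", gene_name, "' needs >= 2 rows")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment '", gene_name, "' rows have unequal lengths: ",
         paste(range(widths), collapse = "-"))
  }
  validate_iupac(seqs, names(seqs), paste0("alignment:", gene_name))
  structure(list(gene_name = gene_name, seqs = seqs, length = widths[[1]]),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("<gene_alignment> ", x$gene_name, ": ", length(x$seqs), " strains x ",
      x$length, " columns\n", sep = "")
  invisible(x)
}

#' Read a gene alignment from FASTA
#'
#' @param path FASTA file of aligned sequences.
#' @param gene_name Gene name; defaults to the file name without extension.
#' @return A [gene_alignment()].
#' @export
read_gene_alignment <- function(path, gene_name = NULL) {
  if (is.null(gene_name)) gene_name <- sub("\\.[^.]*$", "", basename(path))
  recs <- read_fasta(path)
  gene_alignment(gene_name, stats::setNames(recs$seq, recs$id))
}

# Integer code matrix (rows = strains) used by the difference counters.
# A/C/G/T (case-insensitive) map to 1:4; everything else (gaps, ambiguity
# codes) maps to NA and is excluded from compared sites.
aln_code_matrix <- function(aln) {
  codes <- rep(NA_integer_, 256L)
  codes[utf8ToInt("A")] <- 1L; codes[utf8ToInt("a")] <- 1L
  codes[utf8ToInt("C")] <- 2L; codes[utf8ToInt("c")] <- 2L
  codes[utf8ToInt("G")] <- 3L; codes[utf8ToInt("g")] <- 3L
  codes[utf8ToInt("T")] <- 4L; codes[utf8ToInt("t")] <- 4L
  m <- matrix(NA_integer_, nrow = length(aln$seqs), ncol = aln$length,
              dimnames = list(names(aln$seqs), NULL))
  for (i in seq_along(aln$seqs)) m[i, ] <- codes[utf8ToInt(aln$seqs[[i]])]
  m
}

#' Assemble a strain panel
#'
#' A strain panel bundles strain metadata (species labels, type-strain flags)
#' with optional genome sequences and a set of gene alignments. Every
#' alignment row id must appear in the strain table, and a species may carry
#' at most one type strain.
#'
#' @param strains Tibble/data.frame with columns `strain_id`, `species` and
#'   optionally `is_type_strain` (default `FALSE`).
#' @param alignments List of [gene_alignment()] objects (optionally named;
#'   names default to each alignment's `gene_name`).
#' @param genomes Optional named character vector of genome sequences.
#' @return An object of class `strain_panel`.
#' @export
strain_panel <- function(strains, alignments = list(), genomes = NULL) {
  strains <- as_tibble(strains)
  stopifnot(all(c("strain_id", "species") %in% names(strains)))
  if (!"is_type_strain" %in% names(strains)) strains$is_type_strain <- FALSE
  if (anyDuplicated(strains$strain_id)) stop("duplicate strain_id in panel")
  if (any(is.na(strains$species) | !nzchar(trimws(strains$species)))) {
    stop("every strain needs a non-empty species label")
  }
  ts <- strains[strains$is_type_strain, ]
  sp_norm <- tolower(trimws(ts$species))
  if (anyDuplicated(sp_norm)) {
    stop("more than one type strain for species: ",
         paste(unique(ts$species[duplicated(sp_norm)]), collapse = ", "))
  }
  if (length(alignments)) {
    if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
      names(alignments) <- vapply(alignments, function(a) a$gene_name, character(1))
    }
    if (anyDuplicated(names(alignments))) stop("duplicate gene names in panel")
    for (a in alignments) {
      missing <- setdiff(names(a$seqs), strains$strain_id)
      if (length(missing)) {
        stop("alignment '", a$gene_name, "' has rows not in the strain table: ",
             paste(missing, collapse = ", "))
      }
    }
  }
  if (!is.null(genomes)) {
    missing <- setdiff(names(genomes), strains$strain_id)
    if (length(missing)) {
      stop("genomes present for unknown strain(s): ", paste(missing, collapse = ", "))
    }
  }
  structure(list(strains = strains, alignments = alignments, genomes = genomes),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat("<strain_panel> ", nrow(x$strains), " strains, ",
      length(unique(tolower(trimws(x$strains$species)))), " species, ",
      length(x$alignments), " gene alignment(s), ",
      if (is.null(x$genomes)) 0L else length(x$genomes), " genome(s)\n", sep = "")
  invisible(x)
}

#' Read a strain label table
#'
#' @param path TSV with columns `strain_id`, `species`, `is_type_strain`
#'   (logical or 0/1; optional).
#' @return A tibble.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("strain_id", "species") %in% names(df)))
  if ("is_type_strain" %in% names(df)) {
    df$is_type_strain <- tolower(df$is_type_strain) %in% c("true", "t", "1", "yes")
  } else {
    df$is_type_strain <- FALSE
  }
  df[, c("strain_id", "species", "is_type_strain")]
}

#' Concatenate gene alignments
#'
#' Builds the multi-gene concatenate (e.g. the SMc00019-truA-thrA block used
#' for ANIstt) by joining the rows of each gene in the given order. Every
#' gene must cover exactly the same strain set; a strain missing from any
#' gene is an error, never silently padded.
#'
#' @param alignments Named list of [gene_alignment()] objects.
#' @param order Character vector naming each gene exactly once. Defaults to
#'   the list order.
#' @return A [gene_alignment()] whose `gene_name` joins the gene names with
#'   `-` and which carries a `gene_offsets` attribute (tibble with `gene`,
#'   `start`, `end` column offsets).
#' @export
concatenate_alignments <- function(alignments, order = NULL) {
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    names(alignments) <- vapply(alignments, function(a) a$gene_name, character(1))
  }
  if (is.null(order)) order <- names(alignments)
  if (length(order) != length(alignments) || anyDuplicated(order) ||
      !setequal(order, names(alignments))) {
    stop("'order' must list each gene exactly once")
  }
  alignments <- alignments[order]
  ids <- sort(names(alignments[[1]]$seqs))
  for (a in alignments) {
    missing <- setdiff(ids, names(a$seqs))
    extra <- setdiff(names(a$seqs), ids)
    if (length(missing) || length(extra)) {
      stop("gene '", a$gene_name, "' does not cover the same strains: ",
           if (length(missing)) paste0("missing ", paste(missing, collapse = ", ")) else "",
           if (length(extra)) paste0(" extra ", paste(extra, collapse = ", ")) else "")
    }
  }
  rows <- vapply(ids, function(id) {
    paste(vapply(alignments, function(a) a$seqs[[id]], character(1)), collapse = "")
  }, character(1))
  lens <- unname(vapply(alignments, function(a) a$length, numeric(1)))
  out <- gene_alignment(paste(order, collapse = "-"), rows)
  attr(out, "gene_offsets") <- tibble(
    gene = order,
    start = cumsum(c(1, lens[-length(lens)])),
    end = cumsum(lens)
  )
  out
}

#' Read a newick tree
#'
#' @param path Newick file with named leaves.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("newick parse error in '", path, "': ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in '", path, "': no tree found")
  if (anyDuplicated(tr$tip.label)) {
    stop("newick error in '", path, "': duplicate leaf name(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Write a tree to newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
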