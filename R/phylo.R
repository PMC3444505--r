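#' Neighbor-joining tree from an ANI-derived distance matrix
#'
#' Builds an unrooted NJ tree from a symmetric distance matrix (typically
#' `100 - ANI`). Used as the congruence proxy where maximum-likelihood
#' inference would otherwise be run.
#'
#' @param dist Symmetric numeric matrix with zero diagonal and row/column
#'   names, or a `dist` object.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  if (nrow(dist) < 3) stop("need at least 3 taxa")
  if (is.null(rownames(dist))) stop("distance matrix must have taxon names")
  if (any(is.na(dist))) stop("distance matrix contains NA")
  if (any(dist < 0)) stop("negative distances")
  if (max(abs(dist - t(dist))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(abs(diag(dist)) > 1e-12)) stop("diagonal must be zero")
  ape::nj(dist)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of nontrivial bipartitions, optionally
#' normalized by `2 * (n - 3)`.
#'
#' @param t1,t2 [ape::phylo] trees over identical leaf sets.
#' @param normalize Return the normalized distance in `[0, 1]`.
#' @return A count (or fraction when `normalize = TRUE`).
#' @export
rf_distance <- function(t1, t2, normalize = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  n <- length(t1$tip.label)
  if (n < 4) stop("RF distance needs >= 4 leaves")
  d <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2), check.labels = TRUE)
  if (normalize) d / (2 * (n - 3)) else d
}

#' Refined incompatibility of a pair of alignment columns
#'
#' Generalized four-gamete score for two sites: taxa with a gap or ambiguity
#' at either site are dropped, then the bipartite state graph is built
#' (nodes = states observed at each site, edges = observed joint states) and
#' scored by its cycle rank E - V + C. The score is 0 exactly when the two
#' sites are compatible on some tree; for two binary sites it is 1 when all
#' four gametes are present.
#'
#' @param site_i,site_j Character vectors (one character per taxon) over the
#'   same taxa.
#' @return Non-negative integer incompatibility score.
#' @export
pair_incompatibility <- function(site_i, site_j) {
  stopifnot(length(site_i) == length(site_j))
  a <- base_codes(paste(site_i, collapse = ""))
  b <- base_codes(paste(site_j, collapse = ""))
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("fewer than 2 taxa after filtering gaps/ambiguities")
  incompat_score(a[ok], b[ok])
}

# cycle rank of the bipartite state graph for two coded columns (no NAs)
incompat_score <- function(a, b) {
  joint <- unique(a * 5L + b)
  ua <- unique(joint %/% 5L)
  ub <- unique(joint %% 5L)
  E <- length(joint)
  V <- length(ua) + length(ub)
  # connected components by union-find over the joint edges
  parent <- seq_len(V)
  idx_a <- match(joint %/% 5L, ua)
  idx_b <- length(ua) + match(joint %% 5L, ub)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_len(E)) {
    ra <- find(idx_a[e]); rb <- find(idx_b[e])
    if (ra != rb) parent[rb] <- ra
  }
  C <- length(unique(vapply(seq_len(V), find, integer(1))))
  E - V + C
}

# Parsimony-informative site indices of a coded alignment matrix: at least
# two states each observed in at least two taxa (gaps/ambiguities ignored).
informative_sites <- function(m) {
  which(vapply(seq_len(ncol(m)), function(j) {
    tab <- tabulate(m[, j], nbins = 4L)
    sum(tab >= 2L) >= 2L
  }, logical(1)))
}

# Incompatibility score matrix over informative sites (k x k, zero diagonal).
incompat_matrix <- function(m, inf_idx) {
  k <- length(inf_idx)
  M <- matrix(0, k, k)
  cols <- lapply(inf_idx, function(j) m[, j])
  for (i in seq_len(k - 1)) {
    a <- cols[[i]]
    for (j in (i + 1):k) {
      b <- cols[[j]]
      ok <- !is.na(a) & !is.na(b)
      s <- if (sum(ok) >= 2) incompat_score(a[ok], b[ok]) else 0
      M[i, j] <- s; M[j, i] <- s
    }
  }
  M
}

#' Pairwise homoplasy (PHI) permutation test for recombination
#'
#' The PHI statistic is the mean refined incompatibility
#' ([pair_incompatibility()]) over pairs of parsimony-informative sites
#' whose indices (counted among informative sites) differ by at most
#' `window_w`. Recombination clusters compatible sites locally, so under
#' recombination the observed statistic is low relative to a null obtained
#' by permuting the order of informative sites. The p-value is the
#' add-one-corrected fraction of permutations with a statistic at most the
#' observed one.
#'
#' @param aln A [gene_alignment()] with >= 4 rows.
#' @param window_w Window width in informative-site index space.
#' @param n_permutations Number of permutations.
#' @param seed Integer seed for the permutation null.
#' @return A `phi_result` list: `statistic`, `window_w`, `n_informative`,
#'   `n_permutations`, `p_value` (`NA` with explanatory `status` when fewer
#'   than 2 informative sites or no in-window pair exists), `seed`.
#' @export
phi_test <- function(aln, window_w = 100L, n_permutations = 1000L, seed = 1L) {
  if (length(aln$seqs) < 4L) stop("PHI test needs >= 4 sequences")
  m <- aln_code_matrix(aln)
  inf_idx <- informative_sites(m)
  k <- length(inf_idx)
  res <- list(statistic = NA_real_, window_w = as.integer(window_w),
              n_informative = k, n_permutations = as.integer(n_permutations),
              p_value = NA_real_, seed = as.integer(seed), status = "ok")
  if (k < 2L) {
    res$status <- "too few parsimony-informative sites: p undefined"
    return(structure(res, class = "phi_result"))
  }
  M <- incompat_matrix(m, inf_idx)
  pr <- which(upper.tri(M), arr.ind = TRUE)
  band <- pr[pr[, 2] - pr[, 1] <= window_w, , drop = FALSE]
  if (nrow(band) == 0L) {
    res$status <- "no informative-site pair within window: p undefined"
    return(structure(res, class = "phi_result"))
  }
  obs <- mean(M[band])
  res$statistic <- obs
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  perm_stats <- vapply(seq_len(n_permutations), function(r) {
    p <- sample.int(k)
    mean(M[cbind(p[band[, 1]], p[band[, 2]])])
  }, numeric(1))
  res$p_value <- (sum(perm_stats <= obs + 1e-12) + 1) / (n_permutations + 1)
  structure(res, class = "phi_result")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.phi_result <- function(x, ...) {
  cat("<phi_result> statistic =", format(x$statistic, digits = 4),
      "informative sites =", x$n_informative, "\n  P",
      if (is.na(x$p_value)) paste0("undefined (", x$status, ")")
      else sub("^= ", "= ", format_p(x$p_value, floor = 1 / (x$n_permutations + 1))),
      " (", x$n_permutations, "permutations, seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}
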