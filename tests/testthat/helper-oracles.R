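# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and textbook formulas only.

# column-by-column difference count under pairwise deletion
brute_pair_diff <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  acgt <- c("A", "C", "G", "T")
  diffs <- 0L; sites <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% acgt && cb[i] %in% acgt) {
      sites <- sites + 1L
      if (ca[i] != cb[i]) diffs <- diffs + 1L
    }
  }
  list(diffs = diffs, sites = sites,
       ani = if (sites > 0) 100 * (1 - diffs / sites) else NA_real_)
}

random_alignment_seqs <- function(n, len, ids = sprintf("s%02d", seq_len(n)),
                                  gap_prob = 0.05, amb_prob = 0.02) {
  chars <- c("A", "C", "G", "T")
  out <- vapply(seq_len(n), function(i) {
    s <- sample(chars, len, replace = TRUE)
    r <- runif(len)
    s[r < gap_prob] <- "-"
    s[r >= gap_prob & r < gap_prob + amb_prob] <- sample(c("N", "R", "Y"), 1)
    paste(s, collapse = "")
  }, character(1))
  names(out) <- ids
  out
}

# textbook product-moment correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# average ranks, then product-moment on the ranks
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, numeric(1))
  }
  oracle_pearson(avg_rank(x), avg_rank(y))
}

# polynomial least squares via explicit normal equations
oracle_polyfit <- function(x, y, degree) {
  X <- vapply(0:degree, function(p) x^p, numeric(length(x)))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  list(coef = as.numeric(beta), sse = sum(resid^2),
       r2 = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# Fitch parsimony length of one multistate character on an unrooted tree
oracle_fitch <- function(tree, states) {
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- states[[tree$tip.label[i]]]
  len <- 0L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  score <- function(node) {
    if (node <= n_tip) return(sets[[node]])
    kid_sets <- lapply(children[[as.character(node)]], score)
    inter <- Reduce(intersect, kid_sets)
    if (length(inter)) return(inter)
    # pairwise Fitch: fold children left to right
    acc <- kid_sets[[1]]
    for (k in kid_sets[-1]) {
      both <- intersect(acc, k)
      if (length(both)) acc <- both else { acc <- union(acc, k); len <<- len + 1L }
    }
    acc
  }
  root <- n_tip + 1L
  score(root)
  len
}

# minimal extra steps needed to fit two characters jointly on one tree,
# minimized over all unrooted binary topologies (exhaustive, small n)
oracle_pair_incompat <- function(col_i, col_j, taxa = names(col_i)) {
  keep <- col_i %in% c("A", "C", "G", "T") & col_j %in% c("A", "C", "G", "T")
  col_i <- col_i[keep]; col_j <- col_j[keep]; taxa <- taxa[keep]
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  si <- as.list(stats::setNames(col_i, taxa))
  sj <- as.list(stats::setNames(col_j, taxa))
  min_i <- length(unique(col_i)) - 1L
  min_j <- length(unique(col_j)) - 1L
  best <- Inf
  for (k in seq_along(trees)) {
    tr <- trees[[k]]            # multiPhylo stores tip labels compressed
    l <- oracle_fitch(tr, si) + oracle_fitch(tr, sj)
    if (l < best) best <- l
  }
  best - (min_i + min_j)
}

# canonical nontrivial bipartitions of an unrooted tree, as sorted strings
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- sort(labs[p])
    if (length(side) <= 1 || length(side) >= length(tips) - 1) next
    other <- setdiff(tips, side)
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, canon)
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# small labeled random ANI panel for gap/concordance oracle tests
random_labeled_panel <- function(n_strains, n_species) {
  ids <- sprintf("t%02d", seq_len(n_strains))
  labels <- tibble::tibble(
    strain_id = ids,
    species = sprintf("sp%d", sample(seq_len(n_species), n_strains, replace = TRUE)),
    is_type_strain = FALSE)
  pairs <- t(utils::combn(ids, 2))
  tab <- tibble::tibble(id_a = pairs[, 1], id_b = pairs[, 2],
                        ani = round(runif(nrow(pairs), 85, 100), 2))
  list(labels = labels, table = aniscreen::ani_tbl(tab, source = "gene:test"))
}
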