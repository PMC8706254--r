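# Pairwise sample dissimilarity: Bray-Curtis, weighted UniFrac, beta-MNTD.

#' Bray-Curtis dissimilarity matrix
#'
#' Counts are converted to relative abundances first (removing library-size
#' artifacts), then `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` via
#' [vegan::vegdist()].
#'
#' @param counts Taxa-by-samples count matrix with >= 2 samples.
#' @return Symmetric samples-by-samples matrix in `[0, 1]`.
#' @export
bray_curtis <- function(counts) {
  check_count_matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  p <- rel_abund(counts)
  m <- as.matrix(vegan::vegdist(t(p), method = "bray"))
  attr(m, "metric") <- "bray_curtis"
  m
}

#' Weighted UniFrac distance matrix
#'
#' Abundance-weighted UniFrac on relative abundances:
#' `sum_b l_b |A_b - B_b|` over branches, where `A_b`, `B_b` are the
#' fractions of each sample's abundance descending from branch b. With
#' `normalized = TRUE` (default) each pair's value is divided by its
#' maximum attainable value, `sum_j depth_j (A_j + B_j)` over tips, so
#' results lie in `[0, 1]` and are comparable across pairs.
#'
#' @param counts Taxa-by-samples count matrix; taxa must be tree tips.
#' @param tree Rooted [ape::phylo] tree.
#' @param normalized Normalize to `[0, 1]`.
#' @return Symmetric samples-by-samples matrix.
#' @export
weighted_unifrac <- function(counts, tree, normalized = TRUE) {
  check_count_matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (!all(rownames(counts) %in% tree$tip.label))
    stop("all table taxa must be tree tips; call align_inputs() first")
  p <- rel_abund(counts)
  tree <- ape::keep.tip(tree, rownames(counts))
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n <- ncol(p)
  # fraction of each sample's abundance descending from every node,
  # accumulated child -> parent in postorder
  frac <- matrix(0, n_node, n)
  frac[seq_len(n_tip), ] <- p[tree$tip.label, , drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    frac[par, ] <- frac[par, ] + frac[child, ]
  }
  edge_frac <- frac[tree$edge[, 2], , drop = FALSE]
  len <- tree$edge.length
  m <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  depth <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
  tipw <- depth * frac[seq_len(n_tip), , drop = FALSE]  # depth_j * A_j
  for (k in seq_len(n - 1)) for (l in (k + 1):n) {
    raw <- sum(len * abs(edge_frac[, k] - edge_frac[, l]))
    if (normalized) {
      dmax <- sum(tipw[, k] + tipw[, l])
      raw <- if (dmax > 0) raw / dmax else 0
    }
    m[k, l] <- m[l, k] <- raw
  }
  attr(m, "metric") <- if (normalized) "wunifrac" else "wunifrac_raw"
  m
}

# Core beta-MNTD kernel shared by beta_mntd() and beta_nti(). `F` is the
# taxa-by-samples weight matrix (relative abundances, or presence / richness
# for the unweighted form); `D` the patristic distance matrix; `idx_list`
# the per-sample present-taxon indices, already mapped through any label
# permutation. Returns the symmetric samples-by-samples beta-MNTD matrix:
# bMNTD(k, l) = (sum_i F[i,k] min_{j in l} D[i,j] + reciprocal) / 2.
bmntd_kernel <- function(D, F_w, idx_list) {
  n <- length(idx_list)
  M <- vapply(idx_list, function(idx) {
    sub <- D[, idx, drop = FALSE]
    row_mins(sub)
  }, numeric(nrow(D)))
  B <- crossprod(F_w, M)
  (B + t(B)) / 2
}

#' Beta mean nearest taxon distance (beta-MNTD)
#'
#' For each sample pair (k, l): the mean over taxa in k of the patristic
#' distance to the nearest taxon in l, averaged with the reciprocal
#' direction. The abundance-weighted form (default, following the Stegen
#' null-model procedure) weights each taxon's nearest-neighbor distance by
#' its relative abundance; it matches [picante::comdistnt()] with
#' `abundance.weighted = TRUE`.
#'
#' @param counts Taxa-by-samples count matrix; taxa must be tree tips.
#' @param tree Rooted [ape::phylo] tree.
#' @param weighted Abundance-weight the nearest-neighbor distances.
#' @return Symmetric samples-by-samples matrix.
#' @export
beta_mntd <- function(counts, tree, weighted = TRUE) {
  check_count_matrix(counts)
  taxa <- rownames(counts)
  if (!all(taxa %in% tree$tip.label))
    stop("all table taxa must be tree tips; call align_inputs() first")
  if (any(colSums(counts) == 0)) stop("every sample needs >= 1 present taxon")
  D <- stats::cophenetic(ape::keep.tip(tree, taxa))[taxa, taxa]
  F_w <- beta_weights(counts, weighted)
  idx_list <- lapply(seq_len(ncol(counts)), function(j) which(counts[, j] > 0))
  m <- bmntd_kernel(D, F_w, idx_list)
  dimnames(m) <- list(colnames(counts), colnames(counts))
  attr(m, "metric") <- if (weighted) "bmntd_weighted" else "bmntd"
  m
}

beta_weights <- function(counts, weighted) {
  if (weighted) rel_abund(counts)
  else {
    pres <- (counts > 0) * 1
    sweep(pres, 2, colSums(pres), "/")
  }
}
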