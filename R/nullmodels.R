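# Phylogeny-shuffling and community re-assembly null models: the core of
# the assembly-inference framework.

#' Beta nearest taxon index (beta-NTI)
#'
#' Observed beta-MNTD for every sample pair is compared to a null
#' distribution obtained by shuffling tip labels of the phylogeny across
#' the full analyzed taxon pool ("taxa.labels" null). One label shuffle per
#' replicate is shared by all sample pairs, so pairwise values are mutually
#' consistent and the computation vectorizes.
#' `betaNTI(k, l) = (betaMNTD_obs - mean_null) / sd_null`; values above +2
#' indicate variable selection, below -2 homogeneous selection. Pairs with
#' a degenerate null (`sd_null = 0`) are returned as `NA` and counted in
#' the `n_undefined` attribute.
#'
#' @param counts Taxa-by-samples count matrix; taxa must be tree tips.
#' @param tree Rooted [ape::phylo] tree.
#' @param n_null Number of label randomizations (default 999).
#' @param weighted Abundance-weight beta-MNTD (default `TRUE`).
#' @param seed Integer seed.
#' @return Symmetric samples-by-samples matrix of beta-NTI z-scores with
#'   attributes `bmntd_obs`, `null_mean`, `null_sd`, `n_null`, `seed`,
#'   `n_undefined`.
#' @export
beta_nti <- function(counts, tree, n_null = 999, weighted = TRUE, seed = 1) {
  if (n_null < 1) stop("n_null must be >= 1")
  check_count_matrix(counts)
  taxa <- rownames(counts)
  if (!all(taxa %in% tree$tip.label))
    stop("all table taxa must be tree tips; call align_inputs() first")
  D <- stats::cophenetic(ape::keep.tip(tree, taxa))[taxa, taxa]
  n_taxa <- length(taxa)
  n <- ncol(counts)
  F_w <- beta_weights(counts, weighted)
  idx_list <- lapply(seq_len(n), function(j) which(counts[, j] > 0))
  obs <- bmntd_kernel(D, F_w, idx_list)
  null_sum <- matrix(0, n, n)
  null_sq <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(n_taxa)
      Fp <- F_w
      Fp[perm, ] <- F_w
      idx_p <- lapply(idx_list, function(idx) perm[idx])
      v <- bmntd_kernel(D, Fp, idx_p)
      null_sum <- null_sum + v
      null_sq <- null_sq + v^2
    }
  })
  null_mean <- null_sum / n_null
  null_sd <- if (n_null > 1)
    sqrt(pmax(null_sq / n_null - null_mean^2, 0) * n_null / (n_null - 1))
  else matrix(0, n, n)
  z <- (obs - null_mean) / null_sd
  z[!is.finite(z)] <- NA_real_
  diag(z) <- NA_real_
  n_undef <- sum(is.na(z[upper.tri(z)]))
  if (n_undef > 0)
    warning(n_undef, " pair(s) with degenerate null (sd = 0); beta-NTI = NA")
  dn <- list(colnames(counts), colnames(counts))
  dimnames(z) <- dimnames(obs) <- dimnames(null_mean) <- dimnames(null_sd) <- dn
  structure(z, bmntd_obs = obs, null_mean = null_mean, null_sd = null_sd,
            n_null = n_null, seed = seed, n_undefined = n_undef,
            metric = "beta_nti")
}

#' Bray-Curtis-based Raup-Crick metric (RCbray)
#'
#' Probabilistic community re-assembly null (Stegen/Chase procedure): in
#' each replicate every sample is re-assembled by drawing its observed
#' richness of taxa without replacement with probability proportional to
#' occupancy across samples, then allocating its observed total reads among
#' the drawn taxa multinomially in proportion to metacommunity relative
#' abundance. Bray-Curtis between the two null assemblies of a pair forms
#' the null distribution; with `obs` the observed dissimilarity,
#' `RC_raw = (#null < obs + 0.5 #null = obs) / n_null` and
#' `RCbray = 2 (RC_raw - 0.5)` in `[-1, 1]`. Values above +0.95 indicate
#' dispersal limitation, below -0.95 homogenizing dispersal. One null
#' assembly per sample per replicate is shared by all pairs.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param n_null Number of null assemblies (default 999).
#' @param seed Integer seed.
#' @return Symmetric samples-by-samples matrix in `[-1, 1]` with attributes
#'   `n_null` and `seed`.
#' @export
raup_crick_bray <- function(counts, n_null = 999, seed = 1) {
  if (n_null < 1) stop("n_null must be >= 1")
  check_count_matrix(counts)
  n <- ncol(counts)
  n_taxa <- nrow(counts)
  pres <- counts > 0
  occupancy <- rowSums(pres)
  gamma_pool <- which(occupancy > 0)
  richness <- colSums(pres)
  if (any(richness > length(gamma_pool)))
    stop("sample richness exceeds the occupied taxon pool")
  reads <- colSums(counts)
  meta_p <- rowSums(rel_abund(counts))
  meta_p <- meta_p / sum(meta_p)
  obs <- as.matrix(vegan::vegdist(t(rel_abund(counts)), method = "bray"))
  lt <- numeric(n * n); dim(lt) <- c(n, n)   # count of null < obs
  eq <- matrix(0, n, n)                      # count of null == obs
  occ_w <- occupancy[gamma_pool]
  meta_w <- meta_p[gamma_pool]
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      null_tab <- matrix(0, length(gamma_pool), n)
      for (j in seq_len(n)) {
        drawn <- sample.int(length(gamma_pool), richness[j], prob = occ_w)
        w <- meta_w[drawn]
        # each drawn taxon starts at 1 individual (the draw fixes richness);
        # the remaining reads are allocated by metacommunity abundance
        null_tab[drawn, j] <- 1L +
          stats::rmultinom(1, reads[j] - richness[j], w / sum(w))
      }
      null_bc <- as.matrix(vegan::vegdist(
        t(sweep(null_tab, 2, colSums(null_tab), "/")), method = "bray"))
      lt <- lt + (null_bc < obs - 1e-10)
      eq <- eq + (abs(null_bc - obs) <= 1e-10)
    }
  })
  rc <- 2 * ((lt + 0.5 * eq) / n_null - 0.5)
  diag(rc) <- NA_real_
  dimnames(rc) <- list(colnames(counts), colnames(counts))
  structure(rc, n_null = n_null, seed = seed, metric = "rc_bray")
}
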