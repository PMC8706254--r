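# Per-sample taxonomic and phylogenetic alpha diversity.

#' Richness estimators for one sample
#'
#' `SR` is observed richness. Chao1 is the classic estimator
#' `SR + F1^2 / (2 F2)` (F1, F2 = singleton and doubleton counts), falling
#' back to the bias-corrected form `SR + F1 (F1 - 1) / (2 (F2 + 1))` when
#' there are no doubletons. ACE is the abundance-based coverage estimator
#' with rare threshold 10, as computed by [vegan::estimateR()].
#'
#' @param counts Non-negative integer vector of taxon counts for one sample.
#' @return Named list with `SR`, `chao1`, `ace`.
#' @export
richness_estimators <- function(counts) {
  counts <- check_sample_counts(counts)
  sr <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  chao1 <- if (f2 > 0) sr + f1^2 / (2 * f2) else sr + f1 * (f1 - 1) / (2 * (f2 + 1))
  if (!any(counts[counts > 0] <= 10)) {
    ace <- sr  # no rare class: coverage correction is vacuous
  } else {
    est <- vegan::estimateR(counts)
    ace <- unname(est["S.ACE"])
    if (!is.finite(ace)) ace <- sr
  }
  list(SR = sr, chao1 = chao1, ace = ace)
}

#' Shannon and Simpson diversity for one sample
#'
#' Shannon entropy in natural log (nats) and Gini-Simpson diversity
#' `1 - sum(p^2)`, both via [vegan::diversity()].
#'
#' @inheritParams richness_estimators
#' @return Named list with `shannon`, `simpson`.
#' @export
diversity_indices <- function(counts) {
  counts <- check_sample_counts(counts)
  list(shannon = unname(vegan::diversity(counts, index = "shannon")),
       simpson = unname(vegan::diversity(counts, index = "simpson")))
}

check_sample_counts <- function(counts) {
  x <- as.numeric(counts)
  if (any(!is.finite(x)) || any(x < 0)) stop("counts must be finite and >= 0")
  if (any(abs(x - round(x)) > 1e-8)) stop("counts must be integral")
  if (sum(x) == 0) stop("all-zero sample")
  x
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the present taxa
#' and the root (rooted PD, via [picante::pd()]).
#'
#' @param present_taxa Character vector of tip labels present.
#' @param tree Rooted [ape::phylo] tree.
#' @return PD in branch-length units.
#' @export
faith_pd <- function(present_taxa, tree) {
  if (length(present_taxa) == 0) stop("empty taxon set")
  unknown <- setdiff(present_taxa, tree$tip.label)
  if (length(unknown) > 0)
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  comm <- matrix(as.integer(tree$tip.label %in% present_taxa), nrow = 1,
                 dimnames = list("s", tree$tip.label))
  picante::pd(comm, tree, include.root = TRUE)$PD
}

#' MNTD and the nearest taxon index (NTI)
#'
#' For each sample, the observed mean nearest-taxon distance (MNTD) and its
#' standardized effect size against a "taxa.labels" null: tip labels are
#' shuffled on the patristic distance matrix across the full analyzed taxon
#' pool (all rows of `counts`), preserving each sample's richness.
#' `NTI = -(MNTD_obs - mean_null) / sd_null`, so positive values indicate
#' phylogenetic clustering (values above +2 are conventionally read as
#' environmental filtering). Degenerate nulls (`sd_null = 0`) yield `NA`
#' with a warning rather than a silent zero.
#'
#' @param counts Taxa-by-samples count matrix (taxa must be tree tips).
#' @param tree Rooted [ape::phylo] tree.
#' @param n_null Number of label randomizations (default 1000).
#' @param weighted If `TRUE`, weight each taxon's nearest-neighbor distance
#'   by its relative abundance (presence-based by default, matching the
#'   richness-preserving null).
#' @param seed Integer seed for the null draws.
#' @return data.frame with `sample_id`, `mntd_obs`, `null_mean`, `null_sd`,
#'   `nti`.
#' @export
nti <- function(counts, tree, n_null = 1000, weighted = FALSE, seed = 1) {
  check_count_matrix(counts)
  taxa <- rownames(counts)
  if (!all(taxa %in% tree$tip.label))
    stop("all table taxa must be tree tips; call align_inputs() first")
  D <- stats::cophenetic(ape::keep.tip(tree, taxa))[taxa, taxa]
  n_taxa <- length(taxa)
  idx_list <- lapply(seq_len(ncol(counts)), function(j) which(counts[, j] > 0))
  w_list <- lapply(seq_len(ncol(counts)), function(j) {
    x <- counts[idx_list[[j]], j]
    x / sum(x)
  })
  mntd_of <- function(idx, w) {
    if (length(idx) < 2) return(NA_real_)
    sub <- D[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    nn <- row_mins(sub)
    if (weighted) sum(w * nn) else mean(nn)
  }
  obs <- vapply(seq_along(idx_list), function(j)
    mntd_of(idx_list[[j]], w_list[[j]]), numeric(1))
  null_sum <- numeric(length(obs))
  null_sq <- numeric(length(obs))
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(n_taxa)
      v <- vapply(seq_along(idx_list), function(j)
        mntd_of(perm[idx_list[[j]]], w_list[[j]]), numeric(1))
      null_sum <- null_sum + v
      null_sq <- null_sq + v^2
    }
  })
  null_mean <- null_sum / n_null
  null_sd <- sqrt(pmax(null_sq / n_null - null_mean^2, 0) * n_null / (n_null - 1))
  nti_val <- ifelse(null_sd > 0, -(obs - null_mean) / null_sd, NA_real_)
  if (any(is.na(nti_val) & !is.na(obs)))
    warning(sum(is.na(nti_val) & !is.na(obs)),
            " sample(s) with degenerate null (sd = 0); NTI set to NA")
  data.frame(sample_id = colnames(counts), mntd_obs = obs,
             null_mean = null_mean, null_sd = null_sd, nti = nti_val,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample alpha-diversity table
#'
#' Computes SR, Chao1, ACE, Shannon, Simpson and, when a tree is supplied,
#' Faith's PD, observed MNTD and NTI for every sample.
#'
#' @inheritParams nti
#' @param tree Optional rooted tree; phylogenetic indices are skipped when
#'   `NULL`.
#' @param rarefy If `TRUE`, rarefy all samples to the minimum depth first.
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(counts, tree = NULL, n_null = 1000,
                            weighted = FALSE, rarefy = FALSE, seed = 1) {
  check_count_matrix(counts)
  if (rarefy) {
    counts <- with_seed(stage_seed(seed, "rarefy"),
                        t(vegan::rrarefy(t(counts), min(colSums(counts)))))
  }
  rec <- do.call(rbind, lapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    r <- richness_estimators(x)
    d <- diversity_indices(x)
    data.frame(sample_id = colnames(counts)[j], SR = r$SR, chao1 = r$chao1,
               ace = r$ace, shannon = d$shannon, simpson = d$simpson,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(tree)) {
    rec$pd <- vapply(seq_len(ncol(counts)), function(j)
      faith_pd(rownames(counts)[counts[, j] > 0], tree), numeric(1))
    z <- nti(counts, tree, n_null = n_null, weighted = weighted, seed = seed)
    rec$mntd_obs <- z$mntd_obs
    rec$nti <- z$nti
  }
  rec
}
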