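# Small deterministic fixtures and brute-force oracles used across tests.

toy_tree <- function(text = "((A:1,B:1):1,C:2);") ape::read.tree(text = text)

toy_table <- function() {
  m <- matrix(c(1L, 0L, 2L,
                0L, 3L, 1L,
                4L, 1L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  m
}

# Balanced 4-tip tree with cherries (A,B) and (C,D) on long stems.
balanced4 <- function() ape::read.tree(text = "((A:1,B:1):4,(C:1,D:1):4);")

# MNTD of one community (vector of taxon names) on a distance matrix.
bf_mntd <- function(taxa, D) {
  if (length(taxa) < 2) return(NA_real_)
  sub <- D[taxa, taxa, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

# Abundance-weighted (or not) beta-MNTD between two communities by a direct
# double loop -- the independent oracle for the vectorized kernel.
bf_bmntd <- function(x, y, D, weighted = TRUE) {
  ix <- names(x)[x > 0]; iy <- names(y)[y > 0]
  wx <- if (weighted) x[ix] / sum(x[ix]) else rep(1 / length(ix), length(ix))
  wy <- if (weighted) y[iy] / sum(y[iy]) else rep(1 / length(iy), length(iy))
  dxy <- sum(wx * sapply(ix, function(i) min(D[i, iy])))
  dyx <- sum(wy * sapply(iy, function(j) min(D[j, ix])))
  (dxy + dyx) / 2
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1)
  }
  out
}

# Exhaustive-enumeration NTI for one community: z-score of MNTD over every
# relabeling of the distance matrix (population sd).
bf_nti_exact <- function(taxa, D) {
  labs <- rownames(D)
  idx <- match(taxa, labs)
  vals <- vapply(all_perms(length(labs)), function(p)
    bf_mntd(labs[p[idx]], D), numeric(1))
  obs <- bf_mntd(taxa, D)
  -(obs - mean(vals)) / stats::sd(vals)
}

# Exhaustive-enumeration beta-NTI for a two-community table.
bf_bnti_exact <- function(counts, D, weighted = TRUE) {
  labs <- rownames(D)
  obs <- bf_bmntd(counts[, 1], counts[, 2], D, weighted)
  vals <- vapply(all_perms(length(labs)), function(p) {
    cp <- counts
    rownames(cp) <- labs[p]  # taxon in row i relabelled to labs[p[i]]
    cp <- cp[labs, , drop = FALSE]
    bf_bmntd(cp[, 1], cp[, 2], D, weighted)
  }, numeric(1))
  (obs - mean(vals)) / stats::sd(vals)
}
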