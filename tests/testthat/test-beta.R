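test_that("bray-curtis matches hand values and bounds", {
  m <- matrix(c(1L, 2L, 0L,
                1L, 0L, 2L), ncol = 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  bc <- bray_curtis(m)
  expect_equal(bc["s1", "s2"], 2 / 3)
  expect_equal(diag(bc), c(s1 = 0, s2 = 0))

  ident <- cbind(s1 = c(A = 3L, B = 1L), s2 = c(A = 3L, B = 1L))
  expect_equal(bray_curtis(ident)["s1", "s2"], 0)

  disj <- cbind(s1 = c(A = 3L, B = 0L), s2 = c(A = 0L, B = 7L))
  expect_equal(bray_curtis(disj)["s1", "s2"], 1)

  zero <- cbind(s1 = c(A = 1L, B = 0L), s2 = c(A = 0L, B = 0L))
  expect_error(bray_curtis(zero), "s2")

  # library size does not matter: computed on relative abundances
  expect_equal(bray_curtis(m), bray_curtis(m * 10L))
})

test_that("weighted unifrac matches the two-branch hand computation", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  m <- cbind(s1 = c(A = 10L, B = 0L), s2 = c(A = 0L, B = 10L))
  expect_equal(weighted_unifrac(m, tr, normalized = FALSE)["s1", "s2"], 2)
  expect_equal(weighted_unifrac(m, tr, normalized = TRUE)["s1", "s2"], 1)

  same <- cbind(s1 = c(A = 5L, B = 5L), s2 = c(A = 50L, B = 50L))
  expect_equal(weighted_unifrac(same, tr)["s1", "s2"], 0)

  # collapsing a zero-length branch leaves the value unchanged
  tr3 <- ape::read.tree(text = "((A:1,B:2):0,C:1);")
  tr3b <- ape::read.tree(text = "(A:1,B:2,C:1);")
  m3 <- cbind(s1 = c(A = 4L, B = 1L, C = 5L), s2 = c(A = 1L, B = 6L, C = 3L))
  expect_equal(weighted_unifrac(m3, tr3)["s1", "s2"],
               suppressWarnings(weighted_unifrac(m3, tr3b))["s1", "s2"])
})

test_that("weighted unifrac agrees with phyloseq's implementation", {
  sc <- simulate_scenario("neutral", n_taxa = 25, n_samples = 6,
                          reads = 500, seed = 45)
  mine_n <- weighted_unifrac(sc$counts, sc$tree, normalized = TRUE)
  mine_r <- weighted_unifrac(sc$counts, sc$tree, normalized = FALSE)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(sc$counts, taxa_are_rows = TRUE),
    phyloseq::phy_tree(sc$tree))
  # phyloseq::UniFrac attaches its package; undo so later tests see this
  # package's read_tree again
  withr::defer({
    if ("package:phyloseq" %in% search())
      detach("package:phyloseq", character.only = TRUE)
  })
  ref_n <- as.matrix(suppressMessages(
    phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE)))
  ref_r <- as.matrix(suppressMessages(
    phyloseq::UniFrac(ps, weighted = TRUE, normalized = FALSE)))
  ids <- colnames(mine_n)
  expect_lt(max(abs(mine_n[ids, ids] - ref_n[ids, ids])), 1e-10)
  expect_lt(max(abs(mine_r[ids, ids] - ref_r[ids, ids])), 1e-10)
})

test_that("beta-MNTD matches a brute-force double loop and picante", {
  tr <- simulate_tree(6, seed = 41)
  D <- stats::cophenetic(tr)
  set.seed(42)
  m <- matrix(rpois(6 * 3, 2), 6, 3, dimnames = list(tr$tip.label,
                                                     paste0("s", 1:3)))
  m[cbind(c(1, 2), c(1, 2))] <- m[cbind(c(1, 2), c(1, 2))] + 1L
  m[, colSums(m) == 0] <- 1L
  storage.mode(m) <- "integer"
  for (wt in c(TRUE, FALSE)) {
    got <- beta_mntd(m, tr, weighted = wt)
    for (k in 1:2) for (l in (k + 1):3) {
      expect_equal(got[k, l], bf_bmntd(m[, k], m[, l], D, weighted = wt),
                   info = paste("pair", k, l, "wt", wt))
    }
  }
  ref <- as.matrix(picante::comdistnt(t(sweep(m, 2, colSums(m), "/")), D,
                                      abundance.weighted = TRUE))
  got <- beta_mntd(m, tr, weighted = TRUE)
  expect_lt(max(abs(got[rownames(ref), colnames(ref)] - ref)), 1e-12)
})

test_that("beta-MNTD identities: self-distance zero, singleton pairs patristic", {
  tr <- toy_tree()
  m <- cbind(s1 = c(A = 1L, B = 0L, C = 0L), s2 = c(A = 0L, B = 0L, C = 2L))
  expect_equal(beta_mntd(m, tr)["s1", "s2"],
               unname(stats::cophenetic(tr)["A", "C"]))
  ident <- cbind(s1 = c(A = 2L, B = 1L, C = 0L), s2 = c(A = 2L, B = 1L, C = 0L))
  expect_equal(beta_mntd(ident, tr)["s1", "s2"], 0)
})

test_that("beta metrics are permutation-equivariant in sample order", {
  sc <- simulate_scenario("neutral", n_taxa = 30, n_samples = 5,
                          reads = 400, seed = 51)
  perm <- c(3, 1, 5, 2, 4)
  sh <- sc$counts[, perm]
  for (f in list(bray_curtis,
                 function(x) beta_mntd(x, sc$tree),
                 function(x) weighted_unifrac(x, sc$tree))) {
    a <- f(sc$counts)
    b <- f(sh)
    expect_equal(b, a[perm, perm], ignore_attr = TRUE, tolerance = 1e-12)
  }
})
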