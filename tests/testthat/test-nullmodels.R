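test_that("beta-NTI matches exhaustive enumeration on a 4-tip tree", {
  tr <- balanced4()
  D <- stats::cophenetic(tr)
  counts <- matrix(0L, 4, 2, dimnames = list(tr$tip.label, c("s1", "s2")))
  counts["A", 1] <- 5L
  counts["B", 2] <- 5L
  exact <- bf_bnti_exact(counts, D)
  got <- suppressWarnings(beta_nti(counts, tr, n_null = 10000, seed = 8))
  expect_lt(abs(got["s1", "s2"] - exact), 0.15)
  expect_equal(attr(got, "bmntd_obs")["s1", "s2"], unname(D["A", "B"]))
})

test_that("beta-NTI is invariant to consistent taxon relabeling", {
  sc <- simulate_scenario("neutral", n_taxa = 25, n_samples = 4,
                          reads = 300, seed = 61)
  a <- beta_nti(sc$counts, sc$tree, n_null = 199, seed = 3)
  # rename every taxon consistently in table and tree, keeping row order
  relab <- stats::setNames(paste0("x", seq_len(25)), rownames(sc$counts))
  counts2 <- sc$counts
  rownames(counts2) <- unname(relab[rownames(sc$counts)])
  tree2 <- sc$tree
  tree2$tip.label <- unname(relab[tree2$tip.label])
  b <- beta_nti(counts2, tree2, n_null = 199, seed = 3)
  expect_equal(unname(a), unname(b))
})

test_that("degenerate distance structure is flagged as undefined", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  counts <- matrix(c(1L, 1L, 0L, 0L,
                     0L, 0L, 1L, 1L), 4,
                   dimnames = list(star$tip.label, c("s1", "s2")))
  expect_warning(z <- beta_nti(counts, star, n_null = 30, seed = 1),
                 "degenerate")
  expect_true(is.na(z["s1", "s2"]))
  expect_equal(attr(z, "n_undefined"), 1)
})

test_that("same seed gives bit-identical null-model matrices", {
  sc <- simulate_scenario("neutral", n_taxa = 40, n_samples = 6,
                          reads = 500, seed = 71)
  expect_identical(beta_nti(sc$counts, sc$tree, n_null = 99, seed = 5),
                   beta_nti(sc$counts, sc$tree, n_null = 99, seed = 5))
  expect_identical(raup_crick_bray(sc$counts, n_null = 99, seed = 5),
                   raup_crick_bray(sc$counts, n_null = 99, seed = 5))
})

test_that("RCbray respects its boundaries and sign conventions", {
  # identical single-taxon pair in a two-taxon pool: obs BC = 0, no null
  # can beat it, so RC <= 0
  m <- cbind(s1 = c(A = 5L, B = 0L), s2 = c(A = 5L, B = 0L),
             s3 = c(A = 0L, B = 5L))
  rownames(m) <- c("A", "B")
  rc <- raup_crick_bray(m, n_null = 199, seed = 2)
  expect_lte(rc["s1", "s2"], 0)
  expect_true(all(rc >= -1 & rc <= 1, na.rm = TRUE))

  # identical richer communities in a large pool: essentially no ties -> -1
  set.seed(9)
  pool <- matrix(rpois(200 * 6, 1), 200, 6,
                 dimnames = list(paste0("t", 1:200), paste0("s", 1:6)))
  pool[, 1] <- pool[, 2] <- rpois(200, 1)
  pool[1:5, ] <- pool[1:5, ] + 1L
  storage.mode(pool) <- "integer"
  rc2 <- raup_crick_bray(pool, n_null = 199, seed = 3)
  expect_lt(rc2["s1", "s2"], -0.9)

  # disjoint pair at modest richness inside a large occupied pool -> +1
  set.seed(10)
  n_t <- 300
  tab <- matrix(0L, n_t, 8, dimnames = list(paste0("t", 1:n_t),
                                            paste0("s", 1:8)))
  for (j in 3:8) tab[sample(n_t, 20), j] <- as.integer(rmultinom(1, 500, rep(1, 20)))
  tab[1:20, 1] <- 50L   # s1 and s2 occupy disjoint taxon blocks
  tab[21:40, 2] <- 50L
  rc3 <- raup_crick_bray(tab, n_null = 199, seed = 4)
  expect_gt(rc3["s1", "s2"], 0.9)
})

test_that("neutral-regime data is read as predominantly stochastic", {
  sc <- simulate_scenario("neutral", n_taxa = 150, n_samples = 15,
                          reads = 1500, seed = 81)
  bn <- beta_nti(sc$counts, sc$tree, n_null = 199, seed = 6)
  expect_gt(mean(abs(bn[upper.tri(bn)]) < 2, na.rm = TRUE), 0.8)
})

test_that("monte-carlo error shrinks with replicate count", {
  sc <- simulate_scenario("neutral", n_taxa = 60, n_samples = 6,
                          reads = 600, seed = 91)
  z1 <- beta_nti(sc$counts, sc$tree, n_null = 199, seed = 1)
  z2 <- beta_nti(sc$counts, sc$tree, n_null = 1999, seed = 2)
  z3 <- beta_nti(sc$counts, sc$tree, n_null = 1999, seed = 3)
  d_small <- mean(abs(z1 - z2)[upper.tri(z1)], na.rm = TRUE)
  d_big <- mean(abs(z3 - z2)[upper.tri(z1)], na.rm = TRUE)
  expect_lt(d_big, d_small)
})

test_that("a shared tail optimum drives communities toward phylogenetic similarity", {
  # one environmental group under strong filtering: between-sample beta-NTI
  # is pushed below -2 (homogeneous selection) for most pairs, pooled over
  # replicate worlds
  vals <- unlist(lapply(1:8, function(s) {
    tree <- simulate_tree(600, seed = s * 31)
    meta <- simulate_metacommunity(600, seed = s * 31 + 1)
    tab <- simulate_selection_table(tree, meta, env_values = rep(2, 10),
                                    sigma_w = 0.2, reads = 2000,
                                    seed = s * 31 + 2)
    bn <- suppressWarnings(beta_nti(tab, tree, n_null = 99, seed = s))
    bn[upper.tri(bn)]
  }))
  expect_gte(mean(vals < -2, na.rm = TRUE), 0.5)
})
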