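test_that("richness estimators follow the Chao1 and ACE formulas", {
  # F1 = 4, F2 = 2: classic Chao1 = SR + F1^2 / (2 F2)
  x <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  r <- richness_estimators(x)
  expect_equal(r$SR, 10)
  expect_equal(r$chao1, 14)

  # no singletons: chao1 equals SR
  r2 <- richness_estimators(c(3, 4, 2, 2))
  expect_equal(r2$chao1, r2$SR)

  # F2 = 0 uses the bias-corrected form
  r3 <- richness_estimators(c(1, 1, 1, 5, 20))
  expect_equal(r3$chao1, 5 + 3 * 2 / 2)

  # hand-evaluated ACE: all rare, no singletons -> ACE = Srare / Cace = 3
  expect_equal(richness_estimators(c(5, 5, 5))$ace, 3)

  expect_error(richness_estimators(c(0, 0)), "all-zero")
})

test_that("estimator inequalities hold across random samples", {
  set.seed(71)
  for (i in 1:25) {
    x <- rpois(60, lambda = sample(c(0.5, 2, 8), 1))
    if (sum(x) == 0) next
    r <- richness_estimators(x)
    expect_gte(r$chao1, r$SR)
    expect_gte(r$ace, r$SR - 1e-9)
    d <- diversity_indices(x)
    expect_lte(d$shannon, log(r$SR) + 1e-12)
    expect_gte(d$simpson, 0)
    expect_lt(d$simpson, 1)
  }
})

test_that("shannon and simpson match hand-computed values", {
  expect_equal(diversity_indices(c(7, 0, 0))$shannon, 0)
  expect_equal(diversity_indices(c(7, 0, 0))$simpson, 0)
  expect_equal(diversity_indices(rep(4, 8))$shannon, log(8))
  expect_equal(diversity_indices(c(2, 1, 1))$shannon, 1.5 * log(2))
  expect_equal(diversity_indices(c(2, 1, 1))$simpson, 1 - (0.25 + 2 * 0.0625))
})

test_that("merging two taxa never increases shannon entropy", {
  set.seed(5)
  for (i in 1:20) {
    x <- rpois(30, 3) + 1
    h0 <- diversity_indices(x)$shannon
    merged <- c(x[1] + x[2], x[-(1:2)])
    expect_lte(diversity_indices(merged)$shannon, h0 + 1e-12)
  }
})

test_that("faith PD sums the spanning subtree including the root stem", {
  tr <- toy_tree()  # ((A:1,B:1):1,C:2);
  expect_equal(faith_pd(c("A", "B"), tr), 3)
  expect_equal(faith_pd(c("A", "B", "C"), tr), sum(tr$edge.length))
  # monotone under adding taxa
  expect_gte(faith_pd(c("A", "B", "C"), tr), faith_pd(c("A", "B"), tr))
  expect_error(faith_pd(character(0), tr), "empty")
  expect_error(faith_pd(c("A", "Z"), tr), "not in tree")
})

test_that("NTI matches exhaustive enumeration and flags degenerate nulls", {
  # community = one cherry of a balanced 4-tip tree with long stems
  tr <- balanced4()
  D <- stats::cophenetic(tr)
  counts <- matrix(0L, 4, 2, dimnames = list(tr$tip.label, c("s1", "s2")))
  counts[c("A", "B"), 1] <- 1L
  counts[c("A", "C"), 2] <- 1L
  exact <- c(bf_nti_exact(c("A", "B"), D), bf_nti_exact(c("A", "C"), D))
  got <- nti(counts, tr, n_null = 10000, seed = 3)
  expect_lt(max(abs(got$nti - exact)), 0.15)
  expect_equal(got$mntd_obs, c(2, 10))

  # star tree with equal branch lengths: every null identical -> NA, warned
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  cs <- matrix(1L, 4, 2, dimnames = list(star$tip.label, c("s1", "s2")))
  cs["D", 1] <- 0L
  expect_warning(z <- nti(cs, star, n_null = 50, seed = 1), "degenerate")
  expect_true(all(is.na(z$nti)))
})

test_that("NTI agrees with picante's ses.mntd on a random community", {
  set.seed(13)
  tr <- simulate_tree(15, seed = 2)
  counts <- matrix(rbinom(15 * 5, 1, 0.5) * rpois(15 * 5, 4), 15, 5,
                   dimnames = list(tr$tip.label, paste0("s", 1:5)))
  counts[1:2, colSums(counts > 0) < 2] <- 1L
  storage.mode(counts) <- "integer"
  mine <- nti(counts, tr, n_null = 600, seed = 4)
  ref <- picante::ses.mntd(t((counts > 0) * 1), stats::cophenetic(tr),
                           null.model = "taxa.labels", runs = 600,
                           abundance.weighted = FALSE)
  expect_equal(mine$mntd_obs, ref$mntd.obs)
  expect_lt(max(abs(mine$nti - (-ref$mntd.obs.z)), na.rm = TRUE), 0.25)
})

test_that("NTI is approximately standard normal under uniform random draws", {
  tr <- simulate_tree(40, seed = 6)
  set.seed(91)
  n_s <- 150
  counts <- matrix(0L, 40, n_s,
                   dimnames = list(tr$tip.label, paste0("s", seq_len(n_s))))
  for (j in seq_len(n_s)) counts[sample(40, 12), j] <- 1L
  z <- nti(counts, tr, n_null = 300, seed = 7)
  expect_lt(abs(mean(z$nti)), 0.15)
  expect_lt(abs(stats::sd(z$nti) - 1), 0.25)
})

test_that("alpha_diversity assembles all indices per sample", {
  sc <- simulate_scenario("neutral", n_taxa = 40, n_samples = 6,
                          reads = 500, seed = 31)
  tab <- alpha_diversity(sc$counts, sc$tree, n_null = 99, seed = 1)
  expect_identical(tab$sample_id, colnames(sc$counts))
  expect_true(all(c("SR", "chao1", "ace", "shannon", "simpson", "pd",
                    "mntd_obs", "nti") %in% colnames(tab)))
  expect_true(all(tab$chao1 >= tab$SR))
  expect_true(all(tab$pd >= 0))
})
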