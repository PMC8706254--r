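# Synthetic communities with known assembly regimes. Every generator is a
# pure function of its seed and attaches a provenance attribute (regime,
# parameters, seed) to its output so downstream results are traceable.

provenance <- function(regime, params, seed) {
  list(regime = regime, params = params, seed = seed)
}

#' Simulate a rooted pure-birth phylogeny
#'
#' Pure-birth (Yule) tree with `n_taxa` tips, unit birth rate and tips
#' labelled `t1..tn`. Deterministic given `seed`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An [ape::phylo] object.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  with_seed(seed, {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tree$tip.label <- paste0("t", seq_len(n_taxa))
    tree
  })
}

#' Simulate a log-normal metacommunity
#'
#' Relative abundances proportional to `exp(Normal(0, sad_sigma^2))`,
#' normalized to sum to 1 — the log-normal species-abundance distribution
#' the regional species pool is assumed to follow.
#'
#' @param n_taxa Number of taxa.
#' @param sad_sigma Log-scale standard deviation of the abundance
#'   distribution (default 1.5, a broad soil-community spread).
#' @param seed Integer seed.
#' @return Named numeric vector of relative abundances summing to 1.
#' @export
simulate_metacommunity <- function(n_taxa, sad_sigma = 1.5, seed = 1) {
  if (sad_sigma < 0) stop("sad_sigma must be >= 0")
  with_seed(seed, {
    lp <- stats::rnorm(n_taxa, 0, sad_sigma)
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    names(p) <- paste0("t", seq_len(n_taxa))
    p
  })
}

#' Simulate a neutral (Sloan) community table
#'
#' Each sample's composition is drawn from a Dirichlet distribution with
#' concentration `Nm * p` — the stationary distribution of Sloan's neutral
#' local-community model, in which `Nm` is the product of local community
#' size and migration rate — and reads are then drawn multinomially.
#' Fitting the neutral model to the output should therefore recover
#' `m = Nm / reads`.
#'
#' @param meta Metacommunity relative-abundance vector
#'   (see [simulate_metacommunity()]).
#' @param Nm Immigration parameter (> 0).
#' @param n_samples Number of samples.
#' @param reads Sequencing depth per sample.
#' @param seed Integer seed.
#' @return Taxa-by-samples integer matrix with a `provenance` attribute.
#' @export
simulate_neutral_table <- function(meta, Nm, n_samples, reads, seed = 1) {
  if (Nm <= 0) stop("Nm must be > 0")
  with_seed(seed, {
    n_taxa <- length(meta)
    counts <- matrix(0L, n_taxa, n_samples,
                     dimnames = list(names(meta), paste0("s", seq_len(n_samples))))
    alpha <- Nm * meta
    for (j in seq_len(n_samples)) {
      g <- stats::rgamma(n_taxa, shape = alpha, rate = 1)
      if (sum(g) == 0) g[which.max(meta)] <- 1  # guard vanishing gamma draws
      counts[, j] <- stats::rmultinom(1, reads, g / sum(g))
    }
    structure(counts, provenance = provenance("neutral",
      list(Nm = Nm, n_samples = n_samples, reads = reads), seed))
  })
}

#' Simulate a selection-structured community table
#'
#' A trait evolves on the tree by Brownian motion (so ecological filtering
#' is phylogenetically autocorrelated); the sampling weight of taxon i in
#' sample j is `p_i * exp(-(trait_i - env_j)^2 / (2 sigma_w^2))` and counts
#' are multinomial. Samples sharing an environment experience homogeneous
#' selection; samples with contrasting environments, variable selection.
#' Traits are standardized to zero mean and unit variance across taxa, so
#' `env_values` and `sigma_w` are in trait standard-deviation units.
#'
#' @param tree Phylogeny over the metacommunity's taxa.
#' @param meta Metacommunity relative-abundance vector.
#' @param env_values Numeric vector, one environmental optimum per sample.
#' @param sigma_w Niche width (> 0); small values mean strong filtering.
#' @param reads Sequencing depth per sample.
#' @param seed Integer seed.
#' @return Taxa-by-samples integer matrix with a `provenance` attribute.
#' @export
simulate_selection_table <- function(tree, meta, env_values, sigma_w,
                                     reads, seed = 1) {
  if (sigma_w <= 0) stop("sigma_w must be > 0")
  stopifnot(all(names(meta) %in% tree$tip.label))
  with_seed(seed, {
    trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    trait <- (trait - mean(trait)) / stats::sd(trait)
    trait <- trait[names(meta)]
    n_samples <- length(env_values)
    counts <- matrix(0L, length(meta), n_samples,
                     dimnames = list(names(meta), paste0("s", seq_len(n_samples))))
    for (j in seq_len(n_samples)) {
      w <- meta * exp(-(trait - env_values[j])^2 / (2 * sigma_w^2))
      if (sum(w) == 0) w <- meta * (abs(trait - env_values[j]) ==
                                      min(abs(trait - env_values[j])))
      counts[, j] <- stats::rmultinom(1, reads, w / sum(w))
    }
    structure(counts, provenance = provenance("selection",
      list(sigma_w = sigma_w, env_values = env_values, reads = reads), seed))
  })
}

#' Simulate a dispersal-limited community table
#'
#' Taxa are assigned at random (no phylogenetic structure) to patch pools
#' that share a fraction `overlap` of their taxa; each sample draws its
#' reads multinomially from its own patch pool only. Between-patch pairs
#' then show stochastic turnover in excess of the null (high RCbray) with
#' no phylogenetic signal (|betaNTI| < 2) — the dispersal-limitation
#' signature.
#'
#' @param meta Metacommunity relative-abundance vector.
#' @param n_patches Number of isolated patches (>= 2).
#' @param overlap Fraction of each patch pool shared by all patches
#'   (0 <= overlap < 1).
#' @param samples_per_patch Samples drawn from each patch.
#' @param reads Sequencing depth per sample.
#' @param pool_size Taxa per patch pool (default: floor of
#'   `length(meta) / n_patches` adjusted for overlap).
#' @param seed Integer seed.
#' @return Taxa-by-samples integer matrix with `provenance` and
#'   `patch` (per-sample patch id) attributes.
#' @export
simulate_dispersal_limited_table <- function(meta, n_patches, overlap,
                                             samples_per_patch, reads,
                                             pool_size = NULL, seed = 1) {
  if (n_patches < 2) stop("n_patches must be >= 2")
  if (overlap < 0 || overlap >= 1)
    stop("overlap must be in [0, 1); overlap = 1 is the neutral limit")
  with_seed(seed, {
    n_taxa <- length(meta)
    if (is.null(pool_size)) {
      # choose the largest pool such that shared + exclusive parts fit
      pool_size <- floor(n_taxa / (overlap + n_patches * (1 - overlap)))
    }
    n_shared <- round(overlap * pool_size)
    n_excl <- pool_size - n_shared
    if (n_shared + n_patches * n_excl > n_taxa)
      stop("metacommunity too small for requested pools")
    perm <- sample.int(n_taxa)
    shared <- perm[seq_len(n_shared)]
    rest <- if (n_shared > 0) perm[-seq_len(n_shared)] else perm
    pools <- lapply(seq_len(n_patches), function(k)
      c(shared, rest[((k - 1) * n_excl + 1):(k * n_excl)]))
    n_samples <- n_patches * samples_per_patch
    counts <- matrix(0L, n_taxa, n_samples,
                     dimnames = list(names(meta), paste0("s", seq_len(n_samples))))
    patch <- rep(seq_len(n_patches), each = samples_per_patch)
    for (j in seq_len(n_samples)) {
      pool <- pools[[patch[j]]]
      w <- meta[pool] / sum(meta[pool])
      counts[pool, j] <- stats::rmultinom(1, reads, w)
    }
    structure(counts, patch = patch, provenance = provenance(
      "dispersal_limited",
      list(n_patches = n_patches, overlap = overlap, pool_size = pool_size,
           samples_per_patch = samples_per_patch, reads = reads), seed))
  })
}

#' Simulate study-design metadata
#'
#' Emulates an altitudinal soil transect: `n_elevations` sites x 3 soil
#' layers (surface/middle/deep) x `replicates` cores, with coordinates along
#' a short latitudinal transect and soil chemistry (pH, EC, SOM, TN, AN,
#' NH4, NO3, TP, AP) responding smoothly to elevation and depth plus noise.
#' Defaults reproduce a 7 x 3 x 3 = 63-sample design spanning 889-3837 m.
#'
#' @param sample_ids Sample ids to attach (length must equal the design
#'   size); defaults to `s1..sn`.
#' @param elevations Site elevations in meters.
#' @param replicates Cores per site x layer.
#' @param seed Integer seed.
#' @return A metadata data.frame (see [read_metadata()] for columns).
#' @export
simulate_metadata <- function(sample_ids = NULL,
                              elevations = c(889, 1297, 1660, 1789, 1812, 3350, 3837),
                              replicates = 3, seed = 1) {
  layers <- c("surface", "middle", "deep")
  design <- expand.grid(rep = seq_len(replicates), layer = layers,
                        elevation = elevations, stringsAsFactors = FALSE)
  n <- nrow(design)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (length(sample_ids) != n) stop("sample_ids length must be ", n)
  with_seed(seed, {
    depth_idx <- match(design$layer, layers) - 1  # 0,1,2
    e_km <- design$elevation / 1000
    md <- data.frame(
      sample_id = sample_ids,
      elevation = design$elevation,
      layer = design$layer,
      latitude = 26.2 + (design$elevation - 889) / (3837 - 889) * 1.9 +
        stats::rnorm(n, 0, 0.005),
      longitude = 98.5 + stats::rnorm(n, 0, 0.05),
      pH = 7.8 - 0.6 * e_km + 0.15 * depth_idx + stats::rnorm(n, 0, 0.15),
      EC = 110 - 15 * e_km + 12 * depth_idx + stats::rnorm(n, 0, 8),
      SOM = 45 + 8 * e_km - 10 * depth_idx + stats::rnorm(n, 0, 4),
      TN = 1.2 + 0.3 * e_km + 0.15 * depth_idx + stats::rnorm(n, 0, 0.1),
      AN = 90 + 15 * e_km + 8 * depth_idx + stats::rnorm(n, 0, 8),
      NH4 = 12 + 2 * e_km - 2 * depth_idx + stats::rnorm(n, 0, 1.5),
      NO3 = 6 + stats::rnorm(n, 0, 1.2),
      TP = 0.6 + 0.05 * depth_idx + stats::rnorm(n, 0, 0.06),
      AP = 8 + 1.5 * e_km + 1 * depth_idx + stats::rnorm(n, 0, 1),
      stringsAsFactors = FALSE
    )
    rownames(md) <- md$sample_id
    md
  })
}

#' Simulate a full assembly scenario
#'
#' Convenience wrapper producing an aligned (table, tree, metadata) triple
#' under one of the known assembly regimes, ready for the full pipeline.
#' For the `selection` regime, samples are split into two equal
#' environmental groups with optima `+/- env_contrast` (set
#' `env_contrast = 0` for homogeneous selection); group membership is
#' recorded in the metadata column `env_group`. For `dispersal_limited`,
#' patch membership is recorded in `patch`.
#'
#' @param regime One of `"neutral"`, `"selection"`, `"dispersal_limited"`.
#' @param n_taxa Metacommunity size.
#' @param n_samples Number of samples (default 63: 7 sites x 3 layers x 3
#'   replicates).
#' @param reads Reads per sample (default 66000, a typical amplicon depth).
#' @param sad_sigma Metacommunity log-normal spread.
#' @param m Migration rate for the neutral regime (`Nm = m * reads`).
#' @param sigma_w,env_contrast Selection-regime niche width and group
#'   optimum separation, in trait-SD units.
#' @param n_patches,overlap Dispersal-regime patch count and pool overlap.
#' @param seed Integer seed.
#' @return List with `counts`, `tree`, `metadata`, `provenance`.
#' @export
simulate_scenario <- function(regime = c("neutral", "selection", "dispersal_limited"),
                              n_taxa = 1000, n_samples = 63, reads = 66000,
                              sad_sigma = 1.5, m = 0.1,
                              sigma_w = 0.3, env_contrast = 1.5,
                              n_patches = 2, overlap = 0.2, seed = 1) {
  regime <- match.arg(regime)
  tree <- simulate_tree(n_taxa, seed = stage_seed(seed, "tree"))
  meta <- simulate_metacommunity(n_taxa, sad_sigma,
                                 seed = stage_seed(seed, "metacommunity"))
  tseed <- stage_seed(seed, "table")
  patch <- NULL
  env_group <- NULL
  if (regime == "neutral") {
    counts <- simulate_neutral_table(meta, Nm = m * reads, n_samples = n_samples,
                                     reads = reads, seed = tseed)
  } else if (regime == "selection") {
    env_group <- rep(c("low", "high"), length.out = n_samples)
    env <- ifelse(env_group == "low", -env_contrast, env_contrast)
    counts <- simulate_selection_table(tree, meta, env, sigma_w, reads,
                                       seed = tseed)
  } else {
    samples_per_patch <- ceiling(n_samples / n_patches)
    counts <- simulate_dispersal_limited_table(meta, n_patches, overlap,
                                               samples_per_patch, reads,
                                               seed = tseed)
    patch <- attr(counts, "patch")
    keep <- seq_len(min(n_samples, ncol(counts)))
    counts <- counts[, keep, drop = FALSE]
    patch <- patch[keep]
  }
  reps <- max(3, ceiling(ncol(counts) / 21))
  md <- simulate_metadata(seed = stage_seed(seed, "metadata"),
                          replicates = reps)
  md <- md[seq_len(ncol(counts)), , drop = FALSE]
  md$sample_id <- colnames(counts)
  rownames(md) <- md$sample_id
  if (!is.null(patch)) md$patch <- paste0("patch", patch)
  if (!is.null(env_group)) md$env_group <- env_group
  al <- align_inputs(counts, tree, md)
  al$provenance <- attr(counts, "provenance")
  al$metacommunity <- meta
  al
}
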