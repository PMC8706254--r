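# Internal helpers shared across modules.

# Relative abundances by sample (columns). Errors on zero-total samples so
# downstream dissimilarities are never silently NaN.
rel_abund <- function(counts) {
  tot <- colSums(counts)
  bad <- names(tot)[tot == 0]
  if (length(bad) > 0)
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  sweep(counts, 2, tot, "/")
}

# Row-wise minima of a numeric matrix via max.col (C-level, no apply loop).
row_mins <- function(m) {
  if (ncol(m) == 1L) return(as.vector(m))
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

# Deterministic per-stage seed derived from a global seed and a stage name,
# kept below 2^31 so it is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Symmetric matrix constructor from a function applied to index pairs is not
# needed; but several modules share this validator.
check_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integral")
  invisible(counts)
}

upper_tri_vec <- function(m) m[upper.tri(m)]
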