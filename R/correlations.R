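# Environmental / geographic distance matrices and Mantel tests.

#' Standardized Euclidean environmental distance
#'
#' Each named variable is z-scored across samples, then pairwise Euclidean
#' distance is taken on the z-scores. Zero-variance variables are dropped
#' with a warning.
#'
#' @param metadata Metadata data.frame (rows = samples; see
#'   [read_metadata()]).
#' @param variables Character vector of numeric metadata columns.
#' @return Symmetric samples-by-samples distance matrix.
#' @export
env_distance <- function(metadata, variables) {
  missing <- setdiff(variables, colnames(metadata))
  if (length(missing) > 0)
    stop("variables not in metadata: ", paste(missing, collapse = ", "))
  x <- as.matrix(metadata[, variables, drop = FALSE])
  if (!is.numeric(x)) stop("environmental variables must be numeric")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(variables[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) == 0) stop("no variables left after dropping")
  }
  z <- scale(x)
  m <- as.matrix(stats::dist(z))
  dimnames(m) <- list(metadata$sample_id, metadata$sample_id)
  m
}

#' Geographic distance between samples
#'
#' Great-circle distance in km by the haversine formula on a 6371-km
#' sphere (default), or plain Euclidean distance on raw decimal-degree
#' coordinates.
#'
#' @param metadata Metadata data.frame with `latitude` and `longitude`.
#' @param mode `"haversine_km"` or `"euclidean_degrees"`.
#' @return Symmetric samples-by-samples distance matrix.
#' @export
geo_distance <- function(metadata, mode = c("haversine_km", "euclidean_degrees")) {
  mode <- match.arg(mode)
  lat <- metadata$latitude
  lon <- metadata$longitude
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates out of range")
  if (mode == "haversine_km") {
    n <- nrow(metadata)
    pts <- cbind(lon, lat)
    m <- matrix(0, n, n)
    for (i in seq_len(n))
      m[i, ] <- geosphere::distHaversine(pts[i, , drop = FALSE], pts,
                                         r = 6371000) / 1000
    m <- (m + t(m)) / 2
  } else {
    m <- as.matrix(stats::dist(cbind(lat, lon)))
  }
  dimnames(m) <- list(metadata$sample_id, metadata$sample_id)
  m
}

#' Mantel test between two distance matrices
#'
#' Permutation Mantel test via [vegan::mantel()]: `r` is the Pearson or
#' Spearman correlation of the off-diagonal entries and
#' `p = (1 + #{permuted r >= observed}) / (1 + n_perm)` under joint
#' row/column permutation of the second matrix (one-sided "greater", the
#' distance-decay convention; `alternative = "two.sided"` recomputes p from
#' the permutation distribution of |r|).
#'
#' @param dx,dy Symmetric distance matrices over the same samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm Number of permutations (default 9999).
#' @param alternative `"greater"` or `"two.sided"`.
#' @param seed Integer seed.
#' @return List with `r`, `p`, `n_perm`, `method`, `alternative`.
#' @export
mantel_test <- function(dx, dy, method = c("pearson", "spearman"),
                        n_perm = 9999, alternative = c("greater", "two.sided"),
                        seed = 1) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  check_matched(dx, dy)
  res <- with_seed(seed,
    vegan::mantel(stats::as.dist(dx), stats::as.dist(dy), method = method,
                  permutations = n_perm))
  p <- if (alternative == "greater") res$signif
       else (1 + sum(abs(res$perm) >= abs(res$statistic))) / (1 + n_perm)
  list(r = unname(res$statistic), p = p, n_perm = n_perm, method = method,
       alternative = alternative)
}

#' Partial Mantel test controlling a third matrix
#'
#' Correlation of `dx` and `dy` with the effect of `dz` partialled out
#' (residual correlation of upper triangles), with permutation p-value, via
#' [vegan::mantel.partial()].
#'
#' @inheritParams mantel_test
#' @param dz Distance matrix to control for.
#' @param n_perm Number of permutations (default 999).
#' @return List with `r`, `p`, `n_perm`, `method`.
#' @export
partial_mantel_test <- function(dx, dy, dz, method = c("pearson", "spearman"),
                                n_perm = 999, seed = 1) {
  method <- match.arg(method)
  check_matched(dx, dy)
  check_matched(dx, dz)
  res <- with_seed(seed,
    vegan::mantel.partial(stats::as.dist(dx), stats::as.dist(dy),
                          stats::as.dist(dz), method = method,
                          permutations = n_perm))
  r <- unname(res$statistic)
  p <- res$signif
  if (!is.finite(r)) {
    warning("partial correlation undefined (control matrix collinear with dy)")
    r <- NA_real_
    p <- NA_real_
  }
  list(r = r, p = p, n_perm = n_perm, method = method)
}

check_matched <- function(a, b) {
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("distance matrices cover different samples")
  if (nrow(a) != nrow(b)) stop("distance matrices differ in size")
  if (nrow(a) < 4) stop("need >= 4 samples for a permutation test")
  invisible(TRUE)
}
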