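# Sloan's neutral community model: occurrence frequency vs mean relative
# abundance, fit by nonlinear least squares on the migration rate m.

#' Predicted detection frequency under Sloan's neutral model
#'
#' The neutral stationary distribution of a taxon's local relative
#' abundance is `Beta(N m p, N m (1 - p))`; its predicted detection
#' frequency at detection limit `d` is `1 - pbeta(d, N m p, N m (1 - p))`.
#'
#' The default detection threshold accounts for read sampling: a taxon at
#' relative abundance `x` is missed by `N` reads with probability
#' `(1 - x)^N`, so the threshold matching a 50% detection chance is
#' `d = 1 - 2^(-1/N)` (approximately `ln(2)/N`). Pass `d = 1/N` for the
#' simple reciprocal-depth convention.
#'
#' @param p Metacommunity mean relative abundances.
#' @param m Migration rate in (0, 1].
#' @param N Community size (mean reads per sample).
#' @param d Detection threshold (default `1 - 2^(-1/N)`).
#' @return Predicted frequencies in `[0, 1]`.
#' @export
sloan_predict <- function(p, m, N, d = 1 - 2^(-1 / N)) {
  stats::pbeta(d, N * m * p, N * m * (1 - p), lower.tail = FALSE)
}

#' Fit the Sloan model to (abundance, frequency) pairs
#'
#' Low-level fitting core: finds the migration rate `m` in (0, 1]
#' minimizing the sum of squared deviations between observed and predicted
#' frequencies (one-parameter nonlinear least squares by golden-section /
#' parabolic search), and computes the generalized
#' `R^2 = 1 - SS_res / SS_tot`. The 95% neutral band around the prediction
#' uses Wilson score intervals at `n_samples` trials (`ci = "wilson"`), or
#' Clopper-Pearson exact intervals (`ci = "exact"`).
#'
#' @param p Mean relative abundance per taxon.
#' @param freq Observed detection frequency per taxon, in `[0, 1]`.
#' @param N Community size (mean reads per sample).
#' @param n_samples Number of samples behind `freq`.
#' @param d Detection threshold (default `1 - 2^(-1/N)`, the read-sampling
#'   threshold; see [sloan_predict()]).
#' @param ci Confidence-band method.
#' @return List with `m`, `r2`, `N`, `d`, and a per-taxon data.frame
#'   `taxa` (`p`, `freq`, `predicted`, `lower`, `upper`, `partition`).
#' @export
fit_ncm_curve <- function(p, freq, N, n_samples, d = 1 - 2^(-1 / N),
                          ci = c("wilson", "exact")) {
  ci <- match.arg(ci)
  if (length(p) != length(freq)) stop("p and freq must have equal length")
  if (length(p) < 2) stop("need >= 2 taxa to fit")
  sse <- function(m) sum((freq - sloan_predict(p, m, N, d))^2)
  opt <- stats::optimize(sse, interval = c(1e-6, 1), tol = 1e-9)
  m <- opt$minimum
  pred <- sloan_predict(p, m, N, d)
  ss_res <- sum((freq - pred)^2)
  ss_tot <- sum((freq - mean(freq))^2)
  r2 <- 1 - ss_res / ss_tot
  band <- if (ci == "wilson") wilson_band(pred, n_samples)
          else exact_band(pred, n_samples)
  partition <- ifelse(freq > band$upper + 1e-9, "above",
                      ifelse(freq < band$lower - 1e-9, "below", "neutral"))
  list(m = m, r2 = r2, N = N, d = d, n_samples = n_samples,
       taxa = data.frame(p = p, freq = freq, predicted = pred,
                         lower = band$lower, upper = band$upper,
                         partition = partition, stringsAsFactors = FALSE))
}

wilson_band <- function(phat, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(center - half, 0), upper = pmin(center + half, 1))
}

exact_band <- function(phat, n, level = 0.95) {
  a <- (1 - level) / 2
  x <- phat * n
  list(lower = stats::qbeta(a, x, n - x + 1),
       upper = stats::qbeta(1 - a, x + 1, n - x))
}

#' Fit Sloan's neutral community model to a count table
#'
#' `N` is the mean reads per sample, `d` the read-sampling detection
#' threshold `1 - 2^(-1/N)` (see [sloan_predict()]), `p_i` the mean of
#' per-sample relative abundances and `f_i` the fraction of samples in
#' which taxon i was detected (count >= 1). The migration rate `m` is the
#' nonlinear least-squares fit of the predicted frequency curve; taxa are
#' partitioned as above / neutral / below the 95% band around the
#' prediction.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param ci Confidence-band method (`"wilson"` or `"exact"`).
#' @return An `ncm_fit` list: `m`, `r2`, `N`, `d`, `n_samples`, `taxa`
#'   (per-OTU data.frame with rownames = taxon ids).
#' @export
fit_ncm <- function(counts, ci = "wilson") {
  check_count_matrix(counts)
  n_samples <- ncol(counts)
  if (n_samples < 10)
    warning("fewer than 10 samples; the neutral fit will be unstable")
  if (nrow(counts) < 2) stop("need >= 2 taxa")
  rel <- rel_abund(counts)
  p <- rowMeans(rel)
  keep <- p > 0
  p <- p[keep]
  freq <- rowMeans(counts[keep, , drop = FALSE] > 0)
  N <- mean(colSums(counts))
  fit <- fit_ncm_curve(p, freq, N, n_samples, ci = ci)
  rownames(fit$taxa) <- rownames(counts)[keep]
  class(fit) <- "ncm_fit"
  fit
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.4f, R2 = %.4f, N = %.1f, d = %.2e, samples = %d\n",
              x$m, x$r2, x$N, x$d, x$n_samples))
  cat("  taxa partition:",
      paste(names(table(x$taxa$partition)), table(x$taxa$partition),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Fit the neutral model independently within sample groups
#'
#' Refits [fit_ncm()] inside each group (e.g. soil layer), enabling
#' comparisons of migration rates across groups. Groups with fewer than
#' `min_samples` samples are skipped with a warning.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param grouping Named character vector mapping sample id to group.
#' @param min_samples Minimum group size (default 3).
#' @param ci Confidence-band method.
#' @return Named list of `ncm_fit` objects (skipped groups absent).
#' @export
ncm_per_group <- function(counts, grouping, min_samples = 3, ci = "wilson") {
  check_count_matrix(counts)
  if (!all(colnames(counts) %in% names(grouping)))
    stop("every sample must be mapped to a group")
  groups <- split(colnames(counts), grouping[colnames(counts)])
  fits <- list()
  for (g in names(groups)) {
    if (length(groups[[g]]) < min_samples) {
      warning("group '", g, "' has fewer than ", min_samples,
              " samples; skipped")
      next
    }
    sub <- counts[, groups[[g]], drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    fits[[g]] <- suppressWarnings(fit_ncm(sub, ci = ci))
  }
  fits
}
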