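# Five-process assembly classification from (beta-NTI, RCbray).

PROCESSES <- c("variable_selection", "homogeneous_selection",
               "dispersal_limitation", "homogenizing_dispersal", "undominated")

#' Classify one sample pair into an assembly process
#'
#' Deterministic threshold rules: `bnti > 2` means variable selection,
#' `bnti < -2` homogeneous selection (selection takes precedence over the
#' Raup-Crick value). Otherwise the pair is stochastic and `rc > 0.95`
#' means dispersal limitation, `rc < -0.95` homogenizing dispersal, and
#' `|rc| <= 0.95` undominated (ecological drift). Boundary values
#' (`bnti = +/-2`, `rc = +/-0.95`) fall to the stochastic / undominated
#' side, since only values *exceeding* the thresholds signal a dominant
#' process.
#'
#' @param bnti Finite beta-NTI value.
#' @param rc Finite RCbray value.
#' @return One of `"variable_selection"`, `"homogeneous_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`, `"undominated"`.
#' @export
classify_pair <- function(bnti, rc) {
  if (!is.finite(bnti) || !is.finite(rc)) stop("bnti and rc must be finite")
  if (bnti > 2) return("variable_selection")
  if (bnti < -2) return("homogeneous_selection")
  if (rc > 0.95) return("dispersal_limitation")
  if (rc < -0.95) return("homogenizing_dispersal")
  "undominated"
}

#' Classify all sample pairs and summarize process fractions by group
#'
#' Applies [classify_pair()] to every off-diagonal pair of the beta-NTI and
#' RCbray matrices, then aggregates percentages per sample group. With
#' `scheme = "within_group"` only pairs whose two samples share a group are
#' counted (the grouping a soil-layer or elevation comparison needs); with
#' `"all_pairs"` every pair is assigned to the single group `"all"`.
#' Pairs with undefined (NA) beta-NTI or RCbray are excluded and reported.
#'
#' @param bnti Symmetric beta-NTI matrix (see [beta_nti()]).
#' @param rc Symmetric RCbray matrix (see [raup_crick_bray()]).
#' @param grouping Named character vector mapping sample id to group, or
#'   `NULL` (treated as one group).
#' @param scheme `"within_group"` or `"all_pairs"`.
#' @return List with `pairs` (long data.frame: sample_1, sample_2, bnti,
#'   rc, process, group) and `summary` (per-group data.frame of process
#'   percentages, `stochastic_pct` = 100 x fraction with |bnti| < 2,
#'   `n_pairs`, `n_undefined`).
#' @export
partition_fractions <- function(bnti, rc, grouping = NULL,
                                scheme = c("within_group", "all_pairs")) {
  scheme <- match.arg(scheme)
  ids <- rownames(bnti)
  if (!identical(ids, rownames(rc)))
    stop("bnti and rc matrices must cover the same samples")
  if (is.null(grouping)) {
    grouping <- stats::setNames(rep("all", length(ids)), ids)
    scheme <- "all_pairs"
  }
  if (!all(ids %in% names(grouping)))
    stop("every sample must be mapped to a group")
  ut <- which(upper.tri(bnti), arr.ind = TRUE)
  pairs <- data.frame(
    sample_1 = ids[ut[, 1]], sample_2 = ids[ut[, 2]],
    bnti = bnti[ut], rc = rc[ut], stringsAsFactors = FALSE)
  pairs$group <- if (scheme == "all_pairs") "all" else
    ifelse(grouping[pairs$sample_1] == grouping[pairs$sample_2],
           unname(grouping[pairs$sample_1]), NA_character_)
  defined <- is.finite(pairs$bnti) & is.finite(pairs$rc)
  pairs$process <- NA_character_
  pairs$process[defined] <- vapply(which(defined), function(i)
    classify_pair(pairs$bnti[i], pairs$rc[i]), character(1))
  keep <- pairs[!is.na(pairs$group), , drop = FALSE]
  groups <- unique(stats::na.omit(keep$group))
  summary <- do.call(rbind, lapply(groups, function(g) {
    sub <- keep[keep$group == g, , drop = FALSE]
    ok <- sub[!is.na(sub$process), , drop = FALSE]
    n <- nrow(ok)
    pct <- if (n > 0)
      100 * vapply(PROCESSES, function(p) mean(ok$process == p), numeric(1))
    else stats::setNames(rep(NA_real_, 5), PROCESSES)
    out <- data.frame(group = g, t(pct), n_pairs = n,
                      n_undefined = nrow(sub) - n,
                      stringsAsFactors = FALSE, check.names = FALSE)
    out$stochastic_pct <- if (n > 0)
      100 * mean(!ok$process %in% c("variable_selection",
                                    "homogeneous_selection"))
    else NA_real_
    out
  }))
  rownames(summary) <- NULL
  list(pairs = pairs, summary = summary)
}
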