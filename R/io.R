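#' Read an OTU count table
#'
#' Reads a tab-separated taxa-by-samples count table (the common OTU-table
#' dialect: first column taxon ids, header row sample ids). Cells must be
#' non-negative integers.
#'
#' @param path Path to a TSV file.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`; the latter
#'   transposes the file after reading.
#' @return An integer matrix with taxon rownames and sample colnames.
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr)) stop("duplicate ids in header row")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs an id column plus >= 1 data column")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(ids))
    stop("duplicate ", if (orientation == "taxa_rows") "taxon" else "sample",
         " ids in first column")
  if (anyDuplicated(colnames(m))) stop("duplicate ids in header row")
  if (!is.numeric(m)) {
    bad <- which(!vapply(seq_len(ncol(m)), function(j)
      is.numeric(raw[[j + 1]]), logical(1)))[1]
    stop("non-numeric cells in column '", colnames(m)[bad], "'")
  }
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative count at taxon '", rownames(m)[idx[1]],
         "', sample '", colnames(m)[idx[2]], "'")
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    idx <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("non-integer count at taxon '", rownames(m)[idx[1]],
         "', sample '", colnames(m)[idx[2]], "'")
  }
  storage.mode(m) <- "integer"
  check_count_matrix(m)
  m
}

#' Write an OTU count table
#'
#' @param counts Taxa-by-samples count matrix.
#' @param path Output TSV path.
#' @param id_column Name for the taxon-id column.
#' @export
write_count_table <- function(counts, path, id_column = "OTU_ID") {
  check_count_matrix(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream phylogenetic
#' metrics rely on: unique tip labels, non-negative branch lengths, and a
#' root. Missing branch lengths are replaced by `default_length` with a
#' warning.
#'
#' @param path Newick file path.
#' @param default_length Value substituted for missing branch lengths.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path, default_length = 0) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree in file")
  validate_tree(tree, default_length = default_length)
}

validate_tree <- function(tree, default_length = 0) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using default ", default_length)
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("tree has missing branch lengths; using default ", default_length)
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Read per-sample metadata
#'
#' TSV with mandatory columns `sample_id`, `elevation`, `layer`, `latitude`,
#' `longitude`; any remaining numeric columns are treated as environmental
#' variables (soil chemistry etc.).
#'
#' @param path TSV file path.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "elevation", "layer", "latitude", "longitude")
  missing <- setdiff(required, colnames(md))
  if (length(missing) > 0)
    stop("metadata missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  ok_layers <- c("surface", "middle", "deep")
  if (!all(md$layer %in% ok_layers))
    stop("layer must be one of: ", paste(ok_layers, collapse = ", "))
  rownames(md) <- md$sample_id
  md
}

#' Align a count table, a tree and metadata onto common taxa and samples
#'
#' Taxa are restricted to the intersection of the table's rownames and the
#' tree's tips (ITS OTU tables routinely exceed the reference tree, so extra
#' taxa are dropped with a message rather than an error). Samples are
#' restricted to the intersection of the table's columns and the metadata.
#' All orderings are lexicographic so outputs are byte-stable.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param tree An [ape::phylo] object, or `NULL` to skip taxon filtering.
#' @param metadata Metadata data.frame (see [read_metadata()]), or `NULL`.
#' @return A list with elements `counts`, `tree`, `metadata`,
#'   `dropped_taxa` (count) and `dropped_samples` (count).
#' @export
align_inputs <- function(counts, tree = NULL, metadata = NULL) {
  check_count_matrix(counts)
  taxa <- rownames(counts)
  dropped_taxa <- 0L
  if (!is.null(tree)) {
    keep <- intersect(taxa, tree$tip.label)
    if (length(keep) == 0) stop("no taxa shared between table and tree")
    dropped_taxa <- length(taxa) - length(keep)
    if (dropped_taxa > 0)
      message(dropped_taxa, " taxa in table but not in tree were dropped")
    taxa <- keep
    tree <- ape::keep.tip(tree, keep)
  }
  samples <- colnames(counts)
  dropped_samples <- 0L
  if (!is.null(metadata)) {
    keep <- intersect(samples, metadata$sample_id)
    if (length(keep) == 0) stop("no samples shared between table and metadata")
    dropped_samples <- length(samples) - length(keep)
    samples <- keep
    metadata <- metadata[sort(samples), , drop = FALSE]
  }
  taxa <- sort(taxa)
  samples <- sort(samples)
  counts <- counts[taxa, samples, drop = FALSE]
  list(counts = counts, tree = tree, metadata = metadata,
       dropped_taxa = dropped_taxa, dropped_samples = dropped_samples)
}

#' Write / read a square pairwise matrix as TSV
#'
#' @param m Symmetric numeric matrix with sample ids as dimnames.
#' @param path TSV path.
#' @export
write_pairwise_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairwise_matrix
#' @export
read_pairwise_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!identical(rownames(m), colnames(m)))
    stop("pairwise matrix rownames and colnames disagree")
  m
}
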