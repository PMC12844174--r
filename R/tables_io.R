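#' Read an ASV feature table from a tab-separated file
#'
#' The on-disk layout follows the classic QIIME convention: taxa as rows,
#' samples as columns, with the first column holding taxon identifiers.
#' In memory the table is held samples-as-rows, the orientation every
#' downstream statistic uses.
#'
#' @param path path to a TSV file; first column taxon ids, remaining columns
#'   one per sample, integer counts.
#' @return integer matrix (samples x taxa) with unique dimnames.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    stop_("feature table file not found: %s", path, class = "io_error")
  raw <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "", quote = "")
  if (ncol(raw) < 2L)
    stop_("feature table needs a taxon-id column plus >= 1 sample column",
          class = "format_error")
  taxa <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(taxa))
    stop_("duplicated taxon id(s): %s",
          paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
          class = "format_error")
  if (anyDuplicated(samples))
    stop_("duplicated sample column(s): %s",
          paste(unique(samples[duplicated(samples)]), collapse = ", "),
          class = "format_error")
  num <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw), dimnames = list(taxa, samples))
  bad <- !is.finite(num) | num < 0 | num != round(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_("cell [taxon %s, sample %s] is not a non-negative integer count",
          taxa[idx[1L]], samples[idx[2L]], class = "format_error")
  }
  t(matrix(as.integer(num), nrow = nrow(raw), dimnames = list(taxa, samples)))
}

#' Write a feature table as TSV (taxa rows x sample columns)
#'
#' @param table integer matrix, samples x taxa.
#' @param path output path.
#' @param id_column header for the taxon-id column.
#' @export
write_feature_table <- function(table, path, id_column = "taxon_id") {
  validate_feature_table(table)
  out <- data.frame(t(table), check.names = FALSE)
  out <- cbind(setNames(data.frame(colnames(table)), id_column), out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a feature table held in memory
#'
#' @param table samples x taxa matrix.
#' @return the table, invisibly, if valid.
#' @export
validate_feature_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop_("feature table must be a numeric matrix (samples x taxa)",
          class = "format_error")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop_("feature table must carry sample and taxon names", class = "format_error")
  if (anyDuplicated(rownames(table)) || anyDuplicated(colnames(table)))
    stop_("duplicated sample or taxon ids", class = "format_error")
  if (any(!is.finite(table)) || any(table < 0) || any(table != round(table)))
    stop_("counts must be finite non-negative integers", class = "format_error")
  invisible(table)
}

#' Read per-sample metadata from CSV
#'
#' Expected columns: `sample_id`, `glacier_id`, `continent`, `lat`, `lon`,
#' `hdi`, and the climatic covariates `u`, `msr`, `mmt`, `tmp`, `vp`.
#' Latitude, longitude and HDI are range-checked; an HDI of 0 is legal
#' (the convention used for polar regions without an index).
#'
#' @param path CSV path.
#' @return data.frame with `sample_id` as first column and row names.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path))
    stop_("metadata file not found: %s", path, class = "io_error")
  md <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata data.frame to validate in place.
#' @export
validate_sample_metadata <- function(metadata) {
  need <- c("sample_id", "glacier_id", "continent", "lat", "lon", "hdi",
            "u", "msr", "mmt", "tmp", "vp")
  miss <- setdiff(need, colnames(metadata))
  if (length(miss))
    stop_("metadata missing column(s): %s", paste(miss, collapse = ", "),
          class = "format_error")
  if (anyDuplicated(metadata$sample_id))
    stop_("duplicated sample_id in metadata", class = "format_error")
  if (any(!is.finite(metadata$lat)) || any(abs(metadata$lat) > 90))
    stop_("latitude out of [-90, 90]", class = "invalid_argument")
  if (any(!is.finite(metadata$lon)) || any(metadata$lon <= -180 | metadata$lon > 180))
    stop_("longitude out of (-180, 180]", class = "invalid_argument")
  if (any(!is.finite(metadata$hdi)) || any(metadata$hdi < 0 | metadata$hdi > 1))
    stop_("hdi out of [0, 1]", class = "invalid_argument")
  rownames(metadata) <- metadata$sample_id
  metadata
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(metadata, path) {
  write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that table, tree and metadata cross-reference cleanly
#'
#' @param table samples x taxa count matrix.
#' @param tree rooted `phylo` tree covering the table's taxa (or NULL).
#' @param metadata sample metadata data.frame (or NULL).
#' @return invisibly TRUE.
#' @export
validate_dataset <- function(table, tree = NULL, metadata = NULL) {
  validate_feature_table(table)
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo"))
      stop_("tree must be an ape 'phylo' object", class = "format_error")
    missing_tips <- setdiff(colnames(table), tree$tip.label)
    if (length(missing_tips))
      stop_("taxa absent from tree: %s",
            paste(utils::head(missing_tips, 5), collapse = ", "),
            class = "format_error")
    if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
      stop_("tree must carry finite branch lengths", class = "format_error")
  }
  if (!is.null(metadata)) {
    metadata <- validate_sample_metadata(metadata)
    if (!setequal(rownames(table), metadata$sample_id))
      stop_("table samples and metadata samples differ", class = "format_error")
  }
  invisible(TRUE)
}

#' Rarefy a feature table to uniform depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads.
#' Samples whose total falls below `depth` are dropped; their ids are
#' reported in the `"dropped"` attribute of the result.
#'
#' @param table samples x taxa count matrix.
#' @param depth target reads per sample; default is the minimum sample sum.
#' @param seed integer seed for the subsampling; NULL uses the current RNG.
#' @return rarefied integer matrix with attribute `dropped` (character vector).
#' @export
rarefy <- function(table, depth = min(rowSums(table)), seed = NULL) {
  validate_feature_table(table)
  depth <- check_count_(depth, "depth", min = 1L)
  totals <- rowSums(table)
  keep <- totals >= depth
  dropped <- rownames(table)[!keep]
  if (!any(keep))
    stop_("no sample reaches depth %d", depth, class = "invalid_argument")
  kept <- table[keep, , drop = FALSE]
  out <- with_seed_(seed, {
    res <- kept
    for (i in seq_len(nrow(kept))) {
      row <- kept[i, ]
      if (sum(row) == depth) next
      reads <- rep.int(seq_along(row), row)
      res[i, ] <- tabulate(sample(reads, depth), nbins = length(row))
    }
    res
  })
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- dropped
  out
}

#' Aggregate counts to relative abundance at a taxonomic rank
#'
#' @param table samples x taxa count matrix.
#' @param taxonomy data.frame with a `taxon_id` column and one column per
#'   rank (e.g. `phylum`, `genus`); taxa missing from it map to
#'   `"Unclassified"`.
#' @param rank rank column to aggregate by.
#' @return samples x rank-label matrix of proportions (rows sum to 1).
#' @export
aggregate_relative_abundance <- function(table, taxonomy, rank = "phylum") {
  validate_feature_table(table)
  if (!rank %in% colnames(taxonomy))
    stop_("rank '%s' not present in taxonomy", rank, class = "invalid_argument")
  labels <- setNames(as.character(taxonomy[[rank]]), taxonomy$taxon_id)
  lab <- labels[colnames(table)]
  lab[is.na(lab) | lab == ""] <- "Unclassified"
  totals <- rowSums(table)
  if (any(totals == 0)) {
    warning(sprintf("excluding all-zero sample(s): %s",
                    paste(rownames(table)[totals == 0], collapse = ", ")))
    table <- table[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  grouped <- t(rowsum(t(table), group = lab))
  sweep(grouped, 1, rowSums(grouped), "/")
}
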