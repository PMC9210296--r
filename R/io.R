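# Readers and writers for the external formats the pipeline touches:
# count matrices + sample metadata (TSV), BED-like gene annotation,
# bedGraph depth tracks. All interval formats are 0-based half-open.
# Readers reject malformed input naming the offending record; they never
# silently coerce.

# ---- constructors --------------------------------------------------------

#' Construct a count matrix with sample metadata
#'
#' @param counts integer matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param samples data.frame with columns `sample_id`, `cross` (one of
#'   `dom`, `mus`, `musXdom`, `domXmus`), `cell_type` (`LZ`, `DIP`, `RS`)
#'   and `replicate`; rows ordered as the columns of `counts`.
#' @return object of class `count_matrix`: a list with elements `counts`
#'   and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (any(counts != round(counts))) .stopf("counts must be integers")
  storage.mode(counts) <- "integer"
  req <- c("sample_id", "cross", "cell_type", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) .stopf("sample metadata missing columns: %s",
                           paste(miss, collapse = ", "))
  if (!all(samples$cross %in% .CROSSES))
    .stopf("unknown cross label(s): %s",
           paste(setdiff(samples$cross, .CROSSES), collapse = ", "))
  if (!all(samples$cell_type %in% .CELL_TYPES))
    .stopf("unknown cell type(s): %s",
           paste(setdiff(samples$cell_type, .CELL_TYPES), collapse = ", "))
  key <- paste(samples$cross, samples$cell_type, samples$replicate)
  if (anyDuplicated(key))
    .stopf("duplicate (cross, cell_type, replicate) triple: %s",
           key[duplicated(key)][1])
  if (ncol(counts) != nrow(samples))
    .stopf("counts has %d columns but metadata %d rows",
           ncol(counts), nrow(samples))
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), as.character(samples$sample_id)))
    .stopf("count column order does not match metadata sample order")
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d crosses, %d cell types)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$cross)),
              length(unique(x$samples$cell_type))))
  invisible(x)
}

#' Construct a gene annotation table
#'
#' Rows are sorted by (chromosome, start); `order_index` is the 0-based
#' rank in that order and `is_x` is set from the chromosome name (`"X"`).
#'
#' @param df data.frame with columns `chromosome`, `start`, `end`
#'   (0-based half-open), `gene_id`, `exonic_length`.
#' @return a `gene_table` data.frame with added `order_index` and `is_x`.
#' @export
gene_table <- function(df) {
  req <- c("chromosome", "start", "end", "gene_id", "exonic_length")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("annotation missing columns: %s",
                           paste(miss, collapse = ", "))
  bad <- which(df$start >= df$end)
  if (length(bad)) .stopf("gene %s has start >= end", df$gene_id[bad[1]])
  if (any(df$exonic_length <= 0))
    .stopf("gene %s has non-positive exonic_length",
           df$gene_id[which(df$exonic_length <= 0)[1]])
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) .stopf("duplicate gene_id: %s", dup[1])
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df$order_index <- seq_len(nrow(df)) - 1L
  df$is_x <- df$chromosome == "X"
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Construct a coverage track
#'
#' @param intervals data.frame with columns `chromosome`, `start`, `end`
#'   (0-based half-open) and `depth`; intervals must be sorted and
#'   non-overlapping within each chromosome.
#' @return object of class `coverage_track` with elements `intervals` and
#'   `genome_mean` (length-weighted mean depth over all intervals).
#' @export
coverage_track <- function(intervals) {
  req <- c("chromosome", "start", "end", "depth")
  miss <- setdiff(req, names(intervals))
  if (length(miss)) .stopf("coverage track missing columns: %s",
                           paste(miss, collapse = ", "))
  if (any(intervals$end <= intervals$start))
    .stopf("coverage interval with end <= start")
  if (any(intervals$depth < 0)) .stopf("negative depth")
  intervals <- intervals[order(intervals$chromosome, intervals$start), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  for (chr in unique(intervals$chromosome)) {
    sub <- intervals[intervals$chromosome == chr, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      .stopf("overlapping coverage intervals on chromosome %s", chr)
  }
  w <- intervals$end - intervals$start
  gm <- sum(w * intervals$depth) / sum(w)
  structure(list(intervals = intervals, genome_mean = gm),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d intervals on %d chromosome(s), genome mean %.3f\n",
              nrow(x$intervals), length(unique(x$intervals$chromosome)),
              x$genome_mean))
  invisible(x)
}

# ---- count table IO ------------------------------------------------------

#' Read a gene count table with sample metadata
#'
#' The count file is a TSV whose header row holds sample ids and whose
#' first column holds gene ids; all count fields must be non-negative
#' integers. The metadata file is a TSV with columns `sample_id`, `cross`,
#' `cell_type`, `replicate`. Samples are returned in metadata order.
#'
#' @param path path to the count TSV.
#' @param meta_path path to the sample metadata TSV.
#' @return a [count_matrix()].
#' @export
read_count_table <- function(path, meta_path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) .stopf("count table %s has no sample columns", path)
  gene_ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(mat))
  bad <- which(is.na(num) | num != floor(num) | num < 0)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(mat)) + 1
    j <- ((bad[1] - 1) %/% nrow(mat)) + 1
    .stopf("non-integer count '%s' at gene %s, sample %s",
           mat[i, j], gene_ids[i], colnames(mat)[j])
  }
  counts <- matrix(as.integer(num), nrow = nrow(mat),
                   dimnames = list(gene_ids, colnames(mat)))
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  missing_meta <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing_meta))
    .stopf("samples missing from metadata: %s",
           paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  # order samples as in the metadata file
  meta_order <- utils::read.delim(meta_path, stringsAsFactors = FALSE)$sample_id
  keep <- meta_order[meta_order %in% colnames(counts)]
  counts <- counts[, keep, drop = FALSE]
  meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  count_matrix(counts, meta)
}

#' Write a count matrix and its sample metadata
#'
#' @param cm a [count_matrix()].
#' @param path,meta_path output TSV paths.
#' @export
write_count_table <- function(cm, path, meta_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  .write_tsv(df, path)
  .write_tsv(cm$samples, meta_path)
  invisible(path)
}

# ---- annotation IO -------------------------------------------------------

#' Read a BED-like gene annotation table
#'
#' Expected columns: `chromosome`, `start`, `end`, `gene_id`,
#' `exonic_length` (and optionally `strand`, which is carried along but
#' ignored by all downstream computation). Coordinates are 0-based
#' half-open. Output rows are sorted by (chromosome, start) with
#' `order_index` and `is_x` assigned.
#'
#' @param path path to the annotation TSV.
#' @return a [gene_table()].
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_table(df)
}

#' Write a gene annotation table
#' @param genes a [gene_table()].
#' @param path output TSV path.
#' @export
write_gene_annotation <- function(genes, path) {
  .write_tsv(as.data.frame(genes), path)
}

# ---- bedGraph IO ---------------------------------------------------------

#' Read a bedGraph depth track
#'
#' bedGraph columns: chromosome, start, end (0-based half-open), depth.
#' A header/track line is tolerated. Overlapping intervals on one
#' chromosome are an error.
#'
#' @param path path to the bedGraph file.
#' @return a [coverage_track()] with `genome_mean` computed as the
#'   length-weighted mean depth.
#' @export
read_coverage_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4)) .stopf("bedGraph line with fewer than 4 fields")
  df <- data.frame(
    chromosome = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)),
    end = as.numeric(vapply(parts, `[`, "", 3)),
    depth = as.numeric(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$depth))
    .stopf("non-numeric field in bedGraph %s", path)
  coverage_track(df)
}

#' Write a coverage track as bedGraph
#' @param track a [coverage_track()].
#' @param path output path.
#' @export
write_coverage_bedgraph <- function(track, path) {
  iv <- track$intervals
  writeLines(sprintf("%s\t%d\t%d\t%s", iv$chromosome, as.integer(iv$start),
                     as.integer(iv$end), format(iv$depth, trim = TRUE,
                                                scientific = FALSE)),
             path)
  invisible(path)
}
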