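# Count-matrix and chromosome-count ingestion.
#
# Gene-level counts arrive as featureCounts-style tables (comment lines,
# Geneid/Chr/Start/End/Strand/Length columns, then one column per sample);
# chromosome-level counts arrive as samtools-idxstats 4-column text. Both
# readers reject malformed input rather than repairing it.

#' Read a featureCounts-style count table
#'
#' Parses the featureCounts dialect: lines starting with `#` are comments,
#' the header row names `Geneid`, `Chr`, `Start`, `End`, `Strand`, `Length`
#' followed by one column per sample. Multi-segment `Chr` entries such as
#' `"chr1;chr1"` collapse to their unique chromosome; entries naming two
#' distinct chromosomes are rejected because the read cannot be assigned to
#' one species of the hybrid reference.
#'
#' @param path Path to the count table.
#' @param gene_table A validated gene table; the returned matrix is restricted
#'   to genes present here and ordered to match it.
#' @return An integer count matrix, genes in rows (rownames are gene ids),
#'   samples in columns.
#' @export
read_counts_featurecounts <- function(path, gene_table) {
  gene_table <- validate_gene_table(gene_table)
  x <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  fixed <- c("Geneid", "Chr", "Start", "End", "Strand", "Length")
  missing <- setdiff(fixed, names(x))
  if (length(missing) > 0L) {
    stop("not a featureCounts table, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sample_cols <- setdiff(names(x), fixed)
  if (length(sample_cols) == 0L) stop("no sample columns found", call. = FALSE)

  chroms <- vapply(strsplit(as.character(x$Chr), ";", fixed = TRUE),
                   function(p) {
                     u <- unique(p)
                     if (length(u) != 1L) {
                       stop("Chr entry names more than one chromosome: ",
                            paste(u, collapse = ";"), call. = FALSE)
                     }
                     u
                   }, character(1))

  counts <- as.matrix(x[, sample_cols, drop = FALSE])
  if (!is.numeric(counts) || any(is.na(counts)) ||
      any(counts != round(counts)) || any(counts < 0)) {
    stop("sample columns must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- as.character(x$Geneid)

  keep <- intersect(gene_table$gene_id, rownames(counts))
  if (length(keep) == 0L) {
    stop("no genes in common between counts and gene table", call. = FALSE)
  }
  counts <- counts[keep, , drop = FALSE]

  # chromosome assignment in the file must agree with the annotation
  ann_chrom <- stats::setNames(gene_table$chromosome, gene_table$gene_id)
  file_chrom <- stats::setNames(chroms, as.character(x$Geneid))[keep]
  mism <- keep[file_chrom != ann_chrom[keep]]
  if (length(mism) > 0L) {
    stop("chromosome mismatch between counts and annotation for gene(s): ",
         paste(utils::head(mism, 5L), collapse = ", "), call. = FALSE)
  }
  counts
}

#' Write a count matrix in featureCounts dialect
#'
#' The inverse of [read_counts_featurecounts()]. `Start`, `End`, `Strand` and
#' `Length` carry placeholder values (this package models counts, not
#' coordinates); `Chr` comes from the gene table.
#'
#' @param counts Integer count matrix with gene rownames.
#' @param gene_table A validated gene table covering all rows of `counts`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_featurecounts <- function(counts, gene_table, path) {
  gene_table <- validate_gene_table(gene_table)
  chrom <- stats::setNames(gene_table$chromosome, gene_table$gene_id)
  if (!all(rownames(counts) %in% names(chrom))) {
    stop("counts contain genes absent from the gene table", call. = FALSE)
  }
  df <- data.frame(Geneid = rownames(counts),
                   Chr = unname(chrom[rownames(counts)]),
                   Start = 1L, End = 1000L, Strand = "+", Length = 1000L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Program:ribotagr; canonical featureCounts-dialect output", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a samtools-idxstats chromosome count file
#'
#' Parses the 4-column idxstats text (chromosome, sequence length, mapped
#' reads, unmapped reads) for a single sample. The mapped column becomes the
#' chromosome count; the `*` (unplaced) row is ignored.
#'
#' @param path Path to an idxstats file.
#' @return A tibble with columns `chromosome` and `count`.
#' @export
read_idxstats <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out_chrom <- character(0)
  out_count <- integer(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L) {
      stop("malformed idxstats row at line ", i, ": expected 4 fields, got ",
           length(f), call. = FALSE)
    }
    if (f[[1]] == "*") next
    mapped <- suppressWarnings(as.integer(f[[3]]))
    if (is.na(mapped) || mapped < 0L) {
      stop("malformed idxstats row at line ", i,
           ": mapped count is not a non-negative integer", call. = FALSE)
    }
    out_chrom <- c(out_chrom, f[[1]])
    out_count <- c(out_count, mapped)
  }
  tibble::tibble(chromosome = out_chrom, count = out_count)
}

#' Write a chromosome count table in idxstats layout
#'
#' @param chrom_counts Tibble with `chromosome` and `count` columns.
#' @param path Output path.
#' @param lengths Optional named vector of sequence lengths; a placeholder is
#'   used otherwise.
#' @return `path`, invisibly.
#' @export
write_idxstats <- function(chrom_counts, path, lengths = NULL) {
  stopifnot(all(c("chromosome", "count") %in% names(chrom_counts)))
  len <- if (is.null(lengths)) rep(1000L, nrow(chrom_counts))
         else unname(lengths[chrom_counts$chromosome])
  df <- data.frame(chrom_counts$chromosome, len, chrom_counts$count, 0L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Aggregate gene-level counts to chromosome level
#'
#' Produces the same chromosome-count table shape as [read_idxstats()], so
#' chromosome-level analyses are agnostic to whether counts arrived from
#' idxstats or from a gene-level matrix.
#'
#' @param counts Integer count matrix with gene rownames.
#' @param gene_table A validated gene table.
#' @param sample_id Column of `counts` to aggregate.
#' @return A tibble with columns `chromosome` and `count`.
#' @export
chrom_counts_from_genes <- function(counts, gene_table, sample_id) {
  gene_table <- validate_gene_table(gene_table)
  if (!sample_id %in% colnames(counts)) {
    stop("sample not found in counts: ", sample_id, call. = FALSE)
  }
  chrom <- stats::setNames(gene_table$chromosome, gene_table$gene_id)
  v <- counts[, sample_id]
  agg <- tapply(v, chrom[rownames(counts)], sum)
  tibble::tibble(chromosome = names(agg), count = as.integer(agg))
}
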