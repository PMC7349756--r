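# Gene annotation model for a hybrid (two-species + reporter) reference.
#
# A gene table is a tibble with columns gene_id, chromosome, species, biotype
# and a derived logical is_mito. Chromosome names are opaque labels; each
# chromosome belongs to exactly one species. Reporter transcripts (GFP,
# mCherry) carry species "reporter" and are kept out of species chromosome
# sets by every downstream computation that reasons about species.

#' Default mitochondrial chromosome names
#'
#' Ensembl-style and UCSC-style names recognised as mitochondrial when
#' deriving the `is_mito` flag.
#' @export
default_mito_chroms <- function() c("MT", "chrM", "chrMT")

#' Validate a gene annotation table
#'
#' Checks the structural invariants of the hybrid-reference annotation:
#' unique gene ids, a single species per chromosome, and a single
#' mitochondrial chromosome per (non-reporter) species at most.
#'
#' @param gene_table A data frame with columns `gene_id`, `chromosome`,
#'   `species`, `biotype`, `is_mito`.
#' @return The validated table as a tibble, invisibly usable downstream.
#' @export
validate_gene_table <- function(gene_table) {
  req <- c("gene_id", "chromosome", "species", "biotype", "is_mito")
  missing <- setdiff(req, names(gene_table))
  if (length(missing) > 0L) {
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gt <- tibble::as_tibble(gene_table)
  dup <- gt$gene_id[duplicated(gt$gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene_id in gene table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  sp_per_chrom <- tapply(gt$species, gt$chromosome,
                         function(s) length(unique(s)))
  bad <- names(sp_per_chrom)[sp_per_chrom > 1L]
  if (length(bad) > 0L) {
    stop("chromosome assigned to more than one species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mito_per_chrom <- tapply(gt$is_mito, gt$chromosome, function(m) unique(m))
  if (any(lengths(mito_per_chrom) > 1L)) {
    stop("chromosome with mixed is_mito flags: ",
         paste(names(mito_per_chrom)[lengths(mito_per_chrom) > 1L],
               collapse = ", "), call. = FALSE)
  }
  gt
}

#' Read a gene annotation table
#'
#' Reads a tab-separated annotation file with header columns `gene_id`,
#' `chromosome`, `species`, `biotype` and derives the mitochondrial flag
#' from a configurable chromosome name set.
#'
#' @param path Path to a tab-separated annotation file.
#' @param mito_chroms Character vector of chromosome names treated as
#'   mitochondrial (default [default_mito_chroms()]).
#' @return A validated gene table tibble with an `is_mito` column.
#' @export
read_gene_table <- function(path, mito_chroms = default_mito_chroms()) {
  gt <- read_tsv_checked(path, required = c("gene_id", "chromosome",
                                            "species", "biotype"))
  gt <- gt[, c("gene_id", "chromosome", "species", "biotype")]
  gt$gene_id <- as.character(gt$gene_id)
  gt$chromosome <- as.character(gt$chromosome)
  gt$species <- as.character(gt$species)
  gt$biotype <- as.character(gt$biotype)
  gt$is_mito <- gt$chromosome %in% mito_chroms
  validate_gene_table(gt)
}

#' Write a gene annotation table
#'
#' Writes the four annotation columns in the canonical tab-separated dialect;
#' `is_mito` is derived on read, not stored.
#'
#' @param gene_table A validated gene table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(gene_table, path) {
  gene_table <- validate_gene_table(gene_table)
  write_tsv_canonical(
    gene_table[, c("gene_id", "chromosome", "species", "biotype")], path)
}

# chromosome -> species lookup (includes reporter contigs)
chrom_species_map <- function(gene_table) {
  u <- unique(gene_table[, c("chromosome", "species")])
  stats::setNames(u$species, u$chromosome)
}

# chromosome -> is_mito lookup
chrom_mito_map <- function(gene_table) {
  u <- unique(gene_table[, c("chromosome", "is_mito")])
  stats::setNames(u$is_mito, u$chromosome)
}
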