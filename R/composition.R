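# Read-composition tables: percent of library per chromosome, species
# composition, and IP-vs-input delta tables that feed the depletion
# regression.

#' Per-chromosome percent of library
#'
#' Computes, for one sample, the percentage of counted reads on each
#' chromosome. `mode` selects the quantification universe:
#' * `"all_genes"` — all genes of a gene-level matrix;
#' * `"protein_coding_only"` — numerator and denominator restricted to
#'   protein-coding genes (gene-level counts required);
#' * `"chromosome_level"` — a chromosome count table (e.g. from
#'   [read_idxstats()] or [chrom_counts_from_genes()]).
#'
#' Reporter contigs (species `"reporter"`) are excluded from both numerator
#' and denominator by default; they are quantified separately by the reporter
#' module.
#'
#' @param x An integer count matrix (genes x samples) or a chromosome count
#'   tibble with columns `chromosome`, `count`.
#' @param gene_table A validated gene table.
#' @param sample_id Sample to compute (required for a matrix; a label for a
#'   chromosome table).
#' @param mode Quantification mode, see above.
#' @param include_reporters Keep reporter contigs in the table and the
#'   denominator.
#' @return A tibble `sample_id`, `chromosome`, `percent`, `mode`; percents
#'   sum to 100.
#' @export
chrom_proportions <- function(x, gene_table, sample_id = NULL,
                              mode = c("all_genes", "protein_coding_only",
                                       "chromosome_level"),
                              include_reporters = FALSE) {
  mode <- match.arg(mode)
  gene_table <- validate_gene_table(gene_table)

  if (is.matrix(x)) {
    if (mode == "chromosome_level") {
      stop("mode 'chromosome_level' expects a chromosome count table; ",
           "use chrom_counts_from_genes() to aggregate a gene matrix",
           call. = FALSE)
    }
    if (is.null(sample_id)) stop("sample_id is required", call. = FALSE)
    gt <- gene_table[gene_table$gene_id %in% rownames(x), ]
    if (mode == "protein_coding_only") {
      gt <- gt[gt$biotype == "protein_coding", ]
    }
    if (!include_reporters) gt <- gt[gt$species != "reporter", ]
    if (!sample_id %in% colnames(x)) {
      stop("sample not found in counts: ", sample_id, call. = FALSE)
    }
    v <- x[gt$gene_id, sample_id]
    agg <- tapply(v, gt$chromosome, sum)
    tab <- tibble::tibble(chromosome = names(agg), count = as.numeric(agg))
  } else {
    if (mode != "chromosome_level") {
      stop("mode '", mode, "' requires gene-level counts", call. = FALSE)
    }
    stopifnot(all(c("chromosome", "count") %in% names(x)))
    unknown <- setdiff(x$chromosome, gene_table$chromosome)
    if (length(unknown) > 0L) {
      stop("chromosome(s) absent from gene table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    tab <- tibble::tibble(chromosome = x$chromosome,
                          count = as.numeric(x$count))
    if (!include_reporters) {
      sp <- chrom_species_map(gene_table)
      tab <- tab[sp[tab$chromosome] != "reporter", ]
    }
    if (is.null(sample_id)) sample_id <- "sample"
  }

  total <- sum(tab$count)
  if (total <= 0) stop("empty library: zero total reads for sample ",
                       sample_id, call. = FALSE)
  tibble::tibble(sample_id = sample_id,
                 chromosome = tab$chromosome,
                 percent = 100 * tab$count / total,
                 mode = mode)
}

#' Species composition of a sample
#'
#' Sums chromosome percentages by species. With reporter contigs excluded
#' (the default upstream), the species percentages partition 100.
#'
#' @param props A [chrom_proportions()] table.
#' @param gene_table A validated gene table.
#' @return A tibble `sample_id`, `species`, `percent`.
#' @export
species_composition <- function(props, gene_table) {
  gene_table <- validate_gene_table(gene_table)
  sp <- chrom_species_map(gene_table)
  props |>
    dplyr::mutate(species = unname(sp[.data$chromosome])) |>
    dplyr::group_by(.data$sample_id, .data$species) |>
    dplyr::summarise(percent = sum(.data$percent), .groups = "drop")
}

#' IP-vs-input per-chromosome delta table
#'
#' For a matched IP/input pair, computes the change in percent of library
#' (IP - input) for every chromosome and classifies each chromosome as
#' on-target (its species expresses the immunoprecipitated tag) or
#' off-target. Under this sign convention off-target depletion appears as a
#' negative regression slope.
#'
#' @param input_props,ip_props [chrom_proportions()] tables computed in the
#'   same mode over the same chromosome set.
#' @param gene_table A validated gene table.
#' @param on_target_species Species label carrying the tag for this IP.
#' @return A tibble `chromosome`, `species`, `is_mito`, `initial_percent`,
#'   `delta_percent`, `target_class`; deltas sum to 0.
#' @export
delta_table <- function(input_props, ip_props, gene_table,
                        on_target_species) {
  gene_table <- validate_gene_table(gene_table)
  if (!identical(unique(input_props$mode), unique(ip_props$mode))) {
    stop("input and IP proportion tables use different modes", call. = FALSE)
  }
  if (!setequal(input_props$chromosome, ip_props$chromosome)) {
    stop("input and IP proportion tables cover different chromosomes",
         call. = FALSE)
  }
  sp <- chrom_species_map(gene_table)
  mito <- chrom_mito_map(gene_table)
  ip_pct <- stats::setNames(ip_props$percent, ip_props$chromosome)
  species <- unname(sp[input_props$chromosome])
  tibble::tibble(
    chromosome = input_props$chromosome,
    species = species,
    is_mito = unname(mito[input_props$chromosome]),
    initial_percent = input_props$percent,
    delta_percent = unname(ip_pct[input_props$chromosome]) -
      input_props$percent,
    target_class = dplyr::case_when(
      species == "reporter" ~ NA_character_,
      species == on_target_species ~ "on",
      TRUE ~ "off"))
}

#' Gene-level IP-vs-input delta table
#'
#' The gene-granularity analogue of [delta_table()]: per-gene percent of
#' library in the input, and its change after IP, with biotype and
#' mitochondrial annotation. Used for on-target gene-level views where
#' mitochondrially encoded genes behave like off-target genes.
#'
#' @param counts Integer gene-level count matrix.
#' @param gene_table A validated gene table.
#' @param input_sample,ip_sample Column names in `counts`.
#' @param on_target_species Species carrying the tag for this IP.
#' @param mode `"all_genes"` or `"protein_coding_only"`.
#' @param include_reporters Keep reporter transcripts in the denominators.
#' @return A tibble `gene_id`, `chromosome`, `species`, `biotype`, `is_mito`,
#'   `initial_percent`, `delta_percent`, `target_class`.
#' @export
gene_delta <- function(counts, gene_table, input_sample, ip_sample,
                       on_target_species,
                       mode = c("all_genes", "protein_coding_only"),
                       include_reporters = FALSE) {
  mode <- match.arg(mode)
  gene_table <- validate_gene_table(gene_table)
  gt <- gene_table[gene_table$gene_id %in% rownames(counts), ]
  if (mode == "protein_coding_only") gt <- gt[gt$biotype == "protein_coding", ]
  if (!include_reporters) gt <- gt[gt$species != "reporter", ]
  for (s in c(input_sample, ip_sample)) {
    if (!s %in% colnames(counts)) {
      stop("sample not found in counts: ", s, call. = FALSE)
    }
  }
  v_in <- counts[gt$gene_id, input_sample]
  v_ip <- counts[gt$gene_id, ip_sample]
  if (sum(v_in) <= 0) stop("empty library: ", input_sample, call. = FALSE)
  if (sum(v_ip) <= 0) stop("empty library: ", ip_sample, call. = FALSE)
  pct_in <- 100 * v_in / sum(v_in)
  pct_ip <- 100 * v_ip / sum(v_ip)
  tibble::tibble(
    gene_id = gt$gene_id,
    chromosome = gt$chromosome,
    species = gt$species,
    biotype = gt$biotype,
    is_mito = gt$is_mito,
    initial_percent = unname(pct_in),
    delta_percent = unname(pct_ip - pct_in),
    target_class = dplyr::case_when(
      gt$species == "reporter" ~ NA_character_,
      gt$species == on_target_species ~ "on",
      TRUE ~ "off"))
}
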