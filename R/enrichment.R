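# Self-contained permutation gene-set enrichment over Ensembl biotypes (all
# genes) and over chromosomes (protein-coding genes).
#
# Genes are ranked by log2 fold change of CPM (IP vs input); the enrichment
# score is the classic weighted Kolmogorov-Smirnov running-sum statistic, and
# significance comes from a gene-permutation null: random same-size sets
# drawn from the ranked universe. Sample permutation is impossible for the
# n = 1 input/IP pairing this design produces.

#' Rank genes by IP-vs-input log2 fold change of CPM
#'
#' The ranking statistic is `log2((CPM_ip + pseudocount) /
#' (CPM_input + pseudocount))` with CPM the counts-per-million of each
#' library. Ties are broken by gene id (lexical, stable), so the order is
#' deterministic.
#'
#' @param counts Gene-level count matrix.
#' @param input_sample,ip_sample Column names in `counts`.
#' @param pseudocount Added to both CPMs before the ratio (default 1).
#' @return A tibble `gene_id`, `stat`, sorted by decreasing statistic.
#' @export
rank_genes <- function(counts, input_sample, ip_sample, pseudocount = 1) {
  for (s in c(input_sample, ip_sample)) {
    if (!s %in% colnames(counts)) {
      stop("sample not found in counts: ", s, call. = FALSE)
    }
    if (sum(counts[, s]) <= 0) stop("empty library: ", s, call. = FALSE)
  }
  cpm <- function(v) 1e6 * v / sum(v)
  stat <- log2((cpm(counts[, ip_sample]) + pseudocount) /
               (cpm(counts[, input_sample]) + pseudocount))
  ord <- order(-stat, rownames(counts), method = "radix")
  tibble::tibble(gene_id = rownames(counts)[ord], stat = unname(stat[ord]))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: at a gene-set member the running sum increases by
#' the gene's `|stat|^p` share of the set's total `|stat|^p`; at a non-member
#' it decreases by `1/(n - set size)`. The enrichment score is the signed
#' running-sum value of maximal absolute deviation from zero. If every set
#' member has statistic zero the hit increments fall back to equal weights.
#'
#' @param ranked A [rank_genes()] tibble (or any tibble with `gene_id`,
#'   `stat` in rank order).
#' @param gene_set Character vector of gene ids, a strict non-empty subset of
#'   the ranked genes.
#' @param weight_exponent Exponent `p` on `|stat|` (default 1, the classic
#'   weighted statistic).
#' @return The enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  n <- nrow(ranked)
  hit_pos <- which(ranked$gene_id %in% gene_set)
  n_hit <- length(hit_pos)
  if (n_hit == 0L) stop("gene set has no members in the ranked list",
                        call. = FALSE)
  if (n_hit == n) stop("gene set equals the whole universe", call. = FALSE)
  if (length(unique(gene_set)) != n_hit) {
    stop("gene set contains genes absent from the ranked list", call. = FALSE)
  }
  es_from_positions(abs(ranked$stat)^weight_exponent, n, hit_pos)
}

# Core ES computation from hit positions. Between hits the running sum
# decays linearly, so its extrema occur at hit positions (just before and at
# each hit); only those candidates are inspected.
es_from_positions <- function(absw, n, hit_pos) {
  hit_pos <- sort(hit_pos)
  k <- length(hit_pos)
  w <- absw[hit_pos]
  tot <- sum(w)
  cum_hit <- if (tot > 0) cumsum(w) / tot else seq_len(k) / k
  miss_step <- 1 / (n - k)
  j <- seq_len(k)
  at_hit <- cum_hit - (hit_pos - j) * miss_step
  before_hit <- c(0, cum_hit[-k]) - (hit_pos - j) * miss_step
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

# Leading-edge size: number of set members at or before (ES >= 0) / at or
# after (ES < 0) the running-sum extremum.
leading_edge_size <- function(absw, n, hit_pos, es) {
  hit_pos <- sort(hit_pos)
  k <- length(hit_pos)
  w <- absw[hit_pos]
  tot <- sum(w)
  cum_hit <- if (tot > 0) cumsum(w) / tot else seq_len(k) / k
  miss_step <- 1 / (n - k)
  j <- seq_len(k)
  at_hit <- cum_hit - (hit_pos - j) * miss_step
  if (es >= 0) which.max(at_hit)
  else k - which.min(c(0, cum_hit[-k]) - (hit_pos - j) * miss_step) + 1L
}

#' Permutation gene-set enrichment analysis
#'
#' Computes the enrichment score for every set and a permutation p-value from
#' a null of random same-size gene sets drawn from the ranked universe. The
#' p-value is two-sided on the score magnitude — it counts null scores with
#' `|ES|` at least `|ES_obs|`, with the conventional +1 correction — which
#' makes the test exactly calibrated by exchangeability and bounded below by
#' `1/(n_perm + 1)`; the direction of enrichment is read from the sign of
#' `es`. Benjamini-Hochberg adjustment is applied across all tested sets.
#' Deterministic given `seed`.
#'
#' @param ranked A [rank_genes()] tibble.
#' @param sets Named list of gene-id vectors.
#' @param n_perm Number of permutations per set.
#' @param seed Integer seed (required).
#' @param weight_exponent Exponent on `|stat|` (see [enrichment_score()]).
#' @param min_size Sets smaller than this are skipped with a message.
#' @return A tibble `set`, `size`, `es`, `p_value`, `padj`,
#'   `leading_edge_size`.
#' @export
gsea <- function(ranked, sets, n_perm = 1000L, seed, weight_exponent = 1,
                 min_size = 5L) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n <- nrow(ranked)
  absw <- abs(ranked$stat)^weight_exponent
  keep <- vapply(sets, function(s) {
    size <- sum(ranked$gene_id %in% s)
    ok <- size >= min_size && size < n
    ok
  }, logical(1))
  if (any(!keep)) {
    message("skipping ", sum(!keep), " set(s) outside size bounds: ",
            paste(names(sets)[!keep], collapse = ", "))
  }
  sets <- sets[keep]
  if (length(sets) == 0L) stop("no sets to test", call. = FALSE)

  with_local_seed(seed, {
    rows <- lapply(names(sets), function(label) {
      hit_pos <- which(ranked$gene_id %in% sets[[label]])
      size <- length(hit_pos)
      es <- es_from_positions(absw, n, hit_pos)
      null_es <- vapply(seq_len(n_perm), function(i) {
        es_from_positions(absw, n, sample.int(n, size))
      }, numeric(1))
      p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
      tibble::tibble(set = label, size = size, es = es, p_value = p,
                     leading_edge_size = leading_edge_size(absw, n, hit_pos,
                                                           es))
    })
    out <- dplyr::bind_rows(rows)
    out$padj <- stats::p.adjust(out$p_value, method = "BH")
    out[, c("set", "size", "es", "p_value", "padj", "leading_edge_size")]
  })
}

#' Gene sets from biotypes or chromosomes
#'
#' `universe = "all"` returns one set per Ensembl biotype across all
#' non-reporter genes (the sets partition the universe). `universe =
#' "protein_coding"` restricts to protein-coding genes and returns one set
#' per chromosome — the analysis in which depletion of the mitochondrial
#' chromosome is the expected signal.
#'
#' @param gene_table A validated gene table.
#' @param universe `"all"` or `"protein_coding"`.
#' @return Named list of gene-id vectors.
#' @export
biotype_and_chromosome_sets <- function(gene_table,
                                        universe = c("all",
                                                     "protein_coding")) {
  universe <- match.arg(universe)
  gene_table <- validate_gene_table(gene_table)
  gt <- gene_table[gene_table$species != "reporter", ]
  if (universe == "all") {
    split(gt$gene_id, gt$biotype)
  } else {
    gt <- gt[gt$biotype == "protein_coding", ]
    split(gt$gene_id, gt$chromosome)
  }
}
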