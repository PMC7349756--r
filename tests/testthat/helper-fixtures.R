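# Shared fixtures, built in code.

# A small two-species annotation: 2 human chromosomes + human MT, 2 mouse
# chromosomes + mouse MT, plus both reporters.
tiny_gene_table <- function() {
  tibble::tibble(
    gene_id = c("hA1", "hA2", "hB1", "hB2", "hM1",
                "mA1", "mA2", "mB1", "mB2", "mM1",
                "GFP", "mCherry"),
    chromosome = c("h1", "h1", "h2", "h2", "h_MT",
                   "m1", "m1", "m2", "m2", "m_MT",
                   "GFP", "mCherry"),
    species = c(rep("human", 5), rep("mouse", 5), "reporter", "reporter"),
    biotype = c("protein_coding", "lncRNA", "protein_coding", "pseudogene",
                "protein_coding",
                "protein_coding", "lncRNA", "protein_coding", "pseudogene",
                "protein_coding",
                "protein_coding", "protein_coding"),
    is_mito = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
}

tiny_counts <- function(gt = tiny_gene_table(), seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nrow(gt) * 2, 500) + 1L, ncol = 2,
                dimnames = list(gt$gene_id, c("inp", "ip")))
    storage.mode(m) <- "integer"
    m
  })
}

# A reduced simulation for fast tests: fewer chromosomes, smaller library.
small_sim_config <- function(seed = 1L, library_size = 2e5, ...) {
  sim_config(seed = seed,
             human_chromosomes = c(paste0("hg38_", 1:8), "hg38_MT"),
             mouse_chromosomes = c(paste0("mm10_", 1:8), "mm10_MT"),
             n_genes_per_chrom = 30L,
             library_size = library_size,
             ...)
}

# Closed-form simple-regression oracle (normal equations), independent of lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  se <- sqrt(ss_res / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Brute-force enrichment-score oracle: explicit walk down the ranked list.
es_walk_oracle <- function(stats, gene_ids, gene_set, p = 1) {
  n <- length(stats)
  hit <- gene_ids %in% gene_set
  w <- abs(stats)^p
  nr <- sum(w[hit])
  inc <- if (nr > 0) w * hit / nr else hit / sum(hit)
  dec <- (!hit) / (n - sum(hit))
  running <- cumsum(inc - dec)
  running[which.max(abs(running))]
}

# Build a full-depletion IP/input chromosome-count pair through the package's
# own readers-facing types: arbitrary positive input counts, IP with every
# off-target chromosome zeroed and on-target counts kept proportional.
full_depletion_fixture <- function(n_on = 20, n_off = 20, seed = 5) {
  withr::with_seed(seed, {
    gt <- tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n_on + n_off)),
      chromosome = c(paste0("on", seq_len(n_on)), paste0("off", seq_len(n_off))),
      species = c(rep("human", n_on), rep("mouse", n_off)),
      biotype = "protein_coding",
      is_mito = FALSE)
    input <- tibble::tibble(chromosome = gt$chromosome,
                            count = sample(100:10000, n_on + n_off))
    ip <- input
    ip$count[gt$species == "mouse"] <- 0L
    list(gene_table = gt, input = input, ip = ip)
  })
}
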