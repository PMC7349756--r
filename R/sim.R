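# Generative model of a two-cell-type, two-species co-culture RiboTag IP
# experiment.
#
# Cell type A is human and expresses GFP together with the HA-tagged RPL22;
# cell type B is mouse and expresses mCherry with the V5 tag. Input RNA is a
# mass mixture of the two cell-type expression profiles; an IP reweights the
# input by per-gene capture factors: on-target genes by a biotype-specific
# factor, off-target genes by a uniform retain factor k (non-specific
# contamination), and mitochondrial genes of both species by 0 because
# mitochondrial transcripts are translated by mitoribosomes, never by
# RPL22-containing cytosolic ribosomes. Reads are drawn multinomially.
#
# Uniform proportional retention of off-target RNA predicts that the
# per-chromosome change in percent of library (IP - input) is linear in the
# initial percent, with slope k/Z - 1 where Z is the total retained mass
# fraction; the fitted depletion efficiency then has analytic expectation
# D = 1 - k/Z, recorded in the truth object.

#' Build a simulation configuration
#'
#' Defaults emulate the study conditions of a human/mouse co-culture read at
#' roughly 28% human / 72% mouse composition, i.i.d. log-normal per-gene
#' expression, biotype-dependent ribosome capture (protein-coding captured
#' fully, lncRNA and pseudogenes less), complete exclusion of mitochondrial
#' transcripts from the IP, and uniform off-target retention producing
#' depletion efficiencies in the experimentally observed 0.25-0.87 range.
#'
#' @param seed Integer RNG seed; the simulation is deterministic given it.
#' @param n_genes_per_chrom Genes simulated per non-mitochondrial chromosome.
#' @param human_chromosomes,mouse_chromosomes Chromosome label vectors, each
#'   containing its species' mitochondrial chromosome.
#' @param human_mito,mouse_mito Name of each species' mitochondrial chromosome.
#' @param n_mito_genes Mitochondrial protein-coding genes per species.
#' @param mixing_fraction Fraction `m` of co-culture RNA mass from the human
#'   cell type, in `[0, 1]`.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of per-gene expression.
#' @param biotype_props Named proportions of `protein_coding`, `lncRNA`,
#'   `pseudogene` among nuclear genes (must sum to 1).
#' @param capture Named on-target capture factors per biotype, each in
#'   `[0, 1]`; protein_coding should be the largest. Mitochondrial capture is
#'   fixed at 0.
#' @param offtarget_retain Off-target retain factor `k` in `[0, 1]`: the
#'   fraction of off-target (and off-cell-type reporter) RNA surviving the IP
#'   relative to on-target protein-coding RNA.
#' @param mito_mass_fraction Fraction of each species' input RNA mass on its
#'   mitochondrial chromosome.
#' @param reporter_mass_fraction Fraction of each cell type's RNA mass from
#'   its reporter transcript (GFP for human, mCherry for mouse).
#' @param library_size Reads per sample (multinomial total).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_per_chrom = 40L,
                       human_chromosomes = c(paste0("hg38_", c(1:22, "X")),
                                             "hg38_MT"),
                       mouse_chromosomes = c(paste0("mm10_", c(1:19, "X")),
                                             "mm10_MT"),
                       human_mito = "hg38_MT",
                       mouse_mito = "mm10_MT",
                       n_mito_genes = 13L,
                       mixing_fraction = 0.28,
                       expr_meanlog = 0,
                       expr_sdlog = 1,
                       biotype_props = c(protein_coding = 0.60,
                                         lncRNA = 0.25,
                                         pseudogene = 0.15),
                       capture = c(protein_coding = 1.0,
                                   lncRNA = 0.3,
                                   pseudogene = 0.3),
                       offtarget_retain = 0.2,
                       mito_mass_fraction = 0.10,
                       reporter_mass_fraction = 0.005,
                       library_size = 1e6) {
  cfg <- list(seed = as.integer(seed),
              n_genes_per_chrom = as.integer(n_genes_per_chrom),
              human_chromosomes = human_chromosomes,
              mouse_chromosomes = mouse_chromosomes,
              human_mito = human_mito, mouse_mito = mouse_mito,
              n_mito_genes = as.integer(n_mito_genes),
              mixing_fraction = mixing_fraction,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              biotype_props = biotype_props, capture = capture,
              offtarget_retain = offtarget_retain,
              mito_mass_fraction = mito_mass_fraction,
              reporter_mass_fraction = reporter_mass_fraction,
              library_size = library_size)
  in01 <- function(x) all(x >= 0 & x <= 1)
  stopifnot(human_mito %in% human_chromosomes,
            mouse_mito %in% mouse_chromosomes,
            in01(cfg$mixing_fraction), in01(cfg$offtarget_retain),
            in01(cfg$capture), in01(cfg$mito_mass_fraction),
            in01(cfg$reporter_mass_fraction),
            abs(sum(biotype_props) - 1) < 1e-8,
            setequal(names(biotype_props), names(capture)),
            cfg$library_size >= 1)
  structure(cfg, class = "sim_config")
}

# Annotation implied by a config: per-species nuclear genes with sampled
# biotypes, mitochondrial protein-coding genes, and the two reporters.
# Chromosome gene counts follow a fixed linear size gradient around the
# configured mean (largest chromosome ~8x the smallest), mirroring real
# karyotypes where gene density spans an order of magnitude; per-chromosome
# read shares then spread over a realistic range instead of clustering.
sim_gene_table <- function(config) {
  make_species <- function(prefix, chroms, mito, species) {
    nuc <- setdiff(chroms, mito)
    sizes <- pmax(5L, as.integer(round(
      config$n_genes_per_chrom * seq(2, 0.25, length.out = length(nuc)))))
    n_nuc <- sum(sizes)
    bio <- sample(names(config$biotype_props), n_nuc, replace = TRUE,
                  prob = config$biotype_props)
    tibble::tibble(
      gene_id = sprintf("%s%05d", prefix, seq_len(n_nuc + config$n_mito_genes)),
      chromosome = c(rep(nuc, times = sizes),
                     rep(mito, config$n_mito_genes)),
      species = species,
      biotype = c(bio, rep("protein_coding", config$n_mito_genes)),
      is_mito = c(rep(FALSE, n_nuc), rep(TRUE, config$n_mito_genes)))
  }
  rbind(
    make_species("HSG", config$human_chromosomes, config$human_mito, "human"),
    make_species("MMG", config$mouse_chromosomes, config$mouse_mito, "mouse"),
    tibble::tibble(gene_id = c("GFP", "mCherry"),
                   chromosome = c("GFP", "mCherry"),
                   species = "reporter",
                   biotype = "protein_coding",
                   is_mito = FALSE))
}

# RNA mass distribution of one cell type over the full gene universe:
# log-normal relative masses within the nuclear and mitochondrial gene
# groups, scaled so mito and reporter genes take their configured mass
# fractions. Genes of the other species get zero mass.
sim_celltype_masses <- function(config, gene_table, species, reporter) {
  p <- numeric(nrow(gene_table))
  names(p) <- gene_table$gene_id
  own <- gene_table$species == species
  nuc <- own & !gene_table$is_mito
  mito <- own & gene_table$is_mito
  raw_nuc <- stats::rlnorm(sum(nuc), config$expr_meanlog, config$expr_sdlog)
  raw_mito <- stats::rlnorm(sum(mito), config$expr_meanlog, config$expr_sdlog)
  nuclear_mass <- 1 - config$mito_mass_fraction - config$reporter_mass_fraction
  p[nuc] <- nuclear_mass * raw_nuc / sum(raw_nuc)
  p[mito] <- config$mito_mass_fraction * raw_mito / sum(raw_mito)
  p[gene_table$gene_id == reporter] <- config$reporter_mass_fraction
  p
}

# Per-gene IP capture weights for a given on-target species. Reporters are
# treated as protein-coding transcripts of their host cell type.
sim_capture_weights <- function(config, gene_table, on_target_species) {
  k <- config$offtarget_retain
  host <- c(GFP = "human", mCherry = "mouse")
  sp <- gene_table$species
  rep_idx <- sp == "reporter"
  sp[rep_idx] <- host[gene_table$gene_id[rep_idx]]
  w <- ifelse(sp == on_target_species,
              unname(config$capture[gene_table$biotype]), k)
  w[gene_table$is_mito] <- 0
  stats::setNames(w, gene_table$gene_id)
}

#' Simulate a co-culture IP experiment
#'
#' Generates one shared co-culture input sample plus an HA IP (on-target
#' human) and a V5 IP (on-target mouse), each drawn multinomially at the
#' configured library size, together with a truth record carrying the exact
#' sampling probabilities and the analytic expectation of the depletion
#' statistic for each IP.
#'
#' The expected off-target regression slope for an IP is `k/Z - 1` and the
#' expected depletion efficiency `1 - k/Z`, where `Z` is the IP's total
#' retained mass fraction over the non-reporter gene universe (input
#' proportions renormalised to that universe, matching the default analysis
#' which excludes reporter contigs from chromosome-proportion denominators).
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `gene_table`, `counts` (genes x 3 samples:
#'   `coculture_input`, `IP_HA`, `IP_V5`), `sample_sheet`, and `truth`
#'   (input proportions, per-sample probabilities, `Z`, `s_exp`, `D_exp` per
#'   IP, and a `k_exceeds_Z` warning flag per IP).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    gt <- sim_gene_table(config)
    mass_h <- sim_celltype_masses(config, gt, "human", "GFP")
    mass_m <- sim_celltype_masses(config, gt, "mouse", "mCherry")
    m <- config$mixing_fraction
    p_input <- m * mass_h + (1 - m) * mass_m
    p_input <- p_input / sum(p_input)

    ips <- list(IP_HA = "human", IP_V5 = "mouse")
    probs <- matrix(0, nrow(gt), 3,
                    dimnames = list(gt$gene_id,
                                    c("coculture_input", names(ips))))
    probs[, "coculture_input"] <- p_input

    k <- config$offtarget_retain
    non_rep <- gt$species != "reporter"
    truth_ip <- list()
    for (ip in names(ips)) {
      w <- sim_capture_weights(config, gt, ips[[ip]])
      retained <- w * p_input
      probs[, ip] <- retained / sum(retained)
      # Z over the non-reporter universe, input renormalised to it
      Z <- sum(retained[non_rep]) / sum(p_input[non_rep])
      truth_ip[[ip]] <- list(on_target_species = ips[[ip]], Z = Z,
                             s_exp = k / Z - 1, D_exp = 1 - k / Z,
                             k_exceeds_Z = k > Z)
    }

    counts <- vapply(colnames(probs),
                     function(s) stats::rmultinom(1, config$library_size,
                                                  probs[, s])[, 1],
                     numeric(nrow(gt)))
    storage.mode(counts) <- "integer"
    rownames(counts) <- gt$gene_id

    sheet <- tibble::tibble(
      sample_id = c("coculture_input", "IP_HA", "IP_V5"),
      role = c("input", "ip", "ip"),
      antibody = c("none", "HA", "V5"),
      on_target_species = c(NA, "human", "mouse"),
      input_sample_id = c(NA, "coculture_input", "coculture_input"),
      replicate_label = "sim")

    list(gene_table = gt, counts = counts,
         sample_sheet = validate_sample_sheet(sheet),
         truth = list(p_input = p_input, probs = probs, ips = truth_ip,
                      config = config))
  })
}

#' Write a simulated experiment to disk
#'
#' Writes the gene table, a featureCounts-dialect count table, the sample
#' sheet, and the truth record (as JSON, excluding the full probability
#' matrices) under `outdir`.
#'
#' @param sim Result of [simulate_experiment()].
#' @param outdir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gene_table = file.path(outdir, "gene_table.tsv"),
             counts = file.path(outdir, "counts.featureCounts.tsv"),
             sample_sheet = file.path(outdir, "sample_sheet.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_gene_table(sim$gene_table, paths[["gene_table"]])
  write_counts_featurecounts(sim$counts, sim$gene_table, paths[["counts"]])
  write_sample_sheet(sim$sample_sheet, paths[["sample_sheet"]])
  truth_small <- list(ips = sim$truth$ips,
                      config = unclass(sim$truth$config))
  jsonlite::write_json(truth_small, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Simulate a digital-PCR reaction
#'
#' Partitions a reaction at the given template concentration: each partition
#' is positive with probability `1 - exp(-concentration * partition_volume)`
#' (Poisson occupancy), and the number of positive partitions is drawn
#' binomially.
#'
#' @param concentration Template concentration in copies/uL (>= 0).
#' @param n_total Number of partitions.
#' @param partition_volume Partition volume in uL.
#' @param seed Integer seed.
#' @param target Target label carried through to quantification.
#' @param sample_id Sample label.
#' @return A one-row tibble: `sample_id`, `target`, `n_total`, `n_positive`,
#'   `partition_volume`.
#' @export
simulate_dpcr <- function(concentration, n_total = 10000L,
                          partition_volume = 0.001, seed = 1L,
                          target = "target", sample_id = "sample") {
  stopifnot(concentration >= 0, n_total >= 1, partition_volume > 0)
  p_pos <- 1 - exp(-concentration * partition_volume)
  n_positive <- with_local_seed(seed, stats::rbinom(1, n_total, p_pos))
  tibble::tibble(sample_id = sample_id, target = target,
                 n_total = as.integer(n_total),
                 n_positive = as.integer(n_positive),
                 partition_volume = partition_volume)
}
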