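# Chromosome/species proportion tables and IP-vs-input deltas.

test_that("chromosome percentages are direct count shares", {
  gt <- tiny_gene_table()
  cc <- tibble::tibble(chromosome = "h1", count = 100L)
  props <- chrom_proportions(cc, gt, "s", mode = "chromosome_level")
  expect_equal(props$percent, 100)

  cc <- tibble::tibble(chromosome = c("h1", "h_MT", "m1"),
                       count = c(20L, 5L, 75L))
  props <- chrom_proportions(cc, gt, "s", mode = "chromosome_level")
  expect_equal(stats::setNames(props$percent, props$chromosome),
               c(h1 = 20, h_MT = 5, m1 = 75))

  expect_error(
    chrom_proportions(tibble::tibble(chromosome = "h1", count = 0L),
                      gt, "s", mode = "chromosome_level"),
    "empty library")
})

test_that("percentages sum to 100 and are invariant to uniform count scaling", {
  sim <- simulate_experiment(small_sim_config(seed = 21))
  gt <- sim$gene_table
  for (mode in c("all_genes", "protein_coding_only")) {
    props <- chrom_proportions(sim$counts, gt, "IP_HA", mode = mode)
    expect_equal(sum(props$percent), 100, tolerance = 1e-9)
  }
  scaled <- sim$counts * 7L
  p1 <- chrom_proportions(sim$counts, gt, "coculture_input")
  p2 <- chrom_proportions(scaled, gt, "coculture_input")
  expect_equal(p1$percent, p2$percent)
})

test_that("protein-coding-only mode equals brute-force re-summation", {
  sim <- simulate_experiment(small_sim_config(seed = 22))
  gt <- sim$gene_table
  props <- chrom_proportions(sim$counts, gt, "IP_V5",
                             mode = "protein_coding_only")
  # independent summation oracle
  keep <- gt$biotype == "protein_coding" & gt$species != "reporter"
  v <- sim$counts[gt$gene_id[keep], "IP_V5"]
  oracle <- 100 * tapply(v, gt$chromosome[keep], sum) / sum(v)
  expect_equal(stats::setNames(props$percent, props$chromosome),
               c(oracle[props$chromosome]))
  # differs from all_genes exactly by removal of non-coding counts
  all_props <- chrom_proportions(sim$counts, gt, "IP_V5")
  expect_false(isTRUE(all.equal(all_props$percent, props$percent)))
})

test_that("species composition partitions 100 and tracks the mixing fraction", {
  sim <- simulate_experiment(small_sim_config(seed = 23, library_size = 1e6))
  props <- chrom_proportions(sim$counts, sim$gene_table, "coculture_input")
  comp <- species_composition(props, sim$gene_table)
  expect_true(all(comp$percent >= 0))
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)

  gt <- sim$gene_table
  nonrep <- gt$species != "reporter"
  pr <- sim$truth$p_input[nonrep]
  truth_h <- 100 * sum(pr[gt$species[nonrep] == "human"]) / sum(pr)
  obs_h <- comp$percent[comp$species == "human"]
  expect_lt(abs(obs_h - truth_h), 0.2)  # multinomial error at N = 1e6

  # degenerate composition cases
  cc_h <- tibble::tibble(chromosome = c("h1", "h2"), count = c(10L, 30L))
  comp_h <- species_composition(
    chrom_proportions(cc_h, tiny_gene_table(), "s", "chromosome_level"),
    tiny_gene_table())
  expect_equal(comp_h$percent[comp_h$species == "human"], 100)
})

test_that("delta tables subtract percents, classify targets, and conserve mass", {
  gt <- tiny_gene_table()
  cc <- tibble::tibble(chromosome = c("h1", "h2", "m1", "m2"),
                       count = c(40L, 40L, 15L, 5L))
  pin <- chrom_proportions(cc, gt, "inp", "chromosome_level")
  # identical samples -> all deltas zero
  d0 <- delta_table(pin, pin, gt, "human")
  expect_true(all(d0$delta_percent == 0))

  # fully removing an off-target chromosome with 5% of input reads gives a
  # delta of -5 percentage points when the rest rescales... measured on the
  # unnormalised pair the magnitude equals its initial share
  cc_ip <- cc
  cc_ip$count[cc_ip$chromosome == "m2"] <- 0L
  pip <- chrom_proportions(cc_ip, gt, "ip", "chromosome_level")
  d <- delta_table(pin, pip, gt, "human")
  expect_equal(sum(d$delta_percent), 0, tolerance = 1e-9)
  expect_equal(d$target_class,
               c("on", "on", "off", "off")[match(d$chromosome,
                                                 c("h1", "h2", "m1", "m2"))])

  # random simulated pair: deltas conserve to zero
  sim <- simulate_experiment(small_sim_config(seed = 24))
  p_in <- chrom_proportions(sim$counts, sim$gene_table, "coculture_input")
  p_ip <- chrom_proportions(sim$counts, sim$gene_table, "IP_HA")
  ds <- delta_table(p_in, p_ip, sim$gene_table, "human")
  expect_equal(sum(ds$delta_percent), 0, tolerance = 1e-9)
  expect_true(all(ds$is_mito[ds$chromosome %in% c("hg38_MT", "mm10_MT")]))

  expect_error(delta_table(pin, chrom_proportions(
    sim$counts, sim$gene_table, "IP_HA"), gt, "human"),
    "different chromosomes|different modes")
})

test_that("full off-target depletion makes each delta equal its initial percent", {
  fx <- full_depletion_fixture()
  pin <- chrom_proportions(fx$input, fx$gene_table, "inp", "chromosome_level")
  pip <- chrom_proportions(fx$ip, fx$gene_table, "ip", "chromosome_level")
  d <- delta_table(pin, pip, fx$gene_table, "human")
  off <- d[d$target_class == "off", ]
  expect_equal(off$delta_percent, -off$initial_percent, tolerance = 1e-12)
})

test_that("gene-level deltas match brute-force per-gene percentages", {
  gt <- tiny_gene_table()
  counts <- tiny_counts(gt)
  d <- gene_delta(counts, gt, "inp", "ip", "human")
  keep <- gt$species != "reporter"
  v_in <- counts[gt$gene_id[keep], "inp"]
  v_ip <- counts[gt$gene_id[keep], "ip"]
  expect_equal(d$initial_percent, unname(100 * v_in / sum(v_in)))
  expect_equal(d$delta_percent,
               unname(100 * v_ip / sum(v_ip) - 100 * v_in / sum(v_in)))

  # single-gene library: initial 100%, delta 0 when IP is identical
  one <- matrix(c(50L, 80L), 1, 2,
                dimnames = list("hA1", c("inp", "ip")))
  d1 <- gene_delta(one, gt, "inp", "ip", "human")
  expect_equal(d1$initial_percent, 100)
  expect_equal(d1$delta_percent, 0)
})

test_that("on-target mitochondrial genes are depleted in simulated IPs", {
  sim <- simulate_experiment(small_sim_config(seed = 25, library_size = 1e6))
  d <- gene_delta(sim$counts, sim$gene_table, "coculture_input", "IP_HA",
                  "human")
  mito_on <- d[d$is_mito & d$species == "human", ]
  expect_true(all(mito_on$delta_percent < 0))
})
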