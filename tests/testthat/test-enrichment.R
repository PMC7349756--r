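# Ranking, the running-sum enrichment score, and the permutation GSEA.

test_that("ranking statistic is log2 fold change of CPM with stable ties", {
  gt <- tiny_gene_table()
  counts <- tiny_counts(gt)

  r0 <- rank_genes(counts, "inp", "inp")
  expect_true(all(r0$stat == 0))
  # ties broken lexically by gene id
  expect_equal(r0$gene_id, sort(rownames(counts)))

  # uniform doubling cancels in CPM
  doubled <- cbind(inp = counts[, "inp"], ip = counts[, "inp"] * 2L)
  rownames(doubled) <- rownames(counts)
  r2 <- rank_genes(doubled, "inp", "ip")
  expect_true(all(abs(r2$stat) < 1e-12))

  # 5-gene toy table against direct arithmetic
  m <- matrix(c(100L, 200L, 300L, 400L, 0L,
                400L, 100L, 300L, 150L, 50L), ncol = 2,
              dimnames = list(paste0("g", 1:5), c("inp", "ip")))
  r <- rank_genes(m, "inp", "ip", pseudocount = 1)
  cpm <- function(v) 1e6 * v / sum(v)
  expected <- log2((cpm(m[, "ip"]) + 1) / (cpm(m[, "inp"]) + 1))
  expect_equal(stats::setNames(r$stat, r$gene_id),
               expected[order(-expected, names(expected))])
})

test_that("enrichment score matches its definition at the extremes", {
  ranked <- tibble::tibble(gene_id = paste0("g", 1:10), stat = 10:1)
  # a set holding only the top gene peaks at 1 right after position 1
  expect_equal(enrichment_score(ranked, "g1"), 1)
  # a set holding only the bottom gene: maximal deviation just before the hit
  expect_equal(enrichment_score(ranked, "g10"), -1)
  expect_error(enrichment_score(ranked, character(0)), "no members")
  expect_error(enrichment_score(ranked, ranked$gene_id), "whole universe")
  expect_error(enrichment_score(ranked, c("g1", "nope")), "absent")
})

test_that("enrichment score equals the exhaustive running-sum oracle", {
  ranked <- tibble::tibble(gene_id = paste0("g", 1:10), stat = as.numeric(10:1))
  es <- enrichment_score(ranked, c("g1", "g2", "g5"))
  expect_equal(es, es_walk_oracle(ranked$stat, ranked$gene_id,
                                  c("g1", "g2", "g5")))

  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(20:200, 1)
      stats_v <- sort(rnorm(n), decreasing = TRUE)
      ids <- sprintf("g%04d", seq_len(n))
      set <- sample(ids, sample(1:(n - 1), 1))
      expect_equal(enrichment_score(tibble::tibble(gene_id = ids,
                                                   stat = stats_v), set),
                   es_walk_oracle(stats_v, ids, set), tolerance = 1e-12)
    }
  })
})

test_that("enrichment score is invariant under uniform positive scaling", {
  ranked <- tibble::tibble(gene_id = paste0("g", 1:50),
                           stat = sort(rnorm(50), decreasing = TRUE))
  set <- paste0("g", c(2, 9, 17, 40))
  expect_equal(enrichment_score(ranked, set),
               enrichment_score(dplyr::mutate(ranked, stat = stat * 37), set))
})

test_that("our enrichment score agrees with fgsea on a shared example", {
  skip_if_not_installed("fgsea")
  withr::with_seed(13, {
    n <- 100
    stats_v <- sort(rnorm(n), decreasing = TRUE)
    ids <- sprintf("g%03d", seq_len(n))
    sets <- list(A = sample(ids, 15), B = sample(ids, 8))
    ours <- vapply(sets, function(s)
      enrichment_score(tibble::tibble(gene_id = ids, stat = stats_v), s),
      numeric(1))
    theirs <- suppressWarnings(
      fgsea::fgsea(sets, stats::setNames(stats_v, ids), nperm = 11,
                   gseaParam = 1))
    expect_equal(unname(ours[theirs$pathway]), theirs$ES, tolerance = 1e-10)
  })
})

test_that("permutation p-values honour the floor and are seed-reproducible", {
  ranked <- tibble::tibble(gene_id = sprintf("g%03d", 1:60),
                           stat = seq(3, -3, length.out = 60))
  sets <- list(top = sprintf("g%03d", 1:5))
  res <- gsea(ranked, sets, n_perm = 99, seed = 5)
  expect_equal(res$p_value, 1 / 100)
  res2 <- gsea(ranked, sets, n_perm = 99, seed = 5)
  expect_identical(res, res2)
  expect_true(res$es > 0.9)
})

test_that("BH adjustment matches the hand step-up computation", {
  withr::with_seed(41, {
    ranked <- tibble::tibble(gene_id = sprintf("g%03d", 1:80),
                             stat = sort(rnorm(80), decreasing = TRUE))
    sets <- list(a = sample(ranked$gene_id, 10),
                 b = sample(ranked$gene_id, 10),
                 c = sprintf("g%03d", 1:8))
    res <- gsea(ranked, sets, n_perm = 49, seed = 2)
    m <- nrow(res)
    o <- order(res$p_value)
    stepup <- rev(cummin(rev(res$p_value[o] * m / seq_len(m))))
    expect_equal(res$padj[o], pmin(stepup, 1))
  })
})

test_that("small sets are skipped with a message", {
  ranked <- tibble::tibble(gene_id = sprintf("g%03d", 1:30),
                           stat = sort(rnorm(30), decreasing = TRUE))
  sets <- list(ok = ranked$gene_id[1:6], tiny = ranked$gene_id[1:2])
  expect_message(res <- gsea(ranked, sets, n_perm = 19, seed = 1), "tiny")
  expect_equal(res$set, "ok")
})

test_that("biotype sets partition the universe; chromosome sets are protein-coding", {
  gt <- tiny_gene_table()
  bio <- biotype_and_chromosome_sets(gt, "all")
  expect_setequal(names(bio), c("protein_coding", "lncRNA", "pseudogene"))
  expect_setequal(unlist(bio), gt$gene_id[gt$species != "reporter"])
  expect_equal(sum(lengths(bio)), sum(gt$species != "reporter"))

  chr <- biotype_and_chromosome_sets(gt, "protein_coding")
  expect_false(any(c("hA2", "mA2") %in% unlist(chr)))  # lncRNA excluded
  sim <- simulate_experiment(small_sim_config(seed = 33))
  sets <- biotype_and_chromosome_sets(sim$gene_table, "all")
  oracle <- table(sim$gene_table$biotype[sim$gene_table$species != "reporter"])
  expect_equal(lengths(sets)[names(oracle)], c(oracle))
})

test_that("simulated biotype capture differences reproduce the expected signs", {
  sim <- simulate_experiment(small_sim_config(seed = 34, library_size = 5e5))
  ranked <- rank_genes(sim$counts, "coculture_input", "IP_HA")
  # biotype capture is a within-species effect: test over on-target genes
  gt_on <- sim$gene_table[sim$gene_table$species == "human", ]
  sets <- biotype_and_chromosome_sets(gt_on, "all")
  ranked_on <- ranked[ranked$gene_id %in% unlist(sets), ]
  res <- gsea(ranked_on, sets, n_perm = 500, seed = 3)
  expect_gt(res$es[res$set == "protein_coding"], 0)
  expect_lt(res$es[res$set == "lncRNA"], 0)

  pc_sets <- biotype_and_chromosome_sets(gt_on, "protein_coding")
  ranked_pc <- ranked[ranked$gene_id %in% unlist(pc_sets), ]
  es_mt_h <- enrichment_score(ranked_pc, pc_sets[["hg38_MT"]])
  expect_lt(es_mt_h, 0)
})
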