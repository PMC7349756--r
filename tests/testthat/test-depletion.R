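# The delta-vs-initial regression and the depletion-efficiency statistic.

make_deltas <- function(x, y, target_class = "off", species = "mouse",
                        is_mito = FALSE) {
  tibble::tibble(chromosome = paste0("c", seq_along(x)),
                 species = species, is_mito = is_mito,
                 initial_percent = x, delta_percent = y,
                 target_class = target_class)
}

test_that("full depletion gives slope -1, efficiency 1, R-squared 1", {
  fx <- full_depletion_fixture()
  pin <- chrom_proportions(fx$input, fx$gene_table, "inp", "chromosome_level")
  pip <- chrom_proportions(fx$ip, fx$gene_table, "ip", "chromosome_level")
  d <- delta_table(pin, pip, fx$gene_table, "human")
  fit <- fit_depletion(d, "off")
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  expect_equal(fit$depletion_efficiency, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$p_value > 0 && fit$p_value <= 1)
})

test_that("no change gives slope 0 and efficiency 0", {
  d <- make_deltas(c(5, 10, 20, 30), c(0, 0, 0, 0))
  fit <- fit_depletion(d, "off")
  expect_equal(fit$slope, 0)
  expect_equal(fit$depletion_efficiency, 0)
})

test_that("a three-point fixture matches the frozen normal-equation values", {
  # oracle values computed from the closed form: slope = Sxy/Sxx = -0.85,
  # intercept = ybar - slope*xbar = 1, R2 = 1 - SSres/SStot
  d <- make_deltas(c(10, 20, 30), c(-7, -17, -24))
  fit <- fit_depletion(d, "off")
  expect_equal(fit$slope, -0.85, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0.9897260274, tolerance = 1e-8)
  expect_equal(fit$depletion_efficiency, 0.85, tolerance = 1e-12)
})

test_that("lm-based fits agree with the normal-equation oracle on random fixtures", {
  withr::with_seed(99, {
    for (i in 1:100) {
      n <- sample(3:12, 1)
      x <- runif(n, 0, 30)
      y <- -0.6 * x + rnorm(n, sd = 2)
      fit <- fit_depletion(make_deltas(x, y), "off")
      o <- ols_oracle(x, y)
      expect_equal(fit$slope, o$slope, tolerance = 1e-10)
      expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
      expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-10)
      expect_equal(fit$p_value, o$p_value, tolerance = 1e-10)
    }
  })
})

test_that("degenerate geometries are rejected", {
  expect_error(fit_depletion(make_deltas(c(1, 2), c(-1, -2)), "off"),
               "at least 3")
  expect_error(fit_depletion(make_deltas(c(5, 5, 5), c(-1, -2, -3)), "off"),
               "zero variance")
})

test_that("efficiency is invariant to chromosome order and count scaling", {
  sim <- simulate_experiment(small_sim_config(seed = 31))
  gt <- sim$gene_table
  base <- depletion_report(sim$counts, gt, sim$sample_sheet,
                           on_target_fit = FALSE)

  perm <- withr::with_seed(1, sample(nrow(sim$counts)))
  rep_perm <- depletion_report(sim$counts[perm, ], gt, sim$sample_sheet,
                               on_target_fit = FALSE)
  expect_equal(rep_perm$depletion_efficiency, base$depletion_efficiency)

  scaled <- sim$counts
  scaled[, "IP_HA"] <- scaled[, "IP_HA"] * 5L
  rep_scaled <- depletion_report(scaled, gt, sim$sample_sheet,
                                 on_target_fit = FALSE)
  expect_equal(rep_scaled$depletion_efficiency, base$depletion_efficiency)
})

test_that("expected fitted efficiency decreases strictly in k", {
  effs <- vapply(c(0.05, 0.2, 0.5, 0.75), function(k) {
    sim <- simulate_experiment(small_sim_config(seed = 17,
                                                offtarget_retain = k,
                                                library_size = 1e6))
    rep <- depletion_report(sim$counts, sim$gene_table, sim$sample_sheet,
                            include_mito_off = FALSE, on_target_fit = FALSE)
    mean(rep$depletion_efficiency)
  }, numeric(1))
  expect_true(all(diff(effs) < 0))
})

test_that("the report classifies chromosomes by IP target species", {
  sim <- simulate_experiment(small_sim_config(seed = 32))
  gt <- sim$gene_table
  p_in <- chrom_proportions(sim$counts, gt, "coculture_input")
  p_ha <- chrom_proportions(sim$counts, gt, "IP_HA")
  d <- delta_table(p_in, p_ha, gt, "human")
  expect_true(all(d$species[d$target_class == "off"] == "mouse"))
  expect_true(all(d$species[d$target_class == "on"] == "human"))

  rep <- depletion_report(sim$counts, gt, sim$sample_sheet)
  expect_equal(nrow(rep), 4)  # off + on fit per IP
  expect_true(all(is.na(rep$depletion_efficiency[rep$target_class == "on"])))
  # on-target non-mito chromosomes are enriched when retention is partial
  dir <- classify_chromosome_direction(d)
  on_nuc <- dir[dir$target_class == "on" & !dir$is_mito, ]
  expect_true(all(on_nuc$direction == "enriched"))
})

test_that("direction labels follow the sign of the delta", {
  d <- make_deltas(c(1, 2, 3), c(2, -5, 0))
  dir <- classify_chromosome_direction(d)
  expect_equal(dir$direction, c("enriched", "depleted", "unchanged"))
})

test_that("through-origin fits are available for sensitivity analysis", {
  d <- make_deltas(c(10, 20, 30), c(-7, -17, -24))
  fit <- fit_depletion(d, "off", through_origin = TRUE)
  # closed form through origin: slope = sum(xy)/sum(x^2)
  expect_equal(fit$slope, sum(d$initial_percent * d$delta_percent) /
                 sum(d$initial_percent^2), tolerance = 1e-12)
  expect_true(is.na(fit$intercept))
})
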