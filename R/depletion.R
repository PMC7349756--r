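# The depletion-efficiency statistic: ordinary least squares of the
# per-chromosome change in percent of library (IP - input) on the input
# percent, over chromosomes of one target class. For off-target chromosomes
# the negative of the fitted slope is the depletion efficiency; its maximum
# is 1, attained when every off-target chromosome loses exactly its initial
# share.

#' Fit the delta-vs-initial regression for one target class
#'
#' Regresses `delta_percent` on `initial_percent` over the chromosomes of
#' the selected target class. By default mitochondrial chromosomes are kept
#' in off-target fits (they behave like other off-target chromosomes) and
#' dropped from on-target fits (mitochondrial transcripts are not captured by
#' tagged cytosolic ribosomes, so they are the one systematic exception among
#' on-target chromosomes).
#'
#' @param deltas A [delta_table()] tibble.
#' @param target_class `"off"` or `"on"`.
#' @param include_mito Keep mitochondrial chromosomes in the fit; default
#'   `TRUE` for off-target, `FALSE` for on-target.
#' @param through_origin Force the regression line through the origin
#'   (sensitivity analysis; the default fits an intercept).
#' @return A one-row tibble: `target_class`, `species`, `n_chromosomes`,
#'   `slope`, `intercept`, `r_squared`, `p_value` (two-sided t-test of zero
#'   slope), and `depletion_efficiency` (`-slope`, populated for the
#'   off-target class).
#' @export
fit_depletion <- function(deltas, target_class = c("off", "on"),
                          include_mito = NULL, through_origin = FALSE) {
  target_class <- match.arg(target_class)
  if (is.null(include_mito)) include_mito <- target_class == "off"
  d <- deltas[!is.na(deltas$target_class) &
                deltas$target_class == target_class, ]
  if (!include_mito) d <- d[!d$is_mito, ]
  if (nrow(d) < 3L) {
    stop("need at least 3 chromosomes to fit the ", target_class,
         "-target regression, got ", nrow(d), call. = FALSE)
  }
  if (stats::var(d$initial_percent) == 0) {
    stop("zero variance in initial percent: slope undefined", call. = FALSE)
  }
  fml <- if (through_origin) delta_percent ~ 0 + initial_percent
         else delta_percent ~ initial_percent
  fit <- stats::lm(fml, data = d)
  # a perfect fit (e.g. complete off-target depletion) is a legitimate case
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  coefs <- sm$coefficients
  slope_row <- coefs["initial_percent", ]
  p <- slope_row[["Pr(>|t|)"]]
  if (is.nan(p)) p <- NA_real_
  # a perfect fit underflows the t-test; report the smallest positive double
  if (!is.na(p) && p == 0) p <- .Machine$double.xmin
  tibble::tibble(
    target_class = target_class,
    species = paste(sort(unique(d$species)), collapse = "+"),
    n_chromosomes = nrow(d),
    slope = slope_row[["Estimate"]],
    intercept = if (through_origin) NA_real_ else coefs["(Intercept)",
                                                        "Estimate"],
    r_squared = sm$r.squared,
    p_value = p,
    depletion_efficiency = if (target_class == "off")
      -slope_row[["Estimate"]] else NA_real_)
}

#' Depletion report for every IP in a sample sheet
#'
#' For each IP/input pair, computes chromosome proportions in the requested
#' mode, the delta table, and the off-target regression (plus, optionally,
#' the on-target regression), reproducing the per-library report layout of a
#' mixed-species RiboTag experiment: one row per (IP, target class) with
#' slope, R-squared, p-value and depletion efficiency.
#'
#' @param counts Gene-level count matrix, or a named list of chromosome count
#'   tibbles (one per sample) for `mode = "chromosome_level"`.
#' @param gene_table A validated gene table.
#' @param sheet A validated sample sheet; an `rna_yield` column, if present,
#'   is passed through to the report.
#' @param mode Quantification mode (see [chrom_proportions()]).
#' @param on_target_fit Also fit the on-target regression.
#' @param include_mito_off,include_mito_on Mitochondrial handling per class.
#' @param through_origin Force regressions through the origin.
#' @return A tibble with one row per (IP, target class).
#' @export
depletion_report <- function(counts, gene_table, sheet,
                             mode = "all_genes", on_target_fit = TRUE,
                             include_mito_off = TRUE,
                             include_mito_on = FALSE,
                             through_origin = FALSE) {
  gene_table <- validate_gene_table(gene_table)
  sheet <- validate_sample_sheet(sheet)
  pairs <- pair_samples(sheet)
  yield <- if ("rna_yield" %in% names(sheet)) {
    stats::setNames(sheet$rna_yield, sheet$sample_id)
  } else NULL

  props_for <- function(sample_id) {
    if (is.matrix(counts)) {
      chrom_proportions(counts, gene_table, sample_id, mode = mode)
    } else {
      if (mode != "chromosome_level") {
        stop("list-of-chromosome-tables input requires mode ",
             "'chromosome_level'", call. = FALSE)
      }
      chrom_proportions(counts[[sample_id]], gene_table, sample_id,
                        mode = "chromosome_level")
    }
  }

  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    deltas <- delta_table(props_for(pr$input_sample),
                          props_for(pr$ip_sample),
                          gene_table, pr$on_target_species)
    classes <- if (on_target_fit) c("off", "on") else "off"
    for (cl in classes) {
      f <- fit_depletion(deltas, cl,
                         include_mito = if (cl == "off") include_mito_off
                                        else include_mito_on,
                         through_origin = through_origin)
      f <- tibble::add_column(f,
                              ip_sample = pr$ip_sample,
                              input_sample = pr$input_sample,
                              antibody = pr$antibody,
                              on_target_species = pr$on_target_species,
                              .before = 1)
      if (!is.null(yield)) f$rna_yield <- unname(yield[pr$ip_sample])
      rows[[length(rows) + 1L]] <- f
    }
  }
  dplyr::bind_rows(rows)
}

#' Classify chromosomes as enriched or depleted
#'
#' A chromosome whose share of the library grew after IP is enriched
#' (positive delta, above the zero guide line of the delta-vs-initial
#' scatter); one whose share shrank is depleted; exact zero is unchanged.
#'
#' @param deltas A [delta_table()] tibble.
#' @return The table with an added `direction` column.
#' @export
classify_chromosome_direction <- function(deltas) {
  deltas$direction <- dplyr::case_when(
    deltas$delta_percent > 0 ~ "enriched",
    deltas$delta_percent < 0 ~ "depleted",
    TRUE ~ "unchanged")
  deltas
}
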