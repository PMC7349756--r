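# Figure suite. Plots are conveniences: every number shown is available in a
# written table, and plot failures never abort a run.

#' Delta-vs-initial chromosome scatter
#'
#' The diagnostic scatter for one IP: per-chromosome change in percent of
#' library (IP - input) against the input percent, coloured by species, with
#' mitochondrial chromosomes flagged and a dotted guide line at zero — points
#' above it are enriched, below it depleted.
#'
#' @param deltas A [delta_table()] tibble.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_delta_scatter <- function(deltas, title = "IP vs input") {
  ggplot2::ggplot(deltas,
                  ggplot2::aes(x = .data$initial_percent,
                               y = .data$delta_percent,
                               colour = .data$species,
                               shape = .data$is_mito)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted",
                        colour = "red") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = "Input (% uniquely mapping reads)",
                  y = "Change (IP - input, percentage points)",
                  title = title, shape = "mitochondrial") +
    ggplot2::theme_bw()
}

#' Species composition per sample
#'
#' Dot plot of the percent of reads assigned to each species per sample,
#' lines connecting samples of a matched set.
#'
#' @param comp A [species_composition()] tibble.
#' @return A ggplot object.
#' @export
plot_species_composition <- function(comp) {
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$sample_id,
                                     y = .data$percent,
                                     colour = .data$species,
                                     group = .data$species)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 3) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "% of reads", title = "Species composition") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Depletion efficiency vs fit quality
#'
#' One point per IP: off-target depletion efficiency against the regression
#' R-squared, labelled by antibody. Low-efficiency IPs typically show the
#' weaker correlation.
#'
#' @param report A [depletion_report()] tibble.
#' @return A ggplot object.
#' @export
plot_efficiency <- function(report) {
  off <- report[report$target_class == "off", ]
  ggplot2::ggplot(off, ggplot2::aes(x = .data$depletion_efficiency,
                                    y = .data$r_squared,
                                    colour = .data$antibody)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::xlim(0, 1) + ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Depletion efficiency (-slope)",
                  y = expression(R^2),
                  title = "Off-target depletion per IP") +
    ggplot2::theme_bw()
}

#' GSEA bar plot
#'
#' Signed -log10 adjusted p per gene set (sign from the enrichment score),
#' coloured by whether the set passed the 0.01 adjusted-significance
#' threshold.
#'
#' @param res A [gsea()] result tibble.
#' @param title Plot title.
#' @param alpha Significance threshold on adjusted p (default 0.01).
#' @return A ggplot object.
#' @export
plot_gsea <- function(res, title = "Gene set enrichment", alpha = 0.01) {
  res$signed_logp <- sign(res$es) * -log10(res$padj)
  res$significant <- res$padj < alpha
  ggplot2::ggplot(res, ggplot2::aes(x = stats::reorder(.data$set,
                                                       .data$signed_logp),
                                    y = .data$signed_logp,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "purple",
                                          `FALSE` = "steelblue")) +
    ggplot2::labs(x = NULL, y = expression(sign(ES) %*% -log[10](p[adj])),
                  title = title,
                  fill = sprintf("p[adj] < %.2g", alpha)) +
    ggplot2::theme_bw()
}

#' Write the figure suite for a run
#'
#' Best effort: each figure is attempted in PDF and PNG; failures are
#' messaged, never raised.
#'
#' @param tables List with elements `deltas` (named list of delta tables),
#'   `species`, `report`, `gsea`.
#' @param dir Output directory.
#' @param formats Devices to try.
#' @return Character vector of files written.
#' @export
plot_suite <- function(tables, dir, formats = c("pdf", "png")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  save_plot <- function(p, stem) {
    for (fmt in formats) {
      f <- file.path(dir, paste0(stem, ".", fmt))
      ok <- tryCatch({
        suppressMessages(ggplot2::ggsave(f, p, width = 7, height = 5))
        TRUE
      }, error = function(e) {
        message("figure ", f, " skipped: ", conditionMessage(e))
        FALSE
      })
      if (ok) written <<- c(written, f)
    }
  }
  if (!is.null(tables$deltas)) {
    for (ip in names(tables$deltas)) {
      save_plot(plot_delta_scatter(tables$deltas[[ip]], title = ip),
                paste0("delta_scatter_", ip))
    }
  }
  if (!is.null(tables$species)) {
    save_plot(plot_species_composition(tables$species),
              "species_composition")
  }
  if (!is.null(tables$report)) {
    save_plot(plot_efficiency(tables$report), "depletion_efficiency")
  }
  if (!is.null(tables$gsea)) {
    g <- tables$gsea
    for (key in unique(paste(g$ip_sample, g$universe, sep = "."))) {
      sub <- g[paste(g$ip_sample, g$universe, sep = ".") == key, ]
      save_plot(plot_gsea(sub, title = key), paste0("gsea_", key))
    }
  }
  written
}
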