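# One-command orchestration: simulate (or load) -> composition -> depletion
# -> GSEA -> reporter, with every table written under a run directory plus a
# manifest (checksums, versions, seed, timings). Re-running with the same
# config and inputs reproduces all non-plot outputs bit-identically.

#' Build a pipeline run configuration
#'
#' Either `simulate = TRUE` with a [sim_config()] in `sim`, or paths to a
#' gene table, featureCounts-dialect count table and sample sheet.
#'
#' @param outdir Run directory (created; outputs never overwrite inputs).
#' @param simulate Generate inputs with [simulate_experiment()].
#' @param sim A [sim_config()] (used when `simulate = TRUE`).
#' @param counts,gene_table,sample_sheet Input paths (real-data mode).
#' @param mito_chroms Mitochondrial chromosome names for annotation reading.
#' @param mode Quantification mode for composition/depletion.
#' @param include_mito_off,include_mito_on,through_origin Regression options,
#'   see [fit_depletion()].
#' @param pseudocount,n_perm,min_size,weight_exponent GSEA options.
#' @param partitions Optional path to a dPCR partition TSV (`sample_id`,
#'   `target`, `n_total`, `n_positive`, `partition_volume`).
#' @param seed Integer seed covering every stochastic step.
#' @param plots Write figures.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir,
                       simulate = TRUE,
                       sim = sim_config(),
                       counts = NULL, gene_table = NULL, sample_sheet = NULL,
                       mito_chroms = default_mito_chroms(),
                       mode = "all_genes",
                       include_mito_off = TRUE, include_mito_on = FALSE,
                       through_origin = FALSE,
                       pseudocount = 1, n_perm = 1000L, min_size = 5L,
                       weight_exponent = 1,
                       partitions = NULL,
                       seed = 1L,
                       plots = TRUE) {
  cfg <- as.list(environment())
  if (!simulate && (is.null(counts) || is.null(gene_table) ||
                    is.null(sample_sheet))) {
    stop("real-data mode needs counts, gene_table and sample_sheet paths",
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; a `sim` mapping, if present,
#' is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> composition -> depletion -> GSEA -> reporter,
#' writing every table under `config$outdir` and returning a manifest. Any
#' stage error aborts with the stage name. Plot output is best-effort and
#' never affects numeric outputs.
#'
#' @param config A [run_config()] list.
#' @return The run manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  outputs <- character(0)
  stage <- function(name, code) {
    ts <- Sys.time()
    res <- tryCatch(force(code), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    res
  }
  emit <- function(x, name) {
    p <- file.path(outdir, name)
    write_tsv_canonical(x, p)
    outputs <<- c(outputs, p)
    p
  }

  # --- inputs -------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim <- stage("simulate", {
      cfg <- config$sim
      cfg$seed <- as.integer(config$seed)
      sim <- simulate_experiment(cfg)
      paths <- write_simulation(sim, file.path(outdir, "inputs"))
      outputs <<- c(outputs, unname(paths))
      sim
    })
    gt <- sim$gene_table
    counts <- sim$counts
    sheet <- sim$sample_sheet
  } else {
    loaded <- stage("load", {
      gt <- read_gene_table(config$gene_table, config$mito_chroms)
      list(gt = gt,
           counts = read_counts_featurecounts(config$counts, gt),
           sheet = read_sample_sheet(config$sample_sheet))
    })
    gt <- loaded$gt; counts <- loaded$counts; sheet <- loaded$sheet
  }

  # --- composition --------------------------------------------------------
  comp <- stage("composition", {
    props <- dplyr::bind_rows(lapply(colnames(counts), function(s) {
      chrom_proportions(counts, gt, s, mode = config$mode)
    }))
    emit(props, "chrom_proportions.tsv")
    spc <- species_composition(props, gt)
    emit(spc, "species_composition.tsv")
    pairs <- pair_samples(sheet)
    deltas <- lapply(seq_len(nrow(pairs)), function(i) {
      pr <- pairs[i, ]
      d <- delta_table(props[props$sample_id == pr$input_sample, ],
                       props[props$sample_id == pr$ip_sample, ],
                       gt, pr$on_target_species)
      d <- classify_chromosome_direction(d)
      emit(tibble::add_column(d, ip_sample = pr$ip_sample, .before = 1),
           paste0("delta_", pr$ip_sample, ".tsv"))
      d
    })
    names(deltas) <- pairs$ip_sample
    list(props = props, species = spc, deltas = deltas, pairs = pairs)
  })

  # --- depletion ----------------------------------------------------------
  report <- stage("depletion", {
    rep <- depletion_report(counts, gt, sheet, mode = config$mode,
                            include_mito_off = config$include_mito_off,
                            include_mito_on = config$include_mito_on,
                            through_origin = config$through_origin)
    emit(rep, "depletion_report.tsv")
    p <- file.path(outdir, "depletion_report.json")
    jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA)
    outputs <<- c(outputs, p)
    rep
  })

  # --- gsea ---------------------------------------------------------------
  gsea_tabs <- stage("gsea", {
    pairs <- comp$pairs
    out <- list()
    for (i in seq_len(nrow(pairs))) {
      pr <- pairs[i, ]
      ranked <- rank_genes(counts, pr$input_sample, pr$ip_sample,
                           pseudocount = config$pseudocount)
      # biotype and chromosome enrichment are within-species questions
      # (capture differs by biotype among captured transcripts); restrict
      # the universe to the IP's on-target species so the cross-species
      # composition shift does not drown the biotype signal
      gt_on <- gt[gt$species == pr$on_target_species, ]
      for (uni in c("all", "protein_coding")) {
        sets <- biotype_and_chromosome_sets(gt_on, uni)
        ranked_uni <- ranked[ranked$gene_id %in% unlist(sets), ]
        res <- gsea(ranked_uni, sets, n_perm = config$n_perm,
                    seed = config$seed + i, min_size = config$min_size,
                    weight_exponent = config$weight_exponent)
        res <- tibble::add_column(res, ip_sample = pr$ip_sample,
                                  universe = uni, .before = 1)
        out[[paste(pr$ip_sample, uni, sep = ".")]] <- res
      }
    }
    all <- dplyr::bind_rows(out)
    emit(all, "gsea_results.tsv")
    all
  })

  # --- reporter -----------------------------------------------------------
  reporter_tab <- stage("reporter", {
    ratios <- dplyr::bind_rows(lapply(colnames(counts), function(s) {
      reporter_ratio_from_counts(counts, s)
    }))
    emit(ratios, "reporter_ratios_counts.tsv")
    folds <- NULL
    ips <- comp$pairs$ip_sample
    if (length(ips) >= 2 &&
        all(ratios$defined[match(ips, ratios$sample_id)])) {
      folds <- fold_difference(ratios[ratios$sample_id == ips[1], ],
                               ratios[ratios$sample_id == ips[2], ])
      emit(folds, "reporter_fold_difference.tsv")
    }
    quants <- NULL
    if (!is.null(config$partitions)) {
      parts <- read_tsv_checked(config$partitions,
                                required = c("sample_id", "target", "n_total",
                                             "n_positive",
                                             "partition_volume"))
      quants <- dpcr_concentration(parts)
      emit(quants, "dpcr_quantification.tsv")
    }
    list(ratios = ratios, folds = folds, quants = quants)
  })

  # --- plots --------------------------------------------------------------
  if (isTRUE(config$plots)) {
    stage("plots", {
      figdir <- file.path(outdir, "figures")
      figs <- plot_suite(list(deltas = comp$deltas, species = comp$species,
                              report = report, gsea = gsea_tabs), figdir)
      outputs <<- c(outputs, figs)
      NULL
    })
  }

  # --- manifest -----------------------------------------------------------
  cfg_path <- file.path(outdir, "run_config.yaml")
  cfg_serial <- unclass(config)
  cfg_serial$sim <- if (inherits(cfg_serial$sim, "sim_config"))
    unclass(cfg_serial$sim) else cfg_serial$sim
  yaml::write_yaml(cfg_serial, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ribotagr")),
    r_version = R.version.string,
    seed = config$seed,
    mode = config$mode,
    flags = list(include_mito_off = config$include_mito_off,
                 include_mito_on = config$include_mito_on,
                 through_origin = config$through_origin,
                 pseudocount = config$pseudocount,
                 n_perm = config$n_perm),
    timings_sec = timings,
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)),
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
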