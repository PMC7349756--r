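# Absolute reporter-transcript quantification from digital-PCR partition
# counts, and the mCherry/GFP ratio that proxies the cell-type mixture of an
# RNA sample when each cell type carries one reporter.

#' Poisson concentration estimate from dPCR partitions
#'
#' With template molecules Poisson-distributed over equal-volume partitions,
#' the mean copies per partition is `lambda = -ln(1 - f)` where `f` is the
#' positive-partition fraction, and the concentration is
#' `lambda / partition_volume`. The 95% interval is the exact binomial
#' (Clopper-Pearson) interval on `f` propagated through the same transform.
#' A saturated reaction (`n_positive == n_total`) is an error: the
#' concentration is unbounded and the sample must be diluted, not reported.
#'
#' @param partitions A data frame with columns `sample_id`, `target`,
#'   `n_total`, `n_positive`, `partition_volume` (one row per reaction),
#'   e.g. from [simulate_dpcr()].
#' @return A tibble `sample_id`, `target`, `concentration` (copies/uL),
#'   `conc_lo`, `conc_hi`, `zero_positive` flag.
#' @export
dpcr_concentration <- function(partitions) {
  req <- c("sample_id", "target", "n_total", "n_positive", "partition_volume")
  stopifnot(all(req %in% names(partitions)))
  with(partitions, {
    if (any(n_positive < 0 | n_positive > n_total)) {
      stop("n_positive must lie in [0, n_total]", call. = FALSE)
    }
    if (any(partition_volume <= 0)) {
      stop("partition_volume must be positive", call. = FALSE)
    }
    if (any(n_positive == n_total)) {
      stop("saturated reaction (all partitions positive): ",
           "concentration is unbounded", call. = FALSE)
    }
  })
  out <- lapply(seq_len(nrow(partitions)), function(i) {
    p <- partitions[i, ]
    f <- p$n_positive / p$n_total
    lambda <- -log(1 - f)
    ci <- stats::binom.test(p$n_positive, p$n_total)$conf.int
    # the upper binomial bound can be 1 only when n_positive == n_total,
    # which is excluded above, so the transform stays finite
    tibble::tibble(sample_id = p$sample_id, target = p$target,
                   concentration = lambda / p$partition_volume,
                   conc_lo = -log(1 - ci[1]) / p$partition_volume,
                   conc_hi = -log(1 - ci[2]) / p$partition_volume,
                   zero_positive = p$n_positive == 0L)
  })
  dplyr::bind_rows(out)
}

#' mCherry/GFP ratio of one sample
#'
#' @param quants A [dpcr_concentration()] tibble holding both targets for one
#'   sample.
#' @param context Label for the sample's role (co-culture, HA IP, V5 IP).
#' @param mcherry,gfp Target labels.
#' @return A one-row tibble `sample_id`, `context`, `ratio`, `defined`. When
#'   either target was not detected the ratio is `NA` with `defined = FALSE`
#'   rather than 0 or infinity.
#' @export
reporter_ratio <- function(quants, context = "co-culture",
                           mcherry = "mCherry", gfp = "GFP") {
  qm <- quants[quants$target == mcherry, ]
  qg <- quants[quants$target == gfp, ]
  if (nrow(qm) != 1L || nrow(qg) != 1L) {
    stop("need exactly one quantification per target", call. = FALSE)
  }
  defined <- !qm$zero_positive && !qg$zero_positive && qg$concentration > 0
  tibble::tibble(sample_id = qm$sample_id, context = context,
                 ratio = if (defined) qm$concentration / qg$concentration
                         else NA_real_,
                 defined = defined)
}

#' Fold difference between two reporter ratios
#'
#' The headline comparison of a two-IP experiment: how many-fold the
#' mCherry/GFP ratio differs between the two IP fractions. Always reported
#' as larger/smaller (>= 1) with a direction label.
#'
#' @param ratio_a,ratio_b One-row [reporter_ratio()] tibbles.
#' @return A one-row tibble `fold`, `higher_context`, `lower_context`.
#' @export
fold_difference <- function(ratio_a, ratio_b) {
  if (!isTRUE(ratio_a$defined) || !isTRUE(ratio_b$defined)) {
    stop("both ratios must be defined to form a fold difference",
         call. = FALSE)
  }
  a <- ratio_a$ratio; b <- ratio_b$ratio
  if (a >= b) {
    tibble::tibble(fold = a / b, higher_context = ratio_a$context,
                   lower_context = ratio_b$context)
  } else {
    tibble::tibble(fold = b / a, higher_context = ratio_b$context,
                   lower_context = ratio_a$context)
  }
}

#' mCherry/GFP ratio from sequencing read counts
#'
#' A sequencing-based proxy for the dPCR ratio: the ratio of reporter read
#' counts in one library.
#'
#' @param counts Gene-level count matrix containing the reporter genes.
#' @param sample Column name in `counts`.
#' @param context Label for the sample's role.
#' @param mcherry,gfp Reporter gene ids.
#' @return A one-row tibble as in [reporter_ratio()].
#' @export
reporter_ratio_from_counts <- function(counts, sample, context = sample,
                                       mcherry = "mCherry", gfp = "GFP") {
  for (g in c(mcherry, gfp)) {
    if (!g %in% rownames(counts)) {
      stop("reporter gene not in counts: ", g, call. = FALSE)
    }
  }
  cm <- counts[mcherry, sample]
  cg <- counts[gfp, sample]
  defined <- cm > 0 && cg > 0
  tibble::tibble(sample_id = sample, context = context,
                 ratio = if (defined) cm / cg else NA_real_,
                 defined = defined)
}
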