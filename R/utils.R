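# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Write a table in the package's canonical tab-separated dialect
#'
#' All tabular outputs share one dialect: tab-separated, a fixed header row,
#' no quoting, `NA` for missing values, and floating-point columns printed
#' with 6 significant digits.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_canonical <- function(x, path) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- signif(x[[j]], 6)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                         comment.char = "", stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(x)
}
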