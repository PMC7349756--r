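# Sample sheet model: each IP library is analysed against its matched
# co-culture input. One input may serve several IPs (a single lysate split
# across antibodies).

#' Validate a sample sheet
#'
#' A sheet has one row per library with columns `sample_id`, `role`
#' (`input` or `ip`), `antibody` (`HA`, `V5` or `none`), `on_target_species`,
#' `input_sample_id` (required for IPs, absent for inputs) and an optional
#' free-text `replicate_label`. Extra columns (e.g. `rna_yield`) pass through.
#'
#' @param sheet A data frame.
#' @return The validated sheet as a tibble.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "role", "antibody", "on_target_species",
           "input_sample_id")
  missing <- setdiff(req, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sheet <- tibble::as_tibble(sheet)
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sheet", call. = FALSE)
  }
  if (!all(sheet$role %in% c("input", "ip"))) {
    stop("role must be 'input' or 'ip'", call. = FALSE)
  }
  is_na_like <- function(x) is.na(x) | x %in% c("", "none", "NA")
  inp <- sheet$role == "input"
  if (any(!is_na_like(sheet$antibody[inp]))) {
    stop("input samples must have antibody 'none'", call. = FALSE)
  }
  if (any(!is_na_like(sheet$input_sample_id[inp]))) {
    stop("input samples must not reference an input_sample_id", call. = FALSE)
  }
  ipr <- sheet[sheet$role == "ip", ]
  if (any(is_na_like(ipr$input_sample_id))) {
    stop("every ip sample needs an input_sample_id", call. = FALSE)
  }
  inputs <- sheet$sample_id[inp]
  dangling <- setdiff(ipr$input_sample_id, inputs)
  if (length(dangling) > 0L) {
    stop("input_sample_id does not resolve to an input sample: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  if (!all(ipr$antibody %in% c("HA", "V5"))) {
    stop("ip samples must declare antibody HA or V5", call. = FALSE)
  }
  sheet
}

#' Read a sample sheet (TSV or CSV)
#'
#' @param path Path; comma-separated if the extension is `.csv`, otherwise
#'   tab-separated.
#' @return A validated sample sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_tsv_checked(path, required = c("sample_id", "role",
                                               "antibody"))
  if (!"on_target_species" %in% names(sheet)) sheet$on_target_species <- NA
  if (!"input_sample_id" %in% names(sheet)) sheet$input_sample_id <- NA
  for (col in c("sample_id", "role", "antibody", "on_target_species",
                "input_sample_id")) {
    sheet[[col]] <- as.character(sheet[[col]])
  }
  validate_sample_sheet(sheet)
}

#' Write a sample sheet
#'
#' @param sheet A validated sample sheet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv_canonical(validate_sample_sheet(sheet), path)
}

#' Pair each IP library with its matched input
#'
#' @param sheet A validated sample sheet.
#' @return A tibble with one row per IP sample, in sheet order: `ip_sample`,
#'   `input_sample`, `antibody`, `on_target_species`.
#' @export
pair_samples <- function(sheet) {
  sheet <- validate_sample_sheet(sheet)
  ipr <- sheet[sheet$role == "ip", ]
  tibble::tibble(ip_sample = ipr$sample_id,
                 input_sample = ipr$input_sample_id,
                 antibody = ipr$antibody,
                 on_target_species = ipr$on_target_species)
}
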