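#' Construct a beta-value matrix
#'
#' A `beta_matrix` holds methylation beta values (proportion methylated
#' signal, in `[0, 1]`) as a probes-by-samples numeric matrix with unique
#' probe and sample identifiers. Missing values are allowed and encoded as
#' `NA`.
#'
#' @param values Numeric matrix, probes in rows and samples in columns, with
#'   rownames (probe IDs) and colnames (sample IDs).
#' @return An object of class `beta_matrix` (a validated numeric matrix).
#' @examples
#' m <- matrix(c(0.2, 0.8, 0.5, 0.4), nrow = 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' beta_matrix(m)
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "methage_format_error")
  }
  probe_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(probe_ids) || is.null(sample_ids)) {
    abort("`values` must have probe rownames and sample colnames.",
          class = "methage_format_error")
  }
  if (anyDuplicated(probe_ids)) {
    abort(paste0("Duplicate probe IDs: ",
                 paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", ")),
          class = "methage_format_error")
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("Duplicate sample IDs: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")),
          class = "methage_format_error")
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Beta value out of [0, 1] at probe '%s', sample '%s' (value %g).",
      probe_ids[bad[1, 1]], sample_ids[bad[1, 2]], values[bad[1, , drop = FALSE]]),
      class = "methage_validation_error")
  }
  structure(values, class = c("beta_matrix", "matrix", "array"))
}

#' Read a beta-value matrix from TSV
#'
#' The file must be tab-separated with a header row: first column `probe_id`,
#' remaining columns one per sample; `NA` encodes missing values.
#'
#' @param path Path to the TSV file.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()))
  if (!"probe_id" %in% names(df)) {
    abort("Beta matrix TSV must have a `probe_id` first column.",
          class = "methage_format_error")
  }
  values <- as.matrix(df[setdiff(names(df), "probe_id")])
  rownames(values) <- df$probe_id
  beta_matrix(values)
}

#' Write a beta-value matrix to TSV
#'
#' @param betas A [beta_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path) {
  df <- tibble::as_tibble(unclass(betas), rownames = "probe_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix: %d probes x %d samples, %d missing>\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}
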