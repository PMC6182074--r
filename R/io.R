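# CSV readers/writers for the pipeline's tabular artifacts, and accessors for
# the HHCF case-study tables shipped with the package.

#' Read / write a samples-by-features intensity matrix
#'
#' The CSV layout puts sample ids in the first column (`sample_id`) and one
#' column per feature id.
#'
#' @param file CSV path.
#' @return numeric matrix with sample-id row names and feature-id column names.
#' @export
read_intensity_matrix <- function(file) {
  tab <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  rownames(X) <- tab[[1]]
  storage.mode(X) <- "double"
  X
}

#' @rdname read_intensity_matrix
#' @param X intensity matrix.
#' @export
write_intensity_matrix <- function(X, file) {
  tab <- data.frame(sample_id = rownames(X), X, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' Read a per-sample peak table CSV
#'
#' Expects columns `sample_id`, `mode`, `rt_min` (or `rt`), `mz`, `intensity`.
#'
#' @param file CSV path.
#' @return named list of peak tables, one per sample, in file order.
#' @export
read_peak_tables <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if ("rt_min" %in% names(tab)) names(tab)[names(tab) == "rt_min"] <- "rt"
  need <- c("sample_id", "mode", "rt", "mz", "intensity")
  if (!all(need %in% names(tab))) {
    stop("peak table CSV needs columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(tab$sample_id)
  out <- lapply(ids, function(s) {
    as_peak_table(tab[tab$sample_id == s, c("mode", "rt", "mz", "intensity")])
  })
  names(out) <- ids
  out
}

#' Case-study reference tables of the hexa-herbal formula (HHCF)
#'
#' Accessors for the published companion tables shipped as plain-text
#' fixtures: the 12-formula uniform-design percent table
#' (`hhcf_design_percent()`), the putatively identified feature catalog with
#' source-herb attributions (`hhcf_feature_catalog()`), and the PLS regression
#' coefficients of the 68 features (`hhcf_pls_coefficients()`).
#'
#' @return a data frame (design: run labels + six percent columns; catalog:
#'   `feature_id`, `mode`, `rt`, `mz`, `adduct`, `source_herbs`,
#'   `putative_identity`; coefficients: `feature_id`, `rc`).
#' @export
hhcf_design_percent <- function() {
  utils::read.csv(system.file("extdata", "hhcf_design_percent.csv",
                              package = "spectreff"),
                  stringsAsFactors = FALSE)
}

#' @rdname hhcf_design_percent
#' @export
hhcf_feature_catalog <- function() {
  utils::read.csv(system.file("extdata", "hhcf_feature_catalog.csv",
                              package = "spectreff"),
                  stringsAsFactors = FALSE)
}

#' @rdname hhcf_design_percent
#' @export
hhcf_pls_coefficients <- function() {
  utils::read.csv(system.file("extdata", "hhcf_pls_coefficients.csv",
                              package = "spectreff"),
                  stringsAsFactors = FALSE)
}
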