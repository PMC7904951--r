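#' Write a result table to TSV
#'
#' Deterministic rendering: tab-separated with a header row, rows sorted by
#' `gene_id` unless a `rank` column fixes an order, floating-point columns
#' rendered to 6 significant digits.
#'
#' @param table A data frame of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(table, path) {
  tab <- as_tibble(table)
  if (!"rank" %in% names(tab) && "gene_id" %in% names(tab) && nrow(tab)) {
    tab <- arrange(tab, .data$gene_id)
  }
  tab <- mutate(tab, across(dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read/write abundance matrices with their unit
#'
#' Abundance TSVs carry the unit (RPM or RPKM) in a `# unit=` comment line
#' above the header so a file round-trips to an equivalent object.
#'
#' @param x An `abundance_matrix` tibble (from [compute_rpm()] or
#'   [compute_rpkm()]).
#' @param path File path.
#' @return `write_abundance_matrix()`: `path` invisibly;
#'   `read_abundance_matrix()`: an `abundance_matrix` tibble.
#' @export
write_abundance_matrix <- function(x, path) {
  unit <- attr(x, "unit", exact = TRUE) %||% abort("x has no unit attribute")
  body <- readr::format_tsv(as_tibble(as.data.frame(x)))
  writeLines(c(paste0("# unit=", unit), sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  unit <- sub("^# unit=", "", first)
  if (identical(unit, first)) abort("missing '# unit=' header line")
  if (!unit %in% c("RPM", "RPKM")) abort(paste0("unknown abundance unit: ", unit))
  hdr <- strsplit(readr::read_lines(path, skip = 1, n_max = 1, progress = FALSE), "\t")[[1]]
  tab <- readr::read_tsv(path, skip = 1, show_col_types = FALSE, progress = FALSE,
                         col_types = paste0("c", strrep("d", length(hdr) - 1L)))
  new_abundance(tab, unit)
}

new_abundance <- function(tab, unit, samples = NULL) {
  structure(as_tibble(tab), unit = unit, samples = samples,
            class = c("abundance_matrix", class(tibble())))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("# abundance_matrix (", attr(x, "unit"), "): ", nrow(x), " genes x ",
      ncol(x) - 1L, " samples\n", sep = "")
  NextMethod()
}

#' Unit of an abundance matrix
#' @param x An `abundance_matrix`.
#' @return `"RPM"` or `"RPKM"`.
#' @export
abundance_unit <- function(x) attr(x, "unit", exact = TRUE)
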