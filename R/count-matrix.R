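#' Sample-metadata vocabularies
#'
#' The sample annotation schema is closed: tissues and genotypes outside these
#' vocabularies are rejected at load so that typos never propagate silently
#' into group assignments. Genotype additionally accepts labels of the form
#' `"variant_<name>"` (e.g. `"variant_E454Q"`) for tagged protein variants.
#'
#' @name sample-vocabulary
#' @keywords internal
NULL

.tissue_levels <- c("gonad", "whole_animal", "ip", "mock_ip")
.genotype_levels <- c("wild_type", "mutant", "rescue")

.check_genotype <- function(x) {
  ok <- x %in% .genotype_levels | grepl("^variant_[A-Za-z0-9_.-]+$", x)
  if (!all(ok)) {
    abort(paste0(
      "unknown genotype label(s): ",
      paste(unique(x[!ok]), collapse = ", "),
      " (expected wild_type, mutant, rescue or variant_<label>)"
    ))
  }
  invisible(x)
}

#' Construct a validated count matrix
#'
#' A count matrix is a tibble with a `gene_id` character column followed by
#' one non-negative integer column per sample, carrying the sample metadata
#' as an attribute. Gene and sample order are preserved exactly as given.
#'
#' @param counts A data frame: first column `gene_id`, remaining columns
#'   integer read counts, one per sample.
#' @param samples A data frame of sample metadata with columns `sample_id`,
#'   `tissue`, `genotype`, `temperature_c`, `replicate`. Its `sample_id` set
#'   must equal the count columns; rows are reordered to the column order.
#'
#' @return A `count_matrix` tibble (genes x samples) with a `samples`
#'   attribute holding the metadata tibble.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as_tibble(counts)
  if (ncol(counts) < 2L) abort("counts needs a gene_id column and >= 1 sample column")
  names(counts)[1] <- "gene_id"
  counts$gene_id <- as.character(counts$gene_id)

  dup <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup)) {
    abort(paste0("duplicate gene_id in count matrix: ", paste(unique(dup), collapse = ", ")))
  }

  for (j in seq(2L, ncol(counts))) {
    v <- counts[[j]]
    if (!is.numeric(v) || anyNA(v)) {
      abort(paste0("non-numeric or missing counts in column '", names(counts)[j], "'"))
    }
    bad <- which(v < 0 | v != floor(v))
    if (length(bad)) {
      abort(paste0(
        "non-integer or negative count at row ", bad[1],
        " (gene ", counts$gene_id[bad[1]], "), column '", names(counts)[j], "'"
      ))
    }
  }

  samples <- validate_sample_meta(samples)
  cols <- names(counts)[-1]
  if (!setequal(samples$sample_id, cols)) {
    miss <- setdiff(cols, samples$sample_id)
    extra <- setdiff(samples$sample_id, cols)
    abort(paste0(
      "sample metadata does not match count columns",
      if (length(miss)) paste0("; missing metadata for: ", paste(miss, collapse = ", ")),
      if (length(extra)) paste0("; metadata without counts: ", paste(extra, collapse = ", "))
    ))
  }
  samples <- samples[match(cols, samples$sample_id), , drop = FALSE]

  structure(counts, samples = samples,
            class = c("count_matrix", class(tibble())))
}

#' Validate a sample-metadata table
#'
#' @param samples Data frame with columns `sample_id`, `tissue`, `genotype`,
#'   `temperature_c`, `replicate`.
#' @return The metadata as a tibble, vocabulary-checked.
#' @export
validate_sample_meta <- function(samples) {
  samples <- as_tibble(samples)
  need <- c("sample_id", "tissue", "genotype", "temperature_c", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) abort(paste0("sample metadata lacks column(s): ", paste(miss, collapse = ", ")))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in metadata")
  bad_tissue <- setdiff(unique(samples$tissue), .tissue_levels)
  if (length(bad_tissue)) {
    abort(paste0("unknown tissue label(s): ", paste(bad_tissue, collapse = ", ")))
  }
  .check_genotype(samples$genotype)
  if (!is.numeric(samples$temperature_c)) abort("temperature_c must be numeric")
  rep_ok <- is.numeric(samples$replicate) && all(samples$replicate >= 1) &&
    all(samples$replicate == floor(samples$replicate))
  if (!rep_ok) abort("replicate must be a positive integer")
  samples
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("# count_matrix: ", nrow(x), " genes x ", ncol(x) - 1L, " samples\n", sep = "")
  NextMethod()
}

#' Accessors for count and abundance matrices
#'
#' @param x A `count_matrix` or `abundance_matrix`.
#' @return `gene_ids()`: character vector; `sample_ids()`: character vector;
#'   `sample_meta()`: metadata tibble (or `NULL`); `as_gene_matrix()`: a
#'   numeric matrix with gene ids as rownames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
gene_ids <- function(x) x$gene_id

#' @rdname accessors
#' @export
sample_ids <- function(x) setdiff(names(x), "gene_id")

#' @rdname accessors
#' @export
sample_meta <- function(x) attr(x, "samples", exact = TRUE)

#' @rdname accessors
#' @export
as_gene_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read a count matrix from a tab-separated file
#'
#' Expects a UTF-8 TSV with a header row of sample ids and gene ids in the
#' first column. Genes are never dropped or reordered on load.
#'
#' @param path Path to the TSV.
#' @param metadata Sample metadata: a data frame or a path to a metadata TSV
#'   (columns `sample_id`, `tissue`, `genotype`, `temperature_c`, `replicate`).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, metadata) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1, progress = FALSE), "\t")[[1]]
  tab <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = paste0("c", strrep("d", length(hdr) - 1L))
  )
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- read_sample_metadata(metadata)
  }
  count_matrix(tab, metadata)
}

#' Read sample metadata from TSV
#'
#' @param path Path to a TSV with columns `sample_id`, `tissue`, `genotype`,
#'   `temperature_c`, `replicate`.
#' @return A validated metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  validate_sample_meta(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write a count matrix (and its metadata) to TSV
#'
#' @param x A `count_matrix`.
#' @param path Output TSV path for the counts.
#' @param meta_path Optional path for the sample-metadata TSV.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, meta_path = NULL) {
  readr::write_tsv(as_tibble(as.data.frame(x)), path, progress = FALSE)
  if (!is.null(meta_path)) {
    readr::write_tsv(sample_meta(x), meta_path, progress = FALSE)
  }
  invisible(path)
}
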