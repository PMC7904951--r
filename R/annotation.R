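#' Read gene lengths (longest-isoform transcript lengths)
#'
#' Abundances are length-normalised by the longest isoform of each gene: per
#' transcript the length is the sum of its exon lengths (1-based inclusive
#' coordinates, `end - start + 1`, no overlap merging within a transcript),
#' and per gene the maximum over its transcripts.
#'
#' @param path Annotation file: either a TSV with columns `gene_id`,
#'   `length_nt` (and optionally `biotype`), or a GTF whose `exon` features
#'   carry `gene_id` and `transcript_id` attributes.
#' @param format `"tsv"` or `"gtf"`; guessed from the file extension by
#'   default.
#' @return A tibble with columns `gene_id`, `length_nt`, `biotype`.
#' @export
read_gene_lengths <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  ann <- if (format == "gtf") .lengths_from_gtf(path) else .lengths_from_tsv(path)
  if (anyDuplicated(ann$gene_id)) {
    abort(paste0("duplicate gene_id in annotation: ",
                 paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", ")))
  }
  if (any(ann$length_nt <= 0)) {
    abort(paste0("non-positive transcript length for gene(s): ",
                 paste(ann$gene_id[ann$length_nt <= 0], collapse = ", ")))
  }
  ann
}

.lengths_from_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "length_nt") %in% names(tab))) {
    abort("annotation TSV needs columns gene_id and length_nt")
  }
  tibble(
    gene_id = as.character(tab$gene_id),
    length_nt = as.numeric(tab$length_nt),
    biotype = if ("biotype" %in% names(tab)) as.character(tab$biotype) else NA_character_
  )
}

.lengths_from_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GTF annotations requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) abort("GTF contains no exon features")
  df <- tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    width = BiocGenerics::width(gr),
    biotype = if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype) else NA_character_
  )
  if (anyNA(df$gene_id) || anyNA(df$transcript_id)) {
    abort("GTF exon features must carry gene_id and transcript_id attributes")
  }
  df |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(tx_len = sum(.data$width),
              biotype = .data$biotype[1], .groups = "drop") |>
    group_by(.data$gene_id) |>
    summarise(length_nt = max(.data$tx_len),
              biotype = .data$biotype[1], .groups = "drop")
}
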