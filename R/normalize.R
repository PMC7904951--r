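#' Reads-per-million (RPM) normalisation
#'
#' `RPM(g, s) = count(g, s) / total(s) * 1e6`, where `total(s)` is the sum of
#' per-gene counts of sample `s` (the only library total recoverable from a
#' count table). Every column of the result sums to 1e6.
#'
#' @param counts A [count_matrix()].
#' @return An `abundance_matrix` tibble with unit `"RPM"`.
#' @export
compute_rpm <- function(counts) {
  m <- as_gene_matrix(counts)
  totals <- colSums(m)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    abort(paste0("sample(s) with zero total counts: ", paste(zero, collapse = ", ")))
  }
  rpm <- sweep(m, 2, totals, "/") * 1e6
  out <- tibble(gene_id = gene_ids(counts))
  out <- dplyr::bind_cols(out, as_tibble(rpm, .name_repair = "minimal"))
  new_abundance(out, "RPM", samples = sample_meta(counts))
}

#' Reads-per-kilobase-per-million (RPKM) normalisation
#'
#' `RPKM(g, s) = RPM(g, s) * 1e3 / length_nt(g)`, with gene lengths taken as
#' the longest-isoform transcript length from the annotation.
#'
#' @param rpm An `abundance_matrix` with unit `"RPM"` (see [compute_rpm()]).
#' @param annotation A tibble with columns `gene_id`, `length_nt`
#'   (see [read_gene_lengths()]).
#' @return An `abundance_matrix` tibble with unit `"RPKM"`.
#' @export
compute_rpkm <- function(rpm, annotation) {
  if (!identical(abundance_unit(rpm), "RPM")) abort("compute_rpkm expects an RPM matrix")
  len <- annotation$length_nt[match(rpm$gene_id, annotation$gene_id)]
  if (anyNA(len)) {
    abort(paste0("no annotated length for gene(s): ",
                 paste(head(rpm$gene_id[is.na(len)], 20), collapse = ", ")))
  }
  vals <- as_gene_matrix(rpm) * 1e3 / len
  out <- dplyr::bind_cols(tibble(gene_id = rpm$gene_id),
                          as_tibble(vals, .name_repair = "minimal"))
  new_abundance(out, "RPKM", samples = attr(rpm, "samples", exact = TRUE))
}
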