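#' Expressed-gene call from RPKM values
#'
#' A gene is scored as expressed when its mean RPKM across the named samples
#' is strictly greater than the threshold (default RPKM > 1); with two
#' replicates this is the mean-rule reading of the expressed call.
#'
#' @param rpkm An RPKM `abundance_matrix`.
#' @param samples Character vector of sample columns to use (default: all).
#' @param threshold Strict RPKM threshold (default 1).
#' @return Sorted character vector of expressed gene ids.
#' @export
call_expressed <- function(rpkm, samples = NULL, threshold = 1) {
  cols <- samples %||% sample_ids(rpkm)
  if (!length(cols)) abort("empty sample subset")
  miss <- setdiff(cols, sample_ids(rpkm))
  if (length(miss)) abort(paste0("sample(s) not in matrix: ", paste(miss, collapse = ", ")))
  vals <- rowMeans(as_gene_matrix(rpkm)[, cols, drop = FALSE])
  sort(rpkm$gene_id[vals > threshold])
}

#' Classify differential genes by protein binding
#'
#' Intersects the up- and downregulated gene sets with the bound set:
#' class I = upregulated and bound (genes the protein normally represses in
#' the germline), class II = downregulated and bound (genes it sustains);
#' the unbound remainders are kept alongside.
#'
#' @param up,down Disjoint character vectors of up-/downregulated gene ids.
#' @param bound Character vector of bound gene ids.
#' @return A `target_classes` list of sorted sets: `class_i`, `class_ii`,
#'   `up_unbound`, `down_unbound`.
#' @export
classify_targets <- function(up, down, bound) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  bound <- unique(as.character(bound))
  overlap <- intersect(up, down)
  if (length(overlap)) {
    abort(paste0("up and down sets overlap: ", paste(head(overlap, 10), collapse = ", ")))
  }
  structure(list(
    class_i = sort(intersect(up, bound)),
    class_ii = sort(intersect(down, bound)),
    up_unbound = sort(setdiff(up, bound)),
    down_unbound = sort(setdiff(down, bound))
  ), class = "target_classes")
}

#' @export
print.target_classes <- function(x, ...) {
  cat("target_classes: class I n=", length(x$class_i),
      ", class II n=", length(x$class_ii),
      " (up unbound n=", length(x$up_unbound),
      ", down unbound n=", length(x$down_unbound), ")\n", sep = "")
  invisible(x)
}

#' Chi-square test of binding enrichment in a gene set
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2 table of
#' (in group vs rest of universe) x (bound vs unbound). When any expected
#' cell count falls below 1 the result is flagged low-count (the statistic
#' is still computed, with a warning).
#'
#' @param group Gene set tested for binding enrichment (subset of universe).
#' @param universe Background gene set.
#' @param bound Bound gene set (same id space).
#' @return A one-row tibble: the four observed cells (`group_bound`,
#'   `group_unbound`, `rest_bound`, `rest_unbound`), `chi_square`, `p_value`,
#'   `low_count`.
#' @export
binding_enrichment_test <- function(group, universe, bound) {
  group <- unique(as.character(group)); universe <- unique(as.character(universe))
  bound <- unique(as.character(bound))
  out <- setdiff(group, universe)
  if (length(out)) {
    abort(paste0("group not contained in universe: ", paste(head(out, 10), collapse = ", ")))
  }
  rest <- setdiff(universe, group)
  tab <- matrix(c(
    length(intersect(group, bound)), length(setdiff(group, bound)),
    length(intersect(rest, bound)), length(setdiff(rest, bound))
  ), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  low <- any(expected < 1)
  if (low) warn("expected cell count < 1; chi-square approximation is unreliable")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(
    group_bound = tab[1, 1], group_unbound = tab[1, 2],
    rest_bound = tab[2, 1], rest_unbound = tab[2, 2],
    chi_square = unname(ht$statistic), p_value = unname(ht$p.value),
    low_count = low
  )
}

#' Somatic direct-target derivation
#'
#' Genes upregulated in the whole-animal (soma-dominated) comparison that
#' are also bound are direct-target candidates; removing those that are also
#' upregulated in the gonad leaves the somatically repressed targets.
#'
#' @param soma_up Upregulated genes in the whole-animal comparison.
#' @param bound Bound gene set.
#' @param gonad_up Upregulated genes in the gonad comparison.
#' @return A list of sorted sets `candidates` (`soma_up` intersect `bound`)
#'   and `somatic_targets` (candidates minus `gonad_up`).
#' @export
derive_somatic_targets <- function(soma_up, bound, gonad_up) {
  candidates <- sort(intersect(unique(soma_up), unique(bound)))
  list(
    candidates = candidates,
    somatic_targets = sort(setdiff(candidates, unique(gonad_up)))
  )
}

#' Transgene rescue assessment of class-I targets
#'
#' For each class-I gene the mean expression per genotype is compared with
#' the pseudocounted ratio `(rescue + 2) / (wild_type + 2)`: the gene counts
#' as rescued when the rescue-strain expression is within `criterion_fc`-fold
#' of wild type. The per-gene matrix is ordered by descending mutant /
#' wild-type ratio for heat-map rendering.
#'
#' @param expr An RPKM `abundance_matrix` whose sample metadata (or the
#'   `genotypes` argument) assigns each column to `wild_type`, `mutant` or
#'   `rescue`.
#' @param class_i Character vector of class-I gene ids (subset of the
#'   expression universe).
#' @param criterion_fc Rescue criterion fold (default 2).
#' @param pseudocount Pseudocount in the ratio (default 2, as in the SEF).
#' @param genotypes Optional named character vector mapping sample columns to
#'   genotypes, overriding the metadata attribute.
#' @return A `rescue_assessment` list: `genes` (tibble gene_id, wild_type,
#'   mutant, rescue, rescue_ratio, rescued; ordered by mutant/wild-type ratio
#'   descending), `fraction_rescued`, `criterion_fc`.
#' @export
assess_rescue <- function(expr, class_i, criterion_fc = 2, pseudocount = 2,
                          genotypes = NULL) {
  if (is.null(genotypes)) {
    meta <- attr(expr, "samples", exact = TRUE)
    if (is.null(meta)) abort("expr carries no sample metadata; supply `genotypes`")
    genotypes <- setNames(meta$genotype, meta$sample_id)
  }
  need <- c("wild_type", "mutant", "rescue")
  miss <- setdiff(need, unique(genotypes))
  if (length(miss)) abort(paste0("missing genotype(s) in expression matrix: ",
                                 paste(miss, collapse = ", ")))
  class_i <- unique(as.character(class_i))
  absent <- setdiff(class_i, expr$gene_id)
  if (length(absent)) {
    abort(paste0("class-I gene(s) absent from expression matrix: ",
                 paste(head(absent, 10), collapse = ", ")))
  }
  m <- as_gene_matrix(expr)[class_i, , drop = FALSE]
  gmean <- function(g) {
    cols <- names(genotypes)[genotypes == g]
    rowMeans(m[, intersect(colnames(m), cols), drop = FALSE])
  }
  wt <- gmean("wild_type"); mu <- gmean("mutant"); rs <- gmean("rescue")
  genes <- tibble(
    gene_id = class_i,
    wild_type = unname(wt), mutant = unname(mu), rescue = unname(rs),
    rescue_ratio = unname((rs + pseudocount) / (wt + pseudocount)),
    mutant_ratio = unname((mu + pseudocount) / (wt + pseudocount))
  )
  genes$rescued <- genes$rescue_ratio < criterion_fc
  genes <- arrange(genes, desc(.data$mutant_ratio))
  structure(list(
    genes = genes,
    fraction_rescued = if (nrow(genes)) mean(genes$rescued) else NA_real_,
    criterion_fc = criterion_fc
  ), class = "rescue_assessment")
}

#' @export
print.rescue_assessment <- function(x, ...) {
  cat("rescue_assessment: ", nrow(x$genes), " class-I genes, fraction rescued = ",
      format(x$fraction_rescued, digits = 3), "\n", sep = "")
  invisible(x)
}
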