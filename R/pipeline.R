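#' Subset a count matrix by sample
#'
#' @param counts A [count_matrix()].
#' @param samples Character vector of sample ids to keep (order preserved).
#' @return A `count_matrix` with the selected columns and matching metadata.
#' @export
select_samples <- function(counts, samples) {
  miss <- setdiff(samples, sample_ids(counts))
  if (length(miss)) abort(paste0("unknown sample(s): ", paste(miss, collapse = ", ")))
  tab <- as_tibble(as.data.frame(counts))[, c("gene_id", samples)]
  meta <- sample_meta(counts)
  count_matrix(tab, meta[meta$sample_id %in% samples, , drop = FALSE])
}

#' Run the full analysis pipeline
#'
#' Composes the stages end to end: RPM/RPKM normalisation of the RIP pair,
#' IP/mock enrichment and bound-transcript calling; negative-binomial Wald
#' differential expression of mutant vs wild-type gonads (or ingestion of an
#' external DE table); expressed-gene calling; class I/II target
#' classification with chi-square binding-enrichment tests; SEF computation
#' (whole animal vs wild-type gonad) and group comparison; and transgene
#' rescue assessment. All thresholds come from `config`; every count
#' reported is recomputed from the inputs.
#'
#' @param gonad Gonad `count_matrix` with wild_type, mutant and rescue
#'   samples (or a `synthetic_bundle`, in which case the remaining data
#'   arguments are taken from it).
#' @param rip RIP `count_matrix` with `ip` and `mock_ip` tissue samples.
#' @param whole Whole-animal `count_matrix`.
#' @param annotation Gene-length annotation tibble.
#' @param config An [analysis_config()].
#' @param de_table Optional external `de_result` (from [read_de_table()])
#'   bypassing the internal DE stage.
#' @param outdir Optional directory: result tables plus a manifest of file
#'   hashes are written there.
#' @return A `pipeline_report` list with elements `rip_table`, `bound`,
#'   `de`, `up`, `down`, `expressed`, `classes`, `enrichment_tests`, `sef`,
#'   `sef_comparison`, `rescue`, `counts` (named numeric summary),
#'   `config`, and `manifest` (when `outdir` is given).
#' @export
run_pipeline <- function(gonad, rip = NULL, whole = NULL, annotation = NULL,
                         config = analysis_config(), de_table = NULL,
                         outdir = NULL) {
  if (inherits(gonad, "synthetic_bundle")) {
    bundle <- gonad
    gonad <- bundle$gonad; rip <- bundle$rip
    whole <- bundle$whole; annotation <- bundle$annotation
  }

  # --- RIP stage -----------------------------------------------------------
  rip_meta <- sample_meta(rip)
  ip_ids <- rip_meta$sample_id[rip_meta$tissue == "ip"]
  mock_ids <- rip_meta$sample_id[rip_meta$tissue == "mock_ip"]
  if (!length(ip_ids) || !length(mock_ids)) abort("rip matrix needs ip and mock_ip samples")
  rpm_all <- compute_rpm(rip)
  ip_rpm <- rpm_all[, c("gene_id", ip_ids)]
  mock_rpm <- rpm_all[, c("gene_id", mock_ids)]
  attr(ip_rpm, "unit") <- "RPM"; attr(mock_rpm, "unit") <- "RPM"
  ip_rpkm <- compute_rpkm(new_abundance(ip_rpm, "RPM"), annotation)
  rip_table <- ip_enrichment(new_abundance(ip_rpm, "RPM"),
                             new_abundance(mock_rpm, "RPM"), ip_rpkm,
                             pseudocount = config$rip_pseudocount,
                             fc_min = config$rip_fc_min,
                             rpkm_min = config$rip_rpkm_min)
  bound <- call_bound(rip_table, config$rip_fc_min, config$rip_rpkm_min)

  # --- DE stage ------------------------------------------------------------
  gmeta <- sample_meta(gonad)
  de_samples <- gmeta$sample_id[gmeta$genotype %in% c("wild_type", "mutant")]
  if (is.null(de_table)) {
    de_counts <- select_samples(gonad, de_samples)
    grp <- setNames(sample_meta(de_counts)$genotype, sample_meta(de_counts)$sample_id)
    de <- nb_wald_test(de_counts, grp, reference = "wild_type",
                       fc_min = config$de_fc_min, q_max = config$de_q_max,
                       use_raw_p = config$use_raw_p)
  } else {
    de <- de_table
  }
  sets <- filter_de(de, config$de_fc_min, config$de_q_max,
                    use_raw_p = config$use_raw_p)

  # --- expression and classification ---------------------------------------
  gonad_rpkm <- compute_rpkm(compute_rpm(gonad), annotation)
  wt_ids <- gmeta$sample_id[gmeta$genotype == "wild_type"]
  expressed <- call_expressed(gonad_rpkm, wt_ids, config$expressed_rpkm_min)
  classes <- classify_targets(sets$up, sets$down, bound)

  universe <- union(expressed, union(sets$up, sets$down))
  enrichment_tests <- bind_rows(
    mutate(binding_enrichment_test(sets$up, universe, bound), group = "up", .before = 1),
    mutate(binding_enrichment_test(sets$down, universe, bound), group = "down", .before = 1)
  )

  # --- SEF stage -----------------------------------------------------------
  whole_rpkm <- compute_rpkm(compute_rpm(whole), annotation)
  wt_gonad_rpkm <- new_abundance(gonad_rpkm[, c("gene_id", wt_ids)], "RPKM")
  sef <- compute_sef(whole_rpkm, wt_gonad_rpkm, config$sef_pseudocount)
  detected <- sef$gene_id[sef$rpkm_whole > 0 | sef$rpkm_gonad > 0]
  sef_groups <- list(total = detected)
  if (length(intersect(classes$class_i, detected)) >= 2) {
    sef_groups$class_i <- intersect(classes$class_i, detected)
  }
  if (length(intersect(classes$class_ii, detected)) >= 2) {
    sef_groups$class_ii <- intersect(classes$class_ii, detected)
  }
  sef_comparison <- if (length(sef_groups) >= 2) {
    compare_sef_groups(sef, sef_groups, reference = "total")
  } else NULL

  # --- rescue stage --------------------------------------------------------
  rescue <- if (length(classes$class_i) &&
                all(c("wild_type", "mutant", "rescue") %in% gmeta$genotype)) {
    assess_rescue(gonad_rpkm, classes$class_i,
                  criterion_fc = config$rescue_fc_max,
                  pseudocount = config$sef_pseudocount)
  } else NULL

  counts <- c(
    n_genes = nrow(rip_table),
    n_bound = length(bound),
    n_expressed = length(expressed),
    n_up = length(sets$up),
    n_down = length(sets$down),
    n_class_i = length(classes$class_i),
    n_class_ii = length(classes$class_ii),
    fraction_rescued = if (!is.null(rescue)) rescue$fraction_rescued else NA_real_
  )

  report <- structure(list(
    rip_table = rip_table, bound = bound, de = de,
    up = sets$up, down = sets$down, expressed = expressed,
    classes = classes, enrichment_tests = enrichment_tests,
    sef = sef, sef_comparison = sef_comparison, rescue = rescue,
    counts = counts, config = config
  ), class = "pipeline_report")

  if (!is.null(outdir)) {
    report$manifest <- write_report(report, outdir)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (nm in names(x$counts)) {
    cat("  ", nm, " = ", format(x$counts[[nm]], digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Write a pipeline report to disk with a file manifest
#'
#' @param report A `pipeline_report`.
#' @param outdir Output directory (created if needed).
#' @return A manifest tibble (`file`, `md5`), invisibly attached to files
#'   written: the RIP table, DE table, gene-class lists, enrichment tests,
#'   SEF table, rescue matrix and a summary of the run's counts and
#'   thresholds.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wrt <- function(tab, name) {
    p <- file.path(outdir, name)
    write_results_table(tab, p)
    paths <<- c(paths, p)
  }
  wrt(report$rip_table, "rip_table.tsv")
  wrt(as_tibble(as.data.frame(report$de)), "de_result.tsv")
  wrt(report$enrichment_tests, "enrichment_tests.tsv")
  wrt(as_tibble(as.data.frame(report$sef)), "sef.tsv")
  wrt(tibble(gene_id = report$bound), "bound_genes.tsv")
  wrt(tibble(gene_id = report$classes$class_i), "class_i.tsv")
  wrt(tibble(gene_id = report$classes$class_ii), "class_ii.tsv")
  if (!is.null(report$rescue)) wrt(report$rescue$genes, "rescue_matrix.tsv")

  summary_tab <- tibble(
    key = c(names(report$counts),
            paste0("config.", c("rip_fc_min", "rip_rpkm_min", "expressed_rpkm_min",
                                "de_fc_min", "de_q_max", "sef_pseudocount",
                                "rip_pseudocount", "rescue_fc_max"))),
    value = c(unname(report$counts),
              unlist(report$config[c("rip_fc_min", "rip_rpkm_min",
                                     "expressed_rpkm_min", "de_fc_min",
                                     "de_q_max", "sef_pseudocount",
                                     "rip_pseudocount", "rescue_fc_max")]))
  )
  wrt(summary_tab, "summary.tsv")

  tibble(file = basename(paths), md5 = unname(tools::md5sum(paths)))
}
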