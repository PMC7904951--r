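#' Analysis configuration
#'
#' Collects every threshold the pipeline applies, with defaults equal to the
#' printed constants of the underlying study design: bound transcripts call
#' at enrichment FC >= 4 and IP RPKM >= 1 (with the +1 pseudocount in the FC
#' ratio), expressed genes at RPKM > 1, differential genes at fold change > 2
#' with BH-adjusted q < 0.05, SEF pseudocount +2, rescue within 2-fold of
#' wild type, and an Oil Red O stain threshold of 0.05 normalised intensity
#' units.
#'
#' @param rip_fc_min Minimum IP/mock enrichment FC for a bound call
#'   (inclusive).
#' @param rip_rpkm_min Minimum IP-sample RPKM for a bound call (inclusive).
#' @param expressed_rpkm_min Expressed-gene RPKM threshold (strict `>`).
#' @param de_fc_min Differential-expression fold-change threshold (strict).
#' @param de_q_max Differential-expression significance threshold (strict).
#' @param sef_pseudocount Pseudocount added to both RPKMs in the SEF ratio.
#' @param rip_pseudocount Pseudocount added to both RPMs in the enrichment FC.
#' @param rescue_fc_max A class-I gene counts as rescued when its rescue-strain
#'   expression is within this fold of wild type (pseudocounted ratio).
#' @param oro_stain_threshold Red-excess threshold defining stained pixels.
#' @param use_raw_p Use raw p instead of BH q in `filter_de()` (the looser
#'   criterion variant).
#' @param seed Integer seed recorded for provenance.
#' @param provenance Free-text notes on upstream processing (e.g. alignment
#'   and counting parameters); stored, never acted upon — the pipeline's
#'   contract starts at the count table.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(rip_fc_min = 4,
                            rip_rpkm_min = 1,
                            expressed_rpkm_min = 1,
                            de_fc_min = 2,
                            de_q_max = 0.05,
                            sef_pseudocount = 2,
                            rip_pseudocount = 1,
                            rescue_fc_max = 2,
                            oro_stain_threshold = 0.05,
                            use_raw_p = FALSE,
                            seed = 1L,
                            provenance = character()) {
  cfg <- list(
    rip_fc_min = rip_fc_min, rip_rpkm_min = rip_rpkm_min,
    expressed_rpkm_min = expressed_rpkm_min, de_fc_min = de_fc_min,
    de_q_max = de_q_max, sef_pseudocount = sef_pseudocount,
    rip_pseudocount = rip_pseudocount, rescue_fc_max = rescue_fc_max,
    oro_stain_threshold = oro_stain_threshold, use_raw_p = isTRUE(use_raw_p),
    seed = as.integer(seed), provenance = as.character(provenance)
  )
  num <- cfg[c("rip_fc_min", "rip_rpkm_min", "expressed_rpkm_min", "de_fc_min",
               "de_q_max", "sef_pseudocount", "rip_pseudocount",
               "rescue_fc_max", "oro_stain_threshold")]
  bad <- names(num)[!vapply(num, function(v) is.numeric(v) && length(v) == 1L && v > 0, TRUE)]
  if (length(bad)) abort(paste0("thresholds must be positive scalars: ", paste(bad, collapse = ", ")))
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (nm in setdiff(names(x), "provenance")) {
    cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  }
  if (length(x$provenance)) cat("  provenance notes:", length(x$provenance), "\n")
  invisible(x)
}
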