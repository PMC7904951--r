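#' Soma-enrichment factor (SEF)
#'
#' Per gene, `SEF = (RPKM_whole_animal + 2) / (RPKM_gonad + 2)`; the +2
#' pseudocount damps the large ratios that low RPKM values would otherwise
#' produce. Values well above 1 mark soma-biased expression. Replicate
#' columns are averaged before the ratio; the gene universe is the
#' intersection of the two matrices (mismatches are reported via a message).
#'
#' @param rpkm_whole RPKM `abundance_matrix` of the whole-animal dataset.
#' @param rpkm_gonad RPKM `abundance_matrix` of the gonad dataset.
#' @param pseudocount Pseudocount added to both RPKMs (default 2).
#' @return A `sef_tbl` tibble: `gene_id`, `rpkm_whole`, `rpkm_gonad`, `sef`.
#' @export
compute_sef <- function(rpkm_whole, rpkm_gonad, pseudocount = 2) {
  w <- rowMeans(as_gene_matrix(rpkm_whole))
  g <- rowMeans(as_gene_matrix(rpkm_gonad))
  if (any(w < 0) || any(g < 0)) abort("negative RPKM values: corrupt input")
  common <- intersect(names(w), names(g))
  dropped <- length(w) + length(g) - 2L * length(common)
  if (dropped > 0) {
    inform(paste0("compute_sef: ", dropped,
                  " gene id(s) outside the shared universe were dropped"))
  }
  if (!length(common)) abort("no shared genes between whole-animal and gonad matrices")
  structure(
    tibble(
      gene_id = common,
      rpkm_whole = unname(w[common]),
      rpkm_gonad = unname(g[common]),
      sef = unname((w[common] + pseudocount) / (g[common] + pseudocount))
    ),
    class = c("sef_tbl", class(tibble())), pseudocount = pseudocount
  )
}

#' Compare SEF distributions between gene groups
#'
#' Summarises the SEF distribution of named gene sets (e.g. the total
#' detected universe vs class I and class II targets) with quartiles and
#' medians, then tests group differences with a one-way ANOVA on
#' log-transformed SEF and Dunnett contrasts of each group against the
#' reference (equicorrelated multivariate-t adjustment, as in standard
#' many-to-one comparisons). SEF is a ratio, hence the log transform.
#'
#' Groups may overlap (a target class is typically a subset of the total
#' universe); each gene contributes one observation per group containing it,
#' mirroring how grouped box-plot comparisons treat such sets.
#'
#' @param sef A `sef_tbl` from [compute_sef()].
#' @param groups Named list of gene-id vectors; must be subsets of the SEF
#'   universe and nonempty.
#' @param reference Name of the reference group (default `"total"` if
#'   present, else the first group).
#' @return A `sef_comparison` list: `summary` (tibble group, n, q25, median,
#'   q75), `anova` (tibble f_statistic, p_value, df_between, df_within),
#'   `dunnett` (tibble comparison, estimate_log, p_value), `reference`.
#' @export
compare_sef_groups <- function(sef, groups, reference = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("groups must be a named list")
  }
  for (nm in names(groups)) {
    g <- unique(as.character(groups[[nm]]))
    if (!length(g)) abort(paste0("group '", nm, "' is empty"))
    out <- setdiff(g, sef$gene_id)
    if (length(out)) {
      abort(paste0("group '", nm, "' has gene(s) outside the SEF universe: ",
                   paste(head(out, 10), collapse = ", ")))
    }
    groups[[nm]] <- g
  }
  reference <- reference %||% if ("total" %in% names(groups)) "total" else names(groups)[1]
  if (!reference %in% names(groups)) abort(paste0("unknown reference group: ", reference))

  sef_v <- setNames(sef$sef, sef$gene_id)
  long <- imap(groups, function(g, nm) tibble(group = nm, sef = unname(sef_v[g]))) |>
    list_rbind()
  summary_tbl <- long |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(),
              q25 = quantile(.data$sef, 0.25),
              median = median(.data$sef),
              q75 = quantile(.data$sef, 0.75), .groups = "drop")

  testable <- vapply(groups, length, 0L) >= 2L
  anova_tbl <- NULL
  dunnett_tbl <- NULL
  if (length(groups) >= 2L && all(testable)) {
    dat <- long
    dat$group <- factor(dat$group, levels = c(reference, setdiff(names(groups), reference)))
    dat$log_sef <- log(dat$sef)
    fit <- aov(log_sef ~ group, data = dat)
    an <- summary(fit)[[1]]
    anova_tbl <- tibble(
      f_statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
      df_between = an[["Df"]][1], df_within = an[["Df"]][2]
    )
    glt <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(glt)
    dunnett_tbl <- tibble(
      comparison = names(sm$test$coefficients),
      estimate_log = unname(sm$test$coefficients),
      p_value = unname(as.numeric(sm$test$pvalues))
    )
  } else {
    warn("a group has fewer than 2 genes; reporting summaries only, tests skipped")
  }

  structure(list(summary = summary_tbl, anova = anova_tbl,
                 dunnett = dunnett_tbl, reference = reference),
            class = "sef_comparison")
}

#' @export
print.sef_comparison <- function(x, ...) {
  cat("sef_comparison (reference: ", x$reference, ")\n", sep = "")
  print(x$summary)
  if (!is.null(x$anova)) {
    cat("one-way ANOVA on log SEF: F = ", format(x$anova$f_statistic, digits = 4),
        ", p = ", format(x$anova$p_value, digits = 3), "\n", sep = "")
    print(x$dunnett)
  }
  invisible(x)
}
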