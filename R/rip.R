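#' IP/mock enrichment of a RIP-Seq experiment
#'
#' The enrichment of a transcript is the pseudo-counted RPM ratio
#' `FC = (IP RPM + 1) / (mock RPM + 1)`; the +1 keeps the ratio finite and
#' positive for transcripts absent from either library. A transcript is
#' called bound when both `FC >= fc_min` and its IP-sample RPKM
#' `>= rpkm_min` (both comparisons inclusive).
#'
#' When a matrix carries replicate columns they are averaged before the
#' ratio is formed (the ratio is defined on single RPM values).
#'
#' @param ip RPM `abundance_matrix` of the IP sample.
#' @param mock RPM `abundance_matrix` of the mock-IP sample.
#' @param ip_rpkm RPKM `abundance_matrix` of the IP sample.
#' @param pseudocount Pseudocount added to both RPMs (default 1).
#' @param fc_min,rpkm_min Bound-call thresholds (defaults 4 and 1).
#' @return A `rip_tbl` tibble: `gene_id`, `ip_rpm`, `mock_rpm`,
#'   `enrichment_fc`, `ip_rpkm`, `bound`.
#' @export
ip_enrichment <- function(ip, mock, ip_rpkm, pseudocount = 1,
                          fc_min = 4, rpkm_min = 1) {
  if (!identical(abundance_unit(ip), "RPM") || !identical(abundance_unit(mock), "RPM")) {
    abort("ip and mock must be RPM abundance matrices")
  }
  if (!identical(abundance_unit(ip_rpkm), "RPKM")) {
    abort("ip_rpkm must be an RPKM abundance matrix")
  }
  .check_same_universe(list(ip = ip, mock = mock, ip_rpkm = ip_rpkm))

  avg <- function(x) rowMeans(as_gene_matrix(x))
  mock_v <- avg(mock)[ip$gene_id]
  rpkm_v <- avg(ip_rpkm)[ip$gene_id]
  tab <- tibble(
    gene_id = ip$gene_id,
    ip_rpm = unname(avg(ip)),
    mock_rpm = unname(mock_v),
    enrichment_fc = (unname(avg(ip)) + pseudocount) / (unname(mock_v) + pseudocount),
    ip_rpkm = unname(rpkm_v)
  )
  tab$bound <- tab$enrichment_fc >= fc_min & tab$ip_rpkm >= rpkm_min
  structure(tab, class = c("rip_tbl", class(tibble())),
            fc_min = fc_min, rpkm_min = rpkm_min, pseudocount = pseudocount)
}

.check_same_universe <- function(lst) {
  ids <- lapply(lst, function(x) x$gene_id)
  ref <- ids[[1]]
  for (nm in names(ids)[-1]) {
    if (!setequal(ref, ids[[nm]])) {
      d <- c(setdiff(ref, ids[[nm]]), setdiff(ids[[nm]], ref))
      abort(paste0("gene universes differ (", names(ids)[1], " vs ", nm, "); ",
                   "symmetric difference: ", paste(head(d, 20), collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Bound-transcript call from a RIP enrichment table
#'
#' @param table A `rip_tbl` from [ip_enrichment()].
#' @param fc_min Minimum enrichment FC (inclusive).
#' @param rpkm_min Minimum IP RPKM (inclusive).
#' @return Character vector of bound gene ids (sorted).
#' @export
call_bound <- function(table, fc_min = 4, rpkm_min = 1) {
  sort(table$gene_id[table$enrichment_fc >= fc_min & table$ip_rpkm >= rpkm_min])
}

#' Compare RNA-binding across conditions
#'
#' Summarises a set of RIP enrichment tables (e.g. protein variants at two
#' temperatures): per condition the bound-set size, and per ordered pair of
#' conditions the number and fraction of transcripts with higher IP RPM in
#' the first condition — the tabular form of the variant/temperature
#' binding-affinity comparison.
#'
#' @param tables Named list of `rip_tbl` objects sharing a gene universe.
#' @return A list with tibbles `conditions` (condition, n_bound) and `pairs`
#'   (condition_a, condition_b, n_higher, frac_higher, frac_tied).
#' @export
binding_condition_summary <- function(tables) {
  if (length(tables) < 2L) abort("need at least two conditions to compare")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("tables must be a named list of conditions")
  }
  .check_same_universe(tables)
  conds <- tibble(
    condition = names(tables),
    n_bound = map_dbl(tables, ~ sum(.x$bound))
  )
  pairs <- tidyr::expand_grid(condition_a = names(tables), condition_b = names(tables)) |>
    filter(.data$condition_a != .data$condition_b)
  pairs <- pairs |>
    mutate(purrr::pmap_dfr(list(.data$condition_a, .data$condition_b), function(a, b) {
      ta <- tables[[a]]
      tb <- tables[[b]]
      vb <- tb$ip_rpm[match(ta$gene_id, tb$gene_id)]
      tibble(
        n_higher = sum(ta$ip_rpm > vb),
        frac_higher = mean(ta$ip_rpm > vb),
        frac_tied = mean(ta$ip_rpm == vb)
      )
    }))
  list(conditions = conds, pairs = pairs)
}
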