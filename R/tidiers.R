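#' Broom-style tidiers
#'
#' `tidy()` returns the per-gene (or per-comparison) table of a fitted
#' object; `glance()` returns a one-row summary.
#'
#' @param x The object to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @name ripsef-tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname ripsef-tidiers
#' @export
tidy.de_result <- function(x, ...) as_tibble(as.data.frame(x))

#' @rdname ripsef-tidiers
#' @export
glance.de_result <- function(x, ...) {
  tested <- !is.na(x$p_value)
  tibble(
    n_genes = nrow(x), n_tested = sum(tested),
    n_up = sum(x$direction == "up", na.rm = TRUE),
    n_down = sum(x$direction == "down", na.rm = TRUE),
    reference = attr(x, "reference") %||% NA_character_,
    contrast = attr(x, "contrast") %||% NA_character_
  )
}

#' @rdname ripsef-tidiers
#' @export
tidy.rip_tbl <- function(x, ...) as_tibble(as.data.frame(x))

#' @rdname ripsef-tidiers
#' @export
glance.rip_tbl <- function(x, ...) {
  tibble(n_genes = nrow(x), n_bound = sum(x$bound),
         fc_min = attr(x, "fc_min"), rpkm_min = attr(x, "rpkm_min"))
}

#' @rdname ripsef-tidiers
#' @export
tidy.sef_comparison <- function(x, ...) {
  if (is.null(x$dunnett)) return(x$summary)
  x$dunnett
}

#' @rdname ripsef-tidiers
#' @export
glance.sef_comparison <- function(x, ...) {
  if (is.null(x$anova)) return(tibble(f_statistic = NA_real_, p_value = NA_real_))
  x$anova
}

#' @rdname ripsef-tidiers
#' @export
tidy.target_classes <- function(x, ...) {
  bind_rows(
    tibble(class = "class_i", gene_id = x$class_i),
    tibble(class = "class_ii", gene_id = x$class_ii),
    tibble(class = "up_unbound", gene_id = x$up_unbound),
    tibble(class = "down_unbound", gene_id = x$down_unbound)
  )
}

#' @rdname ripsef-tidiers
#' @export
glance.target_classes <- function(x, ...) {
  tibble(n_class_i = length(x$class_i), n_class_ii = length(x$class_ii),
         n_up_unbound = length(x$up_unbound),
         n_down_unbound = length(x$down_unbound))
}

#' @rdname ripsef-tidiers
#' @export
tidy.rescue_assessment <- function(x, ...) x$genes

#' @rdname ripsef-tidiers
#' @export
glance.rescue_assessment <- function(x, ...) {
  tibble(n_class_i = nrow(x$genes), fraction_rescued = x$fraction_rescued,
         criterion_fc = x$criterion_fc)
}
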