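#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed on the genes with positive counts in
#' every sample: each sample's factor is the median of its count ratios to
#' the row-wise geometric mean, rescaled so the factors' geometric mean is 1.
#' When no gene is positive in all samples the factors fall back to
#' total-count ratios (with a warning).
#'
#' @param counts A [count_matrix()].
#' @return A tibble `sample_id`, `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  m <- as_gene_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    warn("no gene with positive counts in every sample; using total-count size factors")
    sf <- colSums(m)
  } else {
    logm <- log(m[pos, , drop = FALSE])
    loggeo <- rowMeans(logm)
    sf <- apply(exp(sweep(logm, 1, loggeo)), 2, median)
  }
  sf <- sf / exp(mean(log(sf)))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

.sf_vector <- function(size_factors, sample_ids) {
  if (is.data.frame(size_factors)) {
    sf <- setNames(size_factors$size_factor, size_factors$sample_id)
  } else {
    sf <- size_factors
  }
  miss <- setdiff(sample_ids, names(sf))
  if (length(miss)) abort(paste0("no size factor for sample(s): ", paste(miss, collapse = ", ")))
  sf[sample_ids]
}

.group_vector <- function(groups, sample_ids) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample_id)
  if (is.null(names(groups))) {
    if (length(groups) != length(sample_ids)) abort("groups must be named by sample_id")
    names(groups) <- sample_ids
  }
  miss <- setdiff(sample_ids, names(groups))
  if (length(miss)) abort(paste0("no group label for sample(s): ", paste(miss, collapse = ", ")))
  as.character(groups[sample_ids])
}

#' Gene-wise negative-binomial dispersion estimation
#'
#' Raw gene-wise dispersions are method-of-moments estimates on size-factor
#' normalised counts, pooled within groups:
#' `alpha_hat = max((s^2 - mu) / mu^2, alpha_floor)` with the within-group
#' variance pooled across groups. A smooth mean-dispersion trend (loess of
#' log dispersion on log mean) is fitted through the raw estimates, and the
#' final per-gene dispersion shrinks the raw estimate toward the trend:
#' `final = (1 - w) * raw + w * trend` with `w = shrink_weight`.
#'
#' @param counts A [count_matrix()].
#' @param groups Group labels: a named character vector (names = sample ids)
#'   or a tibble `sample_id`, `group`.
#' @param size_factors From [estimate_size_factors()] (computed when `NULL`).
#' @param shrink_weight Weight of the trend in the final estimate (default
#'   0.5).
#' @param alpha_floor Lower bound for dispersions (default 1e-8).
#' @return A `dispersion_fit` tibble: `gene_id`, `mean_norm`, `raw`, `trend`,
#'   `final`.
#' @export
estimate_dispersions <- function(counts, groups, size_factors = NULL,
                                 shrink_weight = 0.5, alpha_floor = 1e-8) {
  m <- as_gene_matrix(counts)
  grp <- .group_vector(groups, colnames(m))
  tab_n <- table(grp)
  if (any(tab_n < 2L)) {
    abort(paste0(
      "group(s) with fewer than 2 samples: ",
      paste(names(tab_n)[tab_n < 2L], collapse = ", "),
      "; dispersion cannot be estimated - supply an external DE table instead"
    ))
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- .sf_vector(size_factors, colnames(m))
  norm <- sweep(m, 2, sf, "/")

  mu_all <- rowMeans(norm)
  # pooled within-group variance and mean (df-weighted across groups)
  lv <- lapply(unique(grp), function(g) {
    sub <- norm[, grp == g, drop = FALSE]
    list(df = ncol(sub) - 1L, v = apply(sub, 1, var), mu = rowMeans(sub))
  })
  dfs <- vapply(lv, `[[`, 0L, "df")
  s2 <- Reduce(`+`, Map(function(x) x$df * x$v, lv)) / sum(dfs)
  mu_w <- Reduce(`+`, Map(function(x) x$df * x$mu, lv)) / sum(dfs)
  raw <- pmax((s2 - mu_w) / pmax(mu_w, 1e-12)^2, alpha_floor)
  raw[mu_w <= 0] <- alpha_floor

  trend <- .dispersion_trend(mu_all, raw, alpha_floor)
  final <- pmax((1 - shrink_weight) * raw + shrink_weight * trend, alpha_floor)

  structure(
    tibble(gene_id = rownames(m), mean_norm = unname(mu_all),
           raw = unname(raw), trend = unname(trend), final = unname(final)),
    class = c("dispersion_fit", class(tibble()))
  )
}

.dispersion_trend <- function(mu, raw, alpha_floor) {
  use <- mu > 0 & raw > alpha_floor * 10
  if (sum(use) < 50L) {
    # too few informative genes for a smooth: flat trend at the median
    med <- if (any(use)) median(raw[use]) else max(median(raw), alpha_floor)
    return(rep(med, length(mu)))
  }
  df <- data.frame(x = log(mu[use]), y = log(raw[use]))
  fit <- suppressWarnings(loess(
    y ~ x, data = df, span = 0.6, degree = 1, family = "symmetric",
    control = stats::loess.control(surface = "direct")
  ))
  rng <- range(df$x)
  lx <- pmin(pmax(log(pmax(mu, min(mu[mu > 0]))), rng[1]), rng[2])
  tr <- as.numeric(exp(predict(fit, newdata = data.frame(x = lx))))
  tr[!is.finite(tr)] <- median(raw[use])
  pmax(tr, alpha_floor)
}

# Vectorised Newton solve of the NB mean MLE per gene for one group:
# sum_i (K_i - s_i mu) / (1 + alpha s_i mu) = 0  (monotone in mu).
.nb_group_mean <- function(K, sf, alpha, iter = 40L) {
  mu <- pmax(rowMeans(sweep(K, 2, sf, "/")), 0)
  for (it in seq_len(iter)) {
    denom <- 1 + alpha * outer(rep(1, nrow(K)), sf) * mu   # n x m
    smat <- matrix(sf, nrow(K), length(sf), byrow = TRUE)
    f <- rowSums((K - smat * mu) / denom)
    # derivative wrt mu
    fp <- rowSums(-(smat + alpha * smat * K) / denom^2)
    step <- f / fp
    mu_new <- mu - step
    mu <- ifelse(is.finite(mu_new) & mu_new >= 0, mu_new, mu / 2)
    if (max(abs(step), na.rm = TRUE) < 1e-10) break
  }
  mu
}

#' Negative-binomial Wald test for two groups
#'
#' Per gene the NB log-likelihood is maximised for each group mean (size
#' factors as offsets, the gene's final dispersion held fixed), the log2 fold
#' change is formed from the pseudocounted group means
#' `log2((mu_B + 0.5) / (mu_A + 0.5))`, and the Wald statistic divides it by
#' a standard error from the NB Fisher information evaluated at the
#' pseudocounted means. Two-sided p-values use the normal reference;
#' q-values are Benjamini-Hochberg adjusted over the tested genes. Genes
#' with zero counts in every sample are excluded from testing and from the
#' BH denominator.
#'
#' @param counts A [count_matrix()].
#' @param groups Group labels (see [estimate_dispersions()]); `reference`
#'   names the denominator group.
#' @param size_factors,dispersions Precomputed stages (computed when `NULL`).
#' @param reference Reference (denominator) group label; default the first
#'   label in sort order, so fold changes read `other / reference`.
#' @param fc_min,q_max Thresholds used to annotate `direction`.
#' @param use_raw_p Classify `direction` on raw p instead of q.
#' @return A `de_result` tibble: `gene_id`, `base_mean`, `fold_change`,
#'   `log2fc`, `p_value`, `q_value`, `direction` (`up`/`down`/`ns`; `NA` for
#'   untested all-zero genes).
#' @export
nb_wald_test <- function(counts, groups, size_factors = NULL,
                         dispersions = NULL, reference = NULL,
                         fc_min = 2, q_max = 0.05, use_raw_p = FALSE) {
  m <- as_gene_matrix(counts)
  grp <- .group_vector(groups, colnames(m))
  lev <- sort(unique(grp))
  if (length(lev) != 2L) abort("nb_wald_test requires exactly two groups")
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) abort(paste0("reference group '", reference, "' not among labels"))
  other <- setdiff(lev, reference)

  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- .sf_vector(size_factors, colnames(m))
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, grp, size_factors)
  alpha <- dispersions$final[match(rownames(m), dispersions$gene_id)]
  if (anyNA(alpha)) abort("dispersions missing for some genes")

  tested <- rowSums(m) > 0
  norm <- sweep(m, 2, sf, "/")
  base_mean <- rowMeans(norm)

  iA <- grp == reference
  iB <- grp == other
  muA <- .nb_group_mean(m[, iA, drop = FALSE], sf[iA], alpha)
  muB <- .nb_group_mean(m[, iB, drop = FALSE], sf[iB], alpha)

  muA5 <- muA + 0.5
  muB5 <- muB + 0.5
  log2fc <- log2(muB5 / muA5)

  info <- function(mu, s, a) {
    s2 <- matrix(s^2, length(mu), length(s), byrow = TRUE)
    rowSums(s2 / (outer(mu, s) + a * outer(mu, s)^2))
  }
  varlnA <- 1 / (info(muA5, sf[iA], alpha) * muA5^2)
  varlnB <- 1 / (info(muB5, sf[iB], alpha) * muB5^2)
  se_log2 <- sqrt(varlnA + varlnB) / log(2)

  z <- log2fc / se_log2
  p <- 2 * pnorm(-abs(z))
  p[!tested] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[tested] <- p.adjust(p[tested], method = "BH")

  crit <- if (use_raw_p) p else q
  fc <- 2^log2fc
  direction <- dplyr::case_when(
    !tested ~ NA_character_,
    fc > fc_min & crit < q_max ~ "up",
    fc < 1 / fc_min & crit < q_max ~ "down",
    TRUE ~ "ns"
  )

  structure(
    tibble(gene_id = rownames(m), base_mean = unname(base_mean),
           fold_change = unname(fc), log2fc = unname(log2fc),
           p_value = unname(p), q_value = unname(q), direction = direction),
    class = c("de_result", class(tibble())),
    reference = reference, contrast = other,
    fc_min = fc_min, q_max = q_max, use_raw_p = use_raw_p
  )
}

#' Fold-change / significance filter on a differential result
#'
#' Both inequalities are strict: `up` requires `fold_change > fc_min` and
#' `q_value < q_max` (or raw p when the result was built with `use_raw_p`);
#' `down` symmetrically requires `fold_change < 1/fc_min`.
#'
#' @param result A `de_result` (from [nb_wald_test()] or [read_de_table()]).
#' @param fc_min Fold-change threshold (default 2).
#' @param q_max Significance threshold (default 0.05).
#' @param use_raw_p Filter on raw p instead of q.
#' @return A list with sorted character vectors `up` and `down`.
#' @export
filter_de <- function(result, fc_min = 2, q_max = 0.05, use_raw_p = FALSE) {
  crit <- if (use_raw_p) result$p_value else result$q_value
  ok <- !is.na(crit) & !is.na(result$fold_change)
  list(
    up = sort(result$gene_id[ok & result$fold_change > fc_min & crit < q_max]),
    down = sort(result$gene_id[ok & result$fold_change < 1 / fc_min & crit < q_max])
  )
}

#' Ingest an externally produced differential-expression table
#'
#' Accepts a TSV with columns `gene_id`, `fold_change` and `p_value` and/or
#' `q_value` (e.g. the output of a dedicated DE or microarray package), and
#' returns it in the same shape as [nb_wald_test()] so downstream
#' classification is source-agnostic. When only `p_value` is given,
#' `q_value` is its BH adjustment.
#'
#' @param path Path to the TSV.
#' @return A `de_result` tibble.
#' @export
read_de_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "fold_change") %in% names(tab))) {
    abort("external DE table needs columns gene_id and fold_change")
  }
  if (!"p_value" %in% names(tab) && !"q_value" %in% names(tab)) {
    abort("external DE table needs p_value and/or q_value")
  }
  p <- if ("p_value" %in% names(tab)) tab$p_value else rep(NA_real_, nrow(tab))
  q <- if ("q_value" %in% names(tab)) tab$q_value else p.adjust(p, method = "BH")
  structure(
    tibble(gene_id = as.character(tab$gene_id),
           base_mean = if ("base_mean" %in% names(tab)) tab$base_mean else NA_real_,
           fold_change = tab$fold_change, log2fc = log2(tab$fold_change),
           p_value = p, q_value = q, direction = NA_character_),
    class = c("de_result", class(tibble())), external = TRUE
  )
}
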