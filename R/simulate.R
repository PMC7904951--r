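#' Simulation configuration for the synthetic bundle
#'
#' Defaults mirror the study design the pipeline targets: 5000 genes, two
#' gonad replicates per genotype at 5e6 reads depth, negative-binomial noise
#' (variance `mu + alpha mu^2`, `alpha = 0.05`), 3% of genes planted as
#' class I (germline-repressed direct targets: low wild-type gonad
#' expression, 8-fold up in the mutant gonad, 8-fold soma-enriched), 1% as
#' class II (8-fold down in the mutant gonad), a bound set of 5% of genes at
#' 16-fold IP enrichment, and 80% of class-I genes restored to wild-type
#' expression in the rescue strain.
#'
#' @param n_genes Number of genes.
#' @param depth Expected library size per sample.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline relative expression profile.
#' @param dispersion NB dispersion `alpha` (variance `mu + alpha mu^2`).
#' @param fraction_bound Fraction of genes planted as bound; must be at
#'   least `fraction_class_i + fraction_class_ii` (target classes are bound
#'   by construction).
#' @param fraction_class_i,fraction_class_ii Fractions planted as class I /
#'   class II.
#' @param class_i_fold Mutant-gonad upregulation fold of class-I genes.
#' @param class_ii_fold Mutant-gonad downregulation fold of class-II genes.
#' @param bound_fold IP-over-mock enrichment fold of bound genes (before
#'   library renormalisation).
#' @param soma_fold Soma expression of class-I genes relative to their low
#'   germline level.
#' @param soma_mix Weight of the gonad profile in the whole-animal mixture.
#' @param rescue_efficiency Fraction of class-I genes restored to wild-type
#'   expression in the rescue strain.
#' @param class_i_gonad_counts Range of class-I wild-type gonad mean counts
#'   (log-uniform draw): soma genes detectably, but lowly, expressed in the
#'   germline.
#' @param length_range Transcript-length range in nt (log-uniform draw).
#' @param replicates Gonad replicates per genotype.
#' @param seed Integer seed fixing every draw.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 5000,
                              depth = 5e6,
                              baseline_meanlog = 0,
                              baseline_sdlog = 1.2,
                              dispersion = 0.05,
                              fraction_bound = 0.05,
                              fraction_class_i = 0.03,
                              fraction_class_ii = 0.01,
                              class_i_fold = 8,
                              class_ii_fold = 8,
                              bound_fold = 16,
                              soma_fold = 8,
                              soma_mix = 0.5,
                              rescue_efficiency = 0.8,
                              class_i_gonad_counts = c(20, 200),
                              length_range = c(300, 15000),
                              replicates = 2L,
                              seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(fraction_bound = fraction_bound, fraction_class_i = fraction_class_i,
          fraction_class_ii = fraction_class_ii,
          rescue_efficiency = rescue_efficiency, soma_mix = soma_mix)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (fraction_class_i + fraction_class_ii > 1) abort("class fractions exceed 1")
  if (fraction_class_i + fraction_class_ii > fraction_bound) {
    abort("infeasible fractions: classes I+II must fit inside the bound set")
  }
  folds <- c(class_i_fold, class_ii_fold, bound_fold, soma_fold)
  if (any(folds <= 1)) abort("effect folds must be > 1")
  if (n_genes < 10 || depth <= 0 || dispersion < 0) abort("invalid simulation size parameters")
  cfg$replicates <- as.integer(replicates)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

.rnb <- function(n, mu, alpha) {
  if (alpha <= 0) return(rpois(n, mu))
  rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate a full synthetic bundle with planted ground truth
#'
#' Generates, deterministically under the config seed, every input the
#' pipeline consumes: an IP/mock RIP-Seq pair with a planted bound set,
#' wild-type / mutant / rescue gonad count matrices with planted class-I
#' (up) and class-II (down) genes, a whole-animal sample mixing the gonad
#' profile with a soma profile in which class-I genes are soma-enriched, and
#' a longest-isoform length annotation.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_bundle` list: `gonad` (count_matrix, wild type /
#'   mutant / rescue x replicates), `rip` (count_matrix, ip + mock_ip),
#'   `whole` (count_matrix, one whole-animal sample), `annotation`,
#'   `truth` (list: `bound`, `class_i`, `class_ii`, `rescued`,
#'   `true_means` tibble of per-condition expected counts), and `config`.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("g%05d", seq_len(n))

  lengths_nt <- round(exp(runif(n, log(config$length_range[1]), log(config$length_range[2]))))
  annotation <- tibble(gene_id = ids, length_nt = lengths_nt,
                       biotype = "protein_coding")

  base <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  base_counts <- config$depth * base / sum(base)

  n_bound <- round(n * config$fraction_bound)
  n_ci <- round(n * config$fraction_class_i)
  n_cii <- round(n * config$fraction_class_ii)
  bound_idx <- sample.int(n, n_bound)
  ci_idx <- bound_idx[seq_len(n_ci)]
  cii_idx <- bound_idx[n_ci + seq_len(n_cii)]
  n_resc <- round(n_ci * config$rescue_efficiency)
  resc_idx <- ci_idx[sample.int(n_ci, n_resc)]

  # condition profiles in expected-count units; each is renormalised to depth
  gonad_wt <- base_counts
  gonad_wt[ci_idx] <- exp(runif(n_ci, log(config$class_i_gonad_counts[1]),
                                log(config$class_i_gonad_counts[2])))
  gonad_mut <- gonad_wt
  gonad_mut[ci_idx] <- gonad_wt[ci_idx] * config$class_i_fold
  gonad_mut[cii_idx] <- gonad_wt[cii_idx] / config$class_ii_fold
  gonad_res <- gonad_mut
  gonad_res[resc_idx] <- gonad_wt[resc_idx]

  soma <- base_counts
  soma[ci_idx] <- gonad_wt[ci_idx] * config$soma_fold
  mix <- function(p, q, w) {
    w * p / sum(p) + (1 - w) * q / sum(q)
  }
  whole <- mix(gonad_wt, soma, config$soma_mix)

  mock <- whole
  ip <- mock
  ip[bound_idx] <- mock[bound_idx] * config$bound_fold

  scale_depth <- function(p) config$depth * p / sum(p)
  profiles <- list(
    gonad_wild_type = scale_depth(gonad_wt),
    gonad_mutant = scale_depth(gonad_mut),
    gonad_rescue = scale_depth(gonad_res),
    whole_animal = scale_depth(whole),
    ip = scale_depth(ip),
    mock_ip = scale_depth(mock)
  )

  alpha <- config$dispersion
  reps <- config$replicates
  draw <- function(mu) .rnb(n, mu, alpha)

  gonad_tab <- tibble(gene_id = ids)
  gonad_meta <- NULL
  for (geno in c("wild_type", "mutant", "rescue")) {
    mu <- profiles[[paste0("gonad_", geno)]]
    for (r in seq_len(reps)) {
      sid <- paste0("gonad_", geno, "_", r)
      gonad_tab[[sid]] <- draw(mu)
      gonad_meta <- bind_rows(gonad_meta, tibble(
        sample_id = sid, tissue = "gonad", genotype = geno,
        temperature_c = 25, replicate = r
      ))
    }
  }
  gonad <- count_matrix(gonad_tab, gonad_meta)

  rip_tab <- tibble(gene_id = ids,
                    ip_1 = draw(profiles$ip),
                    mock_1 = draw(profiles$mock_ip))
  rip_meta <- tibble(
    sample_id = c("ip_1", "mock_1"),
    tissue = c("ip", "mock_ip"),
    genotype = c("variant_E454Q", "variant_mock_gfp"),
    temperature_c = 15, replicate = 1L
  )
  rip <- count_matrix(rip_tab, rip_meta)

  whole_tab <- tibble(gene_id = ids, whole_1 = draw(profiles$whole_animal))
  whole_meta <- tibble(sample_id = "whole_1", tissue = "whole_animal",
                       genotype = "wild_type", temperature_c = 25, replicate = 1L)
  whole <- count_matrix(whole_tab, whole_meta)

  truth <- list(
    bound = sort(ids[bound_idx]),
    class_i = sort(ids[ci_idx]),
    class_ii = sort(ids[cii_idx]),
    rescued = sort(ids[resc_idx]),
    true_means = dplyr::bind_cols(tibble(gene_id = ids),
                                  as_tibble(as.data.frame(profiles)))
  )

  structure(list(gonad = gonad, rip = rip, whole = whole,
                 annotation = annotation, truth = truth, config = config),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle: ", x$config$n_genes, " genes; bound n=",
      length(x$truth$bound), ", class I n=", length(x$truth$class_i),
      ", class II n=", length(x$truth$class_ii), "\n", sep = "")
  invisible(x)
}

#' Simulate stained-worm images with known lipid indices
#'
#' Each image is an elliptical worm body (darker than the light background)
#' with circular stain blobs whose red channel exceeds blue by
#' `stain_amplitude`. The true lipid index is recorded analytically as
#' `amplitude * stained_area / worm_area`, with the stained area taken from
#' the painted blob union (so blob overlap is accounted for).
#'
#' @param n_images Number of worms to draw.
#' @param width,height Image size in pixels.
#' @param stain_amplitude Red excess inside stain blobs (0 gives stain-free
#'   images with a true index of 0).
#' @param stain_area_fraction Target fraction of the worm area covered by
#'   blobs (must be < 1).
#' @param n_blobs Number of stain blobs per worm.
#' @param base_intensity Worm body intensity; `background` the background.
#' @param background Background intensity.
#' @param seed Integer seed.
#' @return A list: `images` (list of [worm_image()]), `truth` (tibble
#'   `worm_id`, `worm_area`, `stained_area`, `true_index`).
#' @export
simulate_oro_images <- function(n_images = 6, width = 160, height = 100,
                                stain_amplitude = 0.4,
                                stain_area_fraction = 0.10,
                                n_blobs = 3, base_intensity = 0.55,
                                background = 0.95, seed = 1L) {
  if (stain_area_fraction >= 1) abort("stain blobs cannot exceed the worm area")
  if (stain_amplitude < 0 || base_intensity + stain_amplitude > 1) {
    abort("stain_amplitude must keep intensities within [0, 1]")
  }
  set.seed(seed)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)

  images <- vector("list", n_images)
  truth <- vector("list", n_images)
  for (k in seq_len(n_images)) {
    cx <- width / 2 + runif(1, -4, 4)
    cy <- height / 2 + runif(1, -3, 3)
    ax <- width * runif(1, 0.32, 0.40)
    ay <- height * runif(1, 0.26, 0.34)
    mask <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1

    stain <- matrix(FALSE, height, width)
    if (stain_amplitude > 0 && stain_area_fraction > 0) {
      target <- stain_area_fraction * sum(mask)
      r_blob <- sqrt(target / (n_blobs * pi))
      # sample blob centres away from the body outline so blobs are not
      # clipped and the painted area tracks the analytic target
      shrink <- max(1 - r_blob / min(ax, ay), 0.1)
      core <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= shrink^2
      if (!any(core)) core <- mask
      inside <- which(core, arr.ind = TRUE)
      centers <- inside[sample.int(nrow(inside), n_blobs, replace = TRUE), , drop = FALSE]
      for (b in seq_len(n_blobs)) {
        d2 <- (xs - centers[b, 2])^2 + (ys - centers[b, 1])^2
        stain <- stain | (d2 <= r_blob^2 & mask)
      }
    }

    px <- array(background, c(height, width, 3))
    for (ch in 1:3) {
      chn <- px[, , ch]
      chn[mask] <- base_intensity
      px[, , ch] <- chn
    }
    red <- px[, , 1]
    red[stain] <- base_intensity + stain_amplitude
    px[, , 1] <- red

    images[[k]] <- worm_image(px, mask)
    truth[[k]] <- tibble(
      worm_id = paste0("worm_", k),
      worm_area = sum(mask),
      stained_area = sum(stain),
      true_index = stain_amplitude * sum(stain) / sum(mask)
    )
  }
  list(images = images, truth = list_rbind(truth))
}

#' Recovery metrics of pipeline outputs against planted truth
#'
#' @param truth The `truth` element of a [simulate_bundle()] result.
#' @param bound,class_i,class_ii Called gene sets (character vectors; any
#'   may be `NULL` to skip).
#' @param fraction_rescued Measured rescue fraction (scalar, optional).
#' @param sef A `sef_tbl` (optional) for the class-I-vs-background rank AUC.
#' @return A list: `sets` (tibble set, n_true, n_called, sensitivity,
#'   precision, f1 — `NA` precision/F1 for empty calls), `rescue_error`
#'   (|measured - planted| or `NA`), `sef_auc` (rank AUC or `NA`).
#' @export
evaluate_recovery <- function(truth, bound = NULL, class_i = NULL,
                              class_ii = NULL, fraction_rescued = NULL,
                              sef = NULL) {
  one <- function(name, called, true_set) {
    if (is.null(called)) return(NULL)
    called <- unique(as.character(called))
    tp <- length(intersect(called, true_set))
    sens <- if (length(true_set)) tp / length(true_set) else NA_real_
    prec <- if (length(called)) tp / length(called) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
      2 * prec * sens / (prec + sens)
    } else NA_real_
    tibble(set = name, n_true = length(true_set), n_called = length(called),
           sensitivity = sens, precision = prec, f1 = f1)
  }
  sets <- bind_rows(
    one("bound", bound, truth$bound),
    one("class_i", class_i, truth$class_i),
    one("class_ii", class_ii, truth$class_ii)
  )

  rescue_error <- NA_real_
  if (!is.null(fraction_rescued)) {
    planted <- length(truth$rescued) / max(length(truth$class_i), 1L)
    rescue_error <- abs(fraction_rescued - planted)
  }

  sef_auc <- NA_real_
  if (!is.null(sef)) {
    pos <- sef$sef[sef$gene_id %in% truth$class_i]
    neg <- sef$sef[!sef$gene_id %in% truth$class_i]
    if (length(pos) && length(neg)) {
      r <- rank(c(pos, neg))
      sef_auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
        (as.numeric(length(pos)) * length(neg))
    }
  }

  list(sets = sets, rescue_error = rescue_error, sef_auc = sef_auc)
}
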