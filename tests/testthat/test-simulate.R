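test_that("simulation config validates fractions and folds", {
  expect_error(simulation_config(fraction_class_i = 0.2, fraction_bound = 0.1),
               "infeasible")
  expect_error(simulation_config(class_i_fold = 1), "folds")
  expect_error(simulation_config(fraction_bound = 1.2), "fractions")
  cfg <- simulation_config(n_genes = 500, seed = 5)
  expect_s3_class(cfg, "simulation_config")
})

test_that("bundles are deterministic under the seed and honour planted structure", {
  cfg <- simulation_config(n_genes = 800, depth = 2e5, seed = 9)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1, b2)
  b3 <- simulate_bundle(simulation_config(n_genes = 800, depth = 2e5, seed = 10))
  expect_false(identical(as_gene_matrix(b1$gonad), as_gene_matrix(b3$gonad)))

  # classes are planted inside the bound set
  expect_true(all(b1$truth$class_i %in% b1$truth$bound))
  expect_true(all(b1$truth$class_ii %in% b1$truth$bound))
  expect_true(all(b1$truth$rescued %in% b1$truth$class_i))
  expect_length(intersect(b1$truth$class_i, b1$truth$class_ii), 0)

  # planted true SEF of class-I genes exceeds background by construction
  tm <- b1$truth$true_means
  true_sef <- (tm$whole_animal + 2) / (tm$gonad_wild_type + 2)
  ci <- tm$gene_id %in% b1$truth$class_i
  expect_gt(median(true_sef[ci]), median(true_sef))

  # all matrices share one gene universe
  expect_identical(gene_ids(b1$gonad), gene_ids(b1$rip))
  expect_identical(gene_ids(b1$gonad), gene_ids(b1$whole))
  expect_identical(gene_ids(b1$gonad), b1$annotation$gene_id)
})

test_that("realised sample means converge to planted means with depth", {
  err_at <- function(depth) {
    b <- simulate_bundle(simulation_config(n_genes = 400, depth = depth,
                                           dispersion = 0, seed = 11))
    m <- as_gene_matrix(b$gonad)[, "gonad_wild_type_1"]
    mu <- b$truth$true_means$gonad_wild_type
    keep <- mu > 5
    median(abs(m[keep] - mu[keep]) / mu[keep])
  }
  e1 <- err_at(2e5)
  e2 <- err_at(2e5 * 16)
  # Poisson relative error scales as 1/sqrt(depth): 16x depth -> ~4x smaller
  expect_lt(e2, e1 / 2)
})

test_that("null effect sizes yield only false-positive-level downstream calls", {
  cfg <- simulation_config(n_genes = 1500, depth = 1e6,
                           class_i_fold = 1.0001, class_ii_fold = 1.0001,
                           bound_fold = 1.0001, soma_fold = 1.0001, seed = 12)
  b <- simulate_bundle(cfg)
  rep <- run_pipeline(b)
  expect_lte(rep$counts[["n_bound"]], 5)
  expect_lte(rep$counts[["n_up"]] + rep$counts[["n_down"]], 1500 * 0.01)
})

test_that("generated stain images carry analytic truth the pipeline recovers", {
  sim0 <- simulate_oro_images(n_images = 2, stain_amplitude = 0, seed = 13)
  expect_true(all(sim0$truth$true_index == 0))
  m0 <- quantify_oro(sim0$images[[1]], 0.05)
  expect_equal(m0$lipid_index, 0)

  # single blob, amplitude 0.4 over ~10% of the worm -> index ~0.04
  sim1 <- simulate_oro_images(n_images = 1, stain_amplitude = 0.4,
                              stain_area_fraction = 0.10, n_blobs = 1, seed = 14)
  expect_equal(sim1$truth$true_index,
               0.4 * sim1$truth$stained_area / sim1$truth$worm_area)
  expect_equal(sim1$truth$true_index, 0.04, tolerance = 0.015)

  sim <- simulate_oro_images(n_images = 6, seed = 15)
  for (k in 1:6) {
    got <- quantify_oro(sim$images[[k]], 0.05)$lipid_index
    expect_equal(got, sim$truth$true_index[k], tolerance = 0.01)
  }

  expect_error(simulate_oro_images(stain_area_fraction = 1.2), "exceed")
})

test_that("recovery metrics behave at the identity and degenerate extremes", {
  truth <- list(bound = c("a", "b"), class_i = c("a"), class_ii = c("b"),
                rescued = "a")
  perfect <- evaluate_recovery(truth, bound = c("a", "b"), class_i = "a",
                               class_ii = "b", fraction_rescued = 1)
  expect_true(all(perfect$sets$sensitivity == 1))
  expect_true(all(perfect$sets$precision == 1))
  expect_equal(perfect$rescue_error, 0)

  empty <- evaluate_recovery(truth, bound = character())
  expect_equal(empty$sets$sensitivity, 0)
  expect_true(is.na(empty$sets$precision))
  expect_true(is.na(empty$sets$f1))

  s <- structure(tibble::tibble(gene_id = c("a", "b", "c"),
                                rpkm_whole = 1, rpkm_gonad = 1,
                                sef = c(9, 1, 2)),
                 class = c("sef_tbl", class(tibble::tibble())))
  auc <- evaluate_recovery(truth, sef = s)$sef_auc
  expect_equal(auc, 1)  # class-I gene "a" outranks both others
})
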