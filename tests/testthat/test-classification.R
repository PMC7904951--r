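test_that("expressed call uses a strict mean-RPKM threshold", {
  ab <- rpm_of(matrix(c(1.0, 0.6, 2.0,
                        1.0, 1.8, 2.0), 3, 2), ids = c("at1", "mix", "hi"),
               unit = "RPKM")
  expr <- call_expressed(ab)
  expect_false("at1" %in% expr)          # mean exactly 1 -> not expressed
  expect_true("mix" %in% expr)           # replicates 0.6, 1.8 -> mean 1.2
  expect_true("hi" %in% expr)
  expect_setequal(call_expressed(ab, threshold = 0), c("at1", "mix", "hi"))
  expect_error(call_expressed(ab, samples = character()), "empty")
  expect_error(call_expressed(ab, samples = "nope"), "not in matrix")
})

test_that("target classification partitions up/down by binding", {
  tc <- classify_targets(up = c("u1", "u2", "u3"), down = c("d1", "d2"),
                         bound = c("u2", "d1", "x9"))
  expect_identical(tc$class_i, "u2")
  expect_identical(tc$class_ii, "d1")
  expect_setequal(tc$up_unbound, c("u1", "u3"))
  expect_identical(tc$down_unbound, "d2")

  empty <- classify_targets(c("a", "b"), c("c"), bound = c("z"))
  expect_length(empty$class_i, 0)
  expect_length(empty$class_ii, 0)

  expect_error(classify_targets(c("a", "b"), c("b"), "x"), "overlap")

  # brute-force membership oracle + partition invariants on random sets
  set.seed(30)
  for (i in 1:100) {
    ids <- sprintf("g%03d", 1:100)
    up <- sample(ids, 30); down <- sample(setdiff(ids, up), 20)
    bound <- sample(ids, 40)
    tc <- classify_targets(up, down, bound)
    expect_identical(tc$class_i, sort(Filter(function(g) g %in% bound, up)))
    expect_identical(tc$class_ii, sort(Filter(function(g) g %in% bound, down)))
    expect_length(intersect(tc$class_i, tc$class_ii), 0)
    expect_setequal(c(tc$class_i, tc$up_unbound), up)
    expect_setequal(c(tc$class_ii, tc$down_unbound), down)
    expect_true(all(tc$class_i %in% bound) && all(tc$class_ii %in% bound))
  }
})

test_that("binding-enrichment chi-square matches the Pearson formula", {
  ids <- sprintf("g%03d", 1:40)
  # group binding fraction equals the rest's -> statistic 0, p 1
  grp <- ids[1:20]
  bound <- c(ids[1:10], ids[21:30])
  r0 <- binding_enrichment_test(grp, ids, bound)
  expect_equal(r0$chi_square, 0)
  expect_equal(r0$p_value, 1)

  # (10, 0, 0, 10): hand evaluation of sum (O-E)^2/E gives 20
  r1 <- binding_enrichment_test(ids[1:10], ids[1:20], ids[1:10])
  expect_equal(unname(unlist(r1[1, c("group_bound", "group_unbound",
                                     "rest_bound", "rest_unbound")])),
               c(10, 0, 0, 10))
  expect_equal(r1$chi_square, 20)

  expect_error(binding_enrichment_test(c("zz"), ids, bound), "not contained")

  # brute-force oracle on random tables
  set.seed(31)
  for (i in 1:100) {
    n <- sample(40:200, 1)
    u <- sprintf("u%04d", 1:n)
    g <- sample(u, sample(10:(n - 10), 1))
    b <- sample(u, sample(5:(n - 5), 1))
    res <- suppressWarnings(binding_enrichment_test(g, u, b))
    o <- matrix(c(res$group_bound, res$group_unbound,
                  res$rest_bound, res$rest_unbound), 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    expect_equal(res$chi_square, sum((o - e)^2 / e), tolerance = 1e-10)
    expect_equal(res$p_value, pchisq(res$chi_square, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(rowSums(o), c(length(g), length(u) - length(g)))
  }

  expect_warning(binding_enrichment_test("a", c("a", "b", "c"), "a"),
                 "expected cell")
})

test_that("somatic direct targets are the bound soma-up genes not gonad-up", {
  res <- derive_somatic_targets(
    soma_up = c("s1", "s2", "s3", "s4"),
    bound = c("s2", "s3", "x1"),
    gonad_up = c("s3", "y1")
  )
  expect_setequal(res$candidates, c("s2", "s3"))
  expect_identical(res$somatic_targets, "s2")

  all_gone <- derive_somatic_targets(c("a", "b"), c("a", "b"), c("a", "b", "c"))
  expect_length(all_gone$somatic_targets, 0)
})

test_that("rescue assessment applies the pseudo-counted within-fold rule", {
  ids <- sprintf("g%03d", 1:4)
  wt <- c(5, 10, 1, 20)
  mk_expr <- function(rescue_vals, mutant_vals = wt * 8) {
    tab <- tibble::tibble(gene_id = ids,
                          w1 = wt, w2 = wt,
                          m1 = mutant_vals, m2 = mutant_vals,
                          r1 = rescue_vals, r2 = rescue_vals)
    structure(tab, unit = "RPKM",
              samples = meta_tbl(c("w1", "w2", "m1", "m2", "r1", "r2"),
                                 genotype = rep(c("wild_type", "mutant", "rescue"), each = 2),
                                 replicate = rep(1:2, 3)),
              class = c("abundance_matrix", class(tibble::tibble())))
  }
  full <- assess_rescue(mk_expr(rescue_vals = wt), ids)
  expect_equal(full$fraction_rescued, 1)
  none <- assess_rescue(mk_expr(rescue_vals = wt * 8), ids)
  expect_equal(none$fraction_rescued, 0)
  # heat-map ordering: rows sorted by mutant/wild-type ratio descending
  ratios <- (none$genes$mutant + 2) / (none$genes$wild_type + 2)
  expect_true(all(diff(ratios) <= 0))

  expect_error(assess_rescue(mk_expr(wt), c(ids, "nope")), "absent")
})

test_that("planted rescue efficiency is recovered on the synthetic bundle", {
  cfg <- simulation_config(fraction_class_i = 0.04, seed = 33)  # 200 class-I genes
  b <- simulate_bundle(cfg)
  gonad_rpkm <- compute_rpkm(compute_rpm(b$gonad), b$annotation)
  ra <- assess_rescue(gonad_rpkm, b$truth$class_i)
  expect_equal(nrow(ra$genes), 200)
  expect_gte(ra$fraction_rescued, 0.75)
  expect_lte(ra$fraction_rescued, 0.85)
})
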