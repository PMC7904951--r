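test_that("size factors are median-of-ratios with geometric mean 1", {
  m <- matrix(rpois(200, 40), 100, 2)
  m[, 2] <- m[, 1]
  sf <- estimate_size_factors(make_counts(m))
  expect_equal(sf$size_factor, c(1, 1))

  m2 <- cbind(m[, 1], m[, 1] * 2L)
  sf2 <- estimate_size_factors(make_counts(m2))
  expect_equal(sf2$size_factor[2] / sf2$size_factor[1], 2)
  expect_equal(exp(mean(log(sf2$size_factor))), 1)

  # brute-force oracle on a random matrix
  set.seed(20)
  m3 <- matrix(rpois(400, 30) + 1L, 100, 4)
  sf3 <- estimate_size_factors(make_counts(m3))
  loggeo <- rowMeans(log(m3))
  oracle <- apply(m3, 2, function(col) median(exp(log(col) - loggeo)))
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(sf3$size_factor, unname(oracle))

  m4 <- matrix(c(0, 5, 3, 0), 2, 2)  # no gene positive everywhere
  expect_warning(estimate_size_factors(make_counts(m4)), "total-count")
})

test_that("dispersion estimation recovers simulated truth", {
  set.seed(21)
  n <- 2000
  mu <- rlnorm(n, log(100), 0.5)

  pois <- two_group_counts(matrix(rpois(n * 6, rep(mu, 6)), n, 6))
  dp <- estimate_dispersions(pois$cm, pois$groups)
  expect_lte(median(dp$final), 0.01)

  nb <- two_group_counts(matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 5), n, 6))
  dn <- estimate_dispersions(nb$cm, nb$groups)
  expect_gt(median(dn$raw), 0.1)
  expect_lt(median(dn$raw), 0.3)
  expect_true(all(dn$final > 0))

  # all-zero gene gets a finite trend-level dispersion
  m <- matrix(rpois(50 * 4, 20), 50, 4); m[1, ] <- 0L
  z <- two_group_counts(m)
  dz <- estimate_dispersions(z$cm, z$groups)
  expect_true(is.finite(dz$final[1]) && dz$final[1] > 0)

  single <- two_group_counts(matrix(rpois(20, 10), 10, 2))
  expect_error(estimate_dispersions(single$cm, single$groups), "fewer than 2")
})

test_that("Wald test is symmetric and label-swap equivariant", {
  set.seed(22)
  m1 <- matrix(rpois(100 * 2, 50), 100, 2)
  dup <- two_group_counts(cbind(m1, m1))  # mutant duplicates wild type
  de <- nb_wald_test(dup$cm, dup$groups, reference = "wild_type")
  expect_equal(de$log2fc, rep(0, 100))

  m <- matrix(rnbinom(100 * 4, mu = 60, size = 10), 100, 4)
  x <- two_group_counts(m)
  de_fwd <- nb_wald_test(x$cm, x$groups, reference = "wild_type")
  de_rev <- nb_wald_test(x$cm, x$groups, reference = "mutant")
  expect_equal(de_rev$log2fc, -de_fwd$log2fc, tolerance = 1e-6)
  expect_equal(de_rev$p_value, de_fwd$p_value, tolerance = 1e-6)

  # all-zero genes are excluded from testing and from the BH denominator
  m0 <- m; m0[1:10, ] <- 0L
  x0 <- two_group_counts(m0)
  de0 <- nb_wald_test(x0$cm, x0$groups)
  expect_true(all(is.na(de0$p_value[1:10])))
  expect_equal(de0$q_value[-(1:10)],
               p.adjust(de0$p_value[-(1:10)], method = "BH"))
})

test_that("BH adjustment agrees with a brute-force implementation", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(5:500, 1)
    p <- runif(n)^sample(1:3, 1)
    brute <- {
      o <- order(p)
      q <- rep(NA_real_, n)
      q[o] <- rev(cummin(rev(n * p[o] / seq_len(n))))
      pmin(q, 1)
    }
    expect_equal(p.adjust(p, method = "BH"), brute, tolerance = 1e-12)
  }
})

test_that("planted 8-fold genes are detected with high power at 2 vs 2", {
  set.seed(24)
  n <- 2000; planted <- 1:200
  muA <- rep(100, n); muB <- muA; muB[planted] <- 800
  m <- cbind(matrix(rnbinom(2 * n, mu = rep(muA, 2), size = 20), n, 2),
             matrix(rnbinom(2 * n, mu = rep(muB, 2), size = 20), n, 2))
  x <- two_group_counts(m)
  de <- nb_wald_test(x$cm, x$groups, reference = "wild_type")
  expect_gte(mean(de$direction[planted] == "up"), 0.95)
  expect_lte(sum(de$direction[-planted] != "ns", na.rm = TRUE), 20)
})

test_that("the fold-change/significance filter uses strict inequalities", {
  res <- structure(tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    base_mean = 10, fold_change = c(2.0, 2.01, 4, 0.4, 0.5),
    log2fc = log2(c(2.0, 2.01, 4, 0.4, 0.5)),
    p_value = c(0.001, 0.001, 0.2, 0.001, 0.001),
    q_value = c(0.01, 0.01, 0.2, 0.01, 0.01),
    direction = NA_character_
  ), class = c("de_result", class(tibble::tibble())))
  sets <- filter_de(res)
  expect_identical(sets$up, "b")          # 2.0 excluded (strict), q 0.2 excluded
  expect_identical(sets$down, "d")        # 0.5 = 1/2 excluded (strict)

  # oracle equivalence on random tables
  set.seed(25)
  for (i in 1:100) {
    n <- sample(10:300, 1)
    r <- structure(tibble::tibble(
      gene_id = sprintf("g%03d", 1:n), base_mean = 1,
      fold_change = exp(rnorm(n)), log2fc = 0,
      p_value = runif(n), q_value = runif(n), direction = NA_character_
    ), class = class(res))
    s <- filter_de(r, fc_min = 2, q_max = 0.05)
    expect_identical(s$up, sort(r$gene_id[r$fold_change > 2 & r$q_value < 0.05]))
    expect_identical(s$down, sort(r$gene_id[r$fold_change < 0.5 & r$q_value < 0.05]))
  }
})

test_that("external DE tables are ingested with BH fallback", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene_id = c("a", "b", "c"), fold_change = c(3, 0.2, 1),
    p_value = c(0.001, 0.02, 0.9)
  ), path)
  de <- read_de_table(path)
  expect_s3_class(de, "de_result")
  expect_equal(de$q_value, p.adjust(de$p_value, "BH"))
  sets <- filter_de(de)
  expect_identical(sets$up, "a")
  expect_identical(sets$down, "b")

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = "a", fold_change = 2), bad)
  expect_error(read_de_table(bad), "p_value")
})
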