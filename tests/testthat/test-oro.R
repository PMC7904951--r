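flat_image <- function(h = 20, w = 30, r = 0.5, g = 0.5, b = 0.5,
                       mask = matrix(TRUE, h, w)) {
  px <- array(0, c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  worm_image(px, mask)
}

test_that("stain excess is clipped red-minus-blue, zero outside the mask", {
  img <- flat_image(r = 0.5, b = 0.5)
  expect_true(all(stain_excess(img) == 0))

  mask <- matrix(FALSE, 20, 30); mask[5:15, 5:25] <- TRUE
  img2 <- flat_image(r = 0.7, b = 0.5, mask = mask)
  ex <- stain_excess(img2)
  expect_equal(ex[10, 10], 0.2, tolerance = 1e-12)
  expect_true(all(ex[!mask] == 0))

  # blue over red carries no signal
  img3 <- flat_image(r = 0.3, b = 0.6)
  expect_true(all(stain_excess(img3) == 0))

  # element-wise brute-force oracle on a random image
  set.seed(50)
  px <- array(runif(20 * 30 * 3), c(20, 30, 3))
  m <- matrix(runif(20 * 30) > 0.4, 20, 30)
  img4 <- worm_image(px, m)
  ex4 <- stain_excess(img4)
  for (idx in sample(20 * 30, 50)) {
    i <- (idx - 1) %% 20 + 1; j <- (idx - 1) %/% 20 + 1
    want <- if (m[i, j]) max(px[i, j, 1] - px[i, j, 3], 0) else 0
    expect_equal(ex4[i, j], want, tolerance = 1e-12)
  }
})

test_that("lipid index is stain excess over stained pixels per worm area", {
  # uniform excess e over a fraction f of the worm -> index e * f
  mask <- matrix(TRUE, 20, 20)
  px <- array(0.5, c(20, 20, 3))
  px[1:10, , 1] <- 0.8                    # excess 0.3 on half the worm
  img <- worm_image(px, mask)
  m <- quantify_oro(img, stain_threshold = 0.05)
  expect_equal(m$worm_area, 400)
  expect_equal(m$stained_area, 200)
  expect_equal(m$lipid_index, 0.3 * 0.5, tolerance = 1e-12)

  # nothing above threshold -> index 0
  m0 <- quantify_oro(img, stain_threshold = 0.5)
  expect_equal(m0$lipid_index, 0)
  expect_error(quantify_oro(img, stain_threshold = 1), "stain_threshold")

  # adding background pixels leaves the index unchanged
  big_mask <- matrix(FALSE, 40, 20); big_mask[1:20, ] <- TRUE
  big_px <- array(0.95, c(40, 20, 3)); big_px[1:20, , ] <- px
  m_bg <- quantify_oro(worm_image(big_px, big_mask), 0.05)
  expect_equal(m_bg$lipid_index, m$lipid_index)

  # linear in stain intensity (below saturation)
  px2 <- px; px2[1:10, , 1] <- 0.5 + 2 * 0.15
  m2 <- quantify_oro(worm_image(px2, mask), 0.05)
  expect_equal(m2$lipid_index, 2 * quantify_oro(worm_image({
    p <- px; p[1:10, , 1] <- 0.65; p
  }, mask), 0.05)$lipid_index, tolerance = 1e-12)

  # brute-force per-pixel oracle on random images
  set.seed(51)
  for (i in 1:20) {
    p <- array(runif(10 * 12 * 3), c(10, 12, 3))
    msk <- matrix(runif(120) > 0.3, 10, 12)
    if (!any(msk)) next
    got <- quantify_oro(worm_image(p, msk), 0.1)
    acc <- 0; st <- 0
    for (a in 1:10) for (b in 1:12) {
      if (!msk[a, b]) next
      e <- max(p[a, b, 1] - p[a, b, 3], 0)
      if (e > 0.1) { acc <- acc + e; st <- st + 1 }
    }
    expect_equal(got$total_excess, acc, tolerance = 1e-12)
    expect_equal(got$stained_area, st)
    expect_equal(got$lipid_index, acc / sum(msk), tolerance = 1e-12)
  }
})

test_that("worm segmentation finds a dark ellipse and respects explicit masks", {
  sim <- simulate_oro_images(n_images = 1, stain_amplitude = 0, seed = 7)
  img <- sim$images[[1]]
  seg <- segment_worm(img)
  true_area <- sum(img$mask)
  expect_lt(abs(sum(seg) - true_area) / true_area, 0.05)
  expect_gt(mean(seg[img$mask]), 0.95)

  explicit <- matrix(FALSE, 10, 10); explicit[3:6, 3:6] <- TRUE
  expect_identical(segment_worm(img, mask = explicit), explicit)

  blank <- flat_image(h = 30, w = 30, r = 0.9, g = 0.9, b = 0.9)
  expect_error(segment_worm(blank), "mask")
})

test_that("group-relative reporting normalises by the control mean", {
  worms <- tibble::tibble(
    worm_id = sprintf("w%d", 1:6),
    worm_area = 100, stained_area = 10,
    total_excess = c(1, 1, 1, 2, 2, 2),
    lipid_index = c(1, 1, 1, 2, 2, 2) / 100,
    group = rep(c("wild_type", "mutant"), each = 3)
  )
  rep <- relative_oro(worms, "wild_type")
  expect_equal(rep$groups$mean_relative[rep$groups$group == "wild_type"], 1)
  expect_equal(rep$groups$mean_relative[rep$groups$group == "mutant"], 2)
  expect_error(relative_oro(worms, "nope"), "control group")

  # seeded cohort with a planted 1.5-fold effect
  set.seed(52)
  idx_ctrl <- rlnorm(30, log(0.02), 0.1)
  idx_mut <- rlnorm(30, log(0.03), 0.1)
  cohort <- tibble::tibble(
    worm_id = sprintf("w%d", 1:60), worm_area = 1, stained_area = 1,
    total_excess = c(idx_ctrl, idx_mut),
    lipid_index = c(idx_ctrl, idx_mut),
    group = rep(c("ctrl", "mut"), each = 30)
  )
  r <- relative_oro(cohort, "ctrl")
  got <- r$groups$mean_relative[r$groups$group == "mut"]
  expect_gt(got, 1.4)
  expect_lt(got, 1.6)
})
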