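test_that("printed worked example reproduces exactly", {
  img <- worked_example_image()
  cm <- compute_glcm(img, matrix(TRUE, 4, 5),
                     glcm_spec(dx = 1, dy = 0, levels = 4,
                               quantize_range = c(0, 3)))
  want <- matrix(0L, 4, 4, dimnames = list(0:3, 0:3))
  want["0", "1"] <- 2L; want["1", "1"] <- 2L; want["1", "2"] <- 3L
  want["1", "3"] <- 1L; want["2", "0"] <- 2L; want["2", "2"] <- 1L
  want["2", "3"] <- 2L; want["3", "0"] <- 2L; want["3", "2"] <- 1L
  expect_identical(cm$counts, want)
  expect_identical(cm$n_pairs, 16L)
  expect_identical(cm$counts["0", "0"], 0L)

  # the published 1/20 denominator needs the stated M = N = 5
  pm <- normalize_glcm(cm, "paper_dims", dims = c(5, 5))
  expect_equal(pm$p["1", "2"], 3 / 20)
  expect_equal(pm$p["0", "0"], 0)

  # pair-count normalization sums to one; homogeneity hand-enumerated
  pc <- normalize_glcm(cm, "pair_count")
  expect_equal(sum(pc$p), 1)
  expect_equal(glcm_homogeneity(pc), 8.5 / 16)
  # the literal printed formula is the constant 1 on any normalized matrix
  expect_equal(glcm_homogeneity(pc, "paper_literal"), 1)
})

test_that("constant regions put all mass on the diagonal", {
  cm <- compute_glcm(matrix(5, 10, 10), disk_mask(10, 10, 5, 5, 4),
                     glcm_spec(levels = 8, quantize_range = c(0, 255)))
  expect_equal(sum(cm$counts) , cm$n_pairs)
  expect_equal(sum(diag(cm$counts)), cm$n_pairs)
  expect_equal(glcm_homogeneity(normalize_glcm(cm)), 1)
})

test_that("compute_glcm matches the brute-force oracle on random instances", {
  set.seed(11)
  for (i in 1:25) {
    H <- sample(6:30, 1); W <- sample(6:30, 1)
    vals <- matrix(sample(0:255, H * W, replace = TRUE), H, W)
    bits <- matrix(runif(H * W) > 0.3, H, W)
    if (!any(bits)) bits[1, 1] <- TRUE
    off <- sample(c(-2, -1, 0, 1, 2), 2, replace = TRUE)
    if (all(off == 0)) off <- c(1, 0)
    L <- sample(c(4, 8), 1)
    mode <- sample(c("both_in_region", "literal_product"), 1)
    spec <- glcm_spec(off[1], off[2], L, pair_mode = mode)
    got <- suppressWarnings(compute_glcm(vals, bits, spec))
    want <- bf_glcm(vals, bits, off[1], off[2], L, mode = mode)
    expect_identical(got$counts, want)
  }
})

test_that("negating the offset transposes the counts", {
  set.seed(4)
  vals <- matrix(sample(0:50, 400, replace = TRUE), 20, 20)
  bits <- disk_mask(20, 20, 10, 10, 8)
  a <- compute_glcm(vals, bits, glcm_spec(1, 1, 8))
  b <- compute_glcm(vals, bits, glcm_spec(-1, -1, 8))
  expect_identical(b$counts, t(a$counts))
})

test_that("zero-pair and degenerate-denominator paths behave", {
  thin <- matrix(FALSE, 6, 6); thin[, 3] <- TRUE  # 1-px column, dx = 1
  expect_warning(cm <- compute_glcm(matrix(1:36, 6, 6), thin, glcm_spec(1, 0, 4)),
                 "zero-pair")
  expect_equal(cm$n_pairs, 0L)
  expect_error(normalize_glcm(cm, "pair_count"), class = "abruptcut_data_error")
  expect_error(compute_glcm(matrix(1, 4, 4), matrix(FALSE, 4, 4), glcm_spec()),
               class = "abruptcut_data_error")
})

test_that("region mean/std match a direct accumulation", {
  expect_equal(region_mean_std(matrix(0.7, 5, 5), matrix(TRUE, 5, 5)),
               c(mean = 0.7, std = 0))
  two <- matrix(c(0, 1), 1, 2)
  expect_equal(region_mean_std(two, matrix(TRUE, 1, 2)),
               c(mean = 0.5, std = 0.5))
  set.seed(9)
  vals <- matrix(runif(900), 30, 30)
  bits <- matrix(runif(900) > 0.5, 30, 30)
  got <- region_mean_std(vals, bits)
  v <- vals[bits]
  expect_equal(got[["mean"]], sum(v) / length(v), tolerance = 1e-12)
  expect_equal(got[["std"]], sqrt(sum((v - mean(v))^2) / length(v)),
               tolerance = 1e-12)
  # channel_image inputs are rescaled by the declared range
  ch <- channel_image(matrix(c(0, 90, 180, 360), 2, 2), "Hue", c(0, 360))
  expect_equal(region_mean_std(ch, matrix(TRUE, 2, 2))[["mean"]], 0.4375)
  expect_error(region_mean_std(vals, matrix(FALSE, 30, 30)),
               class = "abruptcut_data_error")
})

test_that("standard homogeneity lies in (0, 1], 1 iff diagonal", {
  set.seed(14)
  for (i in 1:20) {
    vals <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
    cm <- compute_glcm(vals, matrix(TRUE, 12, 12), glcm_spec(1, 0, 8))
    h <- glcm_homogeneity(normalize_glcm(cm))
    expect_gt(h, 0); expect_lte(h, 1)
    off_diag <- sum(cm$counts) - sum(diag(cm$counts))
    expect_equal(h == 1, off_diag == 0L)
  }
})
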