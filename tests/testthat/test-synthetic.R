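test_that("near-zero tau gives a 1-px step across the border", {
  s <- generate_lesion(synthetic_lesion_spec(
    image_size = c(80, 80), base_radius = 20, sector_tau = 0.1,
    noise_sigma = 0, pattern_contrast = 0))
  blue <- s$image$pixels[, , 3]
  row <- blue[40, ]                       # horizontal profile through center
  # lesion blue is 50, skin blue is 140; a 1-px step leaves at most one
  # intermediate pixel per border crossing (two crossings on the profile)
  expect_lte(sum(row > 60 & row < 130), 2)
  expect_true(any(row < 55) && any(row > 135))
})

test_that("mask of an unmodulated disk has the right area", {
  s <- generate_lesion(synthetic_lesion_spec(
    image_size = c(160, 160), base_radius = 60, sector_tau = 6))
  expect_lt(abs(sum(s$mask) - pi * 60^2) / (pi * 60^2), 0.03)
})

test_that("generation is deterministic and labels are a pure spec function", {
  spec <- synthetic_lesion_spec(image_size = c(64, 64), base_radius = 20,
                                sector_tau = c(1, rep(8, 7)), seed = 33)
  a <- generate_lesion(spec); b <- generate_lesion(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(unclass(a$mask), unclass(b$mask))
  expect_identical(a$label, "malignant")
  expect_identical(lesion_label(spec), "malignant")
  spec2 <- synthetic_lesion_spec(sector_tau = rep(2.01, 8))
  expect_identical(lesion_label(spec2), "benign")   # strictly above threshold
  expect_identical(lesion_label(synthetic_lesion_spec(sector_tau = rep(2, 8))),
                   "malignant")                     # at the threshold
})

test_that("mask equals the 50% threshold of the noiseless sigmoid image", {
  s <- generate_lesion(synthetic_lesion_spec(
    image_size = c(100, 100), base_radius = 30, sector_tau = 4,
    noise_sigma = 0, pattern_contrast = 0,
    harmonics = cbind(k = 3, amplitude = 0.08, phase = 0.7)))
  blue <- s$image$pixels[, , 3]
  mid <- (140 + 50) / 2
  thr <- blue < mid
  disagree <- which(thr != unclass(s$mask), arr.ind = TRUE)
  # every disagreeing pixel sits on the border (has an opposite neighbor)
  for (i in seq_len(nrow(disagree))) {
    r <- disagree[i, 1]; c <- disagree[i, 2]
    nb <- unclass(s$mask)[max(1, r - 1):min(100, r + 1),
                          max(1, c - 1):min(100, c + 1)]
    expect_true(any(nb != unclass(s$mask)[r, c]))
  }
})

test_that("datasets honour class counts, ordering seed, and reproducibility", {
  ds <- generate_dataset(8, 5, seed = 1, image_size = c(48L, 48L))
  expect_length(ds, 13)
  labs <- vapply(ds, `[[`, character(1), "label")
  expect_equal(sum(labs == "malignant"), 5)
  expect_equal(sum(labs == "benign"), 8)
  ds2 <- generate_dataset(8, 5, seed = 1, image_size = c(48L, 48L))
  expect_identical(labs, vapply(ds2, `[[`, character(1), "label"))
  expect_identical(ds[[3]]$image$pixels, ds2[[3]]$image$pixels)

  one <- generate_dataset(1, 0, seed = 9, image_size = c(48L, 48L))
  expect_length(one, 1)
  expect_identical(one[[1]]$label, "benign")
})

test_that("malignant samples have 1-3 abrupt sectors; benign none", {
  ds <- generate_dataset(6, 6, seed = 4, image_size = c(48L, 48L))
  for (s in ds) {
    nab <- sum(s$spec$sector_tau <= s$spec$tau_abrupt)
    if (s$label == "malignant") expect_true(nab >= 1 && nab <= 3)
    else expect_equal(nab, 0)
  }
})

test_that("dataset files round-trip through the PNM writers", {
  d <- withr::local_tempdir()
  ds <- generate_dataset(2, 1, seed = 2, image_size = c(40L, 40L))
  write_dataset(ds, d)
  expect_true(file.exists(file.path(d, "labels.csv")))
  labs <- read.csv(file.path(d, "labels.csv"))
  expect_equal(nrow(labs), 3)
  img <- load_image(file.path(d, "sample001.ppm"))
  expect_identical(img$pixels, ds[[1]]$image$pixels)
  msk <- read_pnm(file.path(d, "sample001_mask.pbm"))
  expect_identical(msk, unclass(ds[[1]]$mask))
})

test_that("invariant-violating specs are rejected", {
  expect_error(synthetic_lesion_spec(image_size = c(64, 64), base_radius = 40),
               class = "abruptcut_param_error")
  expect_error(synthetic_lesion_spec(sector_tau = c(3, 0)),
               class = "abruptcut_param_error")
})
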