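test_that("center spacing is round(1.5 r) half-up along the path", {
  path <- matrix(0, 40, 2)
  expect_equal(place_centers(path, 2), seq(1L, 40L, by = 3L))  # r=2 -> 3 apart
  expect_equal(place_centers(path, 5), c(1L, 9L, 17L, 25L, 33L))
  short <- matrix(0, 7, 2)
  expect_warning(got <- place_centers(short, 5), "single center")
  expect_equal(got, 1L)
})

test_that("method-1 regions are full disks clipped to the frame", {
  bits <- disk_mask(120, 120, 60, 60, 50)
  path <- trace_boundary(lesion_mask(bits))
  regs <- method1_regions(bits, path, 5)
  expect_length(regs, length(place_centers(path, 5)))
  for (reg in regs) {
    expect_identical(reg$provenance, "method1_circle")
    expect_lte(abs(region_size(reg) - pi * 25), 4 * 5 + 4)
  }
  # near-edge circle: clipped but nonempty
  clipped <- abruptcut:::rasterize_disk(2, 2, 5, c(120, 120), "method1_circle")
  expect_gt(region_size(clipped), 0)
  expect_lt(region_size(clipped), pi * 25)
})

test_that("method-2 contraction of a disk gives the inner circle", {
  bits <- disk_mask(140, 140, 70, 70, 50)
  m <- lesion_mask(bits)
  path <- trace_boundary(m)
  ctr <- mask_centroid(m)
  for (r in c(5, 10)) {
    inner <- method2_inner_boundary(path, ctr, r)
    dist <- sqrt((inner[, "col"] - ctr[["x"]])^2 +
                 (inner[, "row"] - ctr[["y"]])^2)
    expect_lt(max(abs(dist - (50 - r))), 1)
    expect_identical(attr(inner, "method"), "vector_shift")
  }
  # degenerate: boundary point within r of the centroid
  small <- disk_mask(20, 20, 10, 10, 4)
  sp <- trace_boundary(lesion_mask(small))
  expect_error(method2_inner_boundary(sp, mask_centroid(small), 5),
               class = "abruptcut_degenerate_contraction")
})

test_that("method-2 failure mode on a crescent is detectable by point spacing", {
  cb <- crescent_mask()
  m <- lesion_mask(cb)
  path <- trace_boundary(m)
  ctr <- mask_centroid(m)
  inner_cre <- method2_inner_boundary(path, ctr, 10)
  ref <- disk_mask(90, 90, 45, 45, 30)
  pr <- trace_boundary(lesion_mask(ref))
  inner_ref <- method2_inner_boundary(pr, mask_centroid(ref), 10)
  # contraction crowds points together far more on the concave shape
  expect_lt(attr(inner_cre, "min_spacing") + 1e-9,
            attr(inner_ref, "min_spacing"))
  expect_lt(attr(inner_cre, "min_spacing"), 0.5)
})

test_that("method-3 scale factor follows s = 1 - r / rho", {
  ctr <- c(x = 0, y = 0)
  expect_equal(method3_scale_factor(c(0, 10), ctr, 5), 0.5)   # rho = 2r
  expect_equal(method3_scale_factor(c(0, 100), ctr, 5), 0.95)
  expect_error(method3_scale_factor(c(0, 5), ctr, 5),
               class = "abruptcut_degenerate_contraction")
})

test_that("method-3 dynamic scaling: similarity about the centroid", {
  bits <- disk_mask(160, 160, 80, 80, 60)
  m <- lesion_mask(bits)
  path <- trace_boundary(m)
  ctr <- mask_centroid(m)
  for (r in c(5, 15)) {
    inner <- method3_inner_boundary(path, ctr, r)
    dist <- sqrt((inner[, "col"] - ctr[["x"]])^2 +
                 (inner[, "row"] - ctr[["y"]])^2)
    expect_lt(max(abs(dist - (60 - r))), 1)
    # centroid preserved by the translation of Eq-style alignment
    expect_lt(abs(mean(inner[, "col"]) - mean(path[, "col"])), 0.5)
    expect_lt(abs(mean(inner[, "row"]) - mean(path[, "row"])), 0.5)
  }

  # irregular star: output similar to input with ratio s (pairwise distances)
  star <- quick_sample(seed = 6, size = 120, R0 = 38,
                       harmonics = cbind(k = c(3, 5), amplitude = c(0.1, 0.05),
                                         phase = c(0.4, 1.1)))
  sm <- standardize_mask(star$mask)
  sp <- trace_boundary(sm)
  sc <- mask_centroid(sm)
  inner <- method3_inner_boundary(sp, sc, 10)
  s <- attr(inner, "s")
  idx <- round(seq(1, nrow(sp), length.out = 12))
  for (a in idx[1:6]) for (b in idx[7:12]) {
    d0 <- sqrt(sum((sp[a, ] - sp[b, ])^2))
    d1 <- sqrt(sum((inner[a, ] - inner[b, ])^2))
    expect_equal(d1 / d0, s, tolerance = 1e-9)
  }
})

test_that("lesion intersection clips circles and skips empty overlaps", {
  bits <- disk_mask(120, 120, 60, 60, 50)
  m <- lesion_mask(bits)
  # fully inside: complete disk
  full <- intersect_with_lesion(c(60, 60), 5, m)
  expect_lte(abs(region_size(full) - pi * 25), 4 * 5 + 4)
  expect_true(all(region_full(full)[!bits] == FALSE))
  # straddling the border of a big disk: between half and full
  onb <- intersect_with_lesion(c(60 + 48, 60), 5, m)
  frac <- region_size(onb) / region_size(full)
  expect_gt(frac, 0.5); expect_lt(frac, 1)
  # fully outside: skipped with a warning
  expect_warning(out <- intersect_with_lesion(c(5, 5), 3, m), "skipped")
  expect_null(out)
})

test_that("method-2/3 regions stay inside the lesion; method 1 may not", {
  s <- quick_sample(seed = 12, size = 120, R0 = 38)
  m <- standardize_mask(s$mask)
  bits <- unclass(m)
  path <- trace_boundary(m)
  ctr <- mask_centroid(m)
  for (meth in 2:3) {
    regs <- suppressWarnings(method_regions(m, path, ctr, meth, 7))
    expect_equal(length(regs) + attr(regs, "n_skipped"),
                 length(place_centers(path, 7)))
    for (reg in regs)
      expect_true(all(bits[region_full(reg)]))
  }
  regs1 <- method_regions(m, path, ctr, 1, 7)
  outside <- vapply(regs1, function(reg) any(!bits[region_full(reg)]),
                    logical(1))
  expect_true(any(outside))
})
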