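## glcm: gray-level co-occurrence matrices, homogeneity, region mean/std.

#' GLCM specification
#'
#' @param dx,dy pixel offset of the co-occurring pair: the partner of pixel
#'   `(row, col)` is `(row + dy, col + dx)`, so the default `dx = 1, dy = 0`
#'   pairs each pixel with its right-hand neighbor.
#' @param levels number of gray levels L (>= 2, default 8).
#' @param quantize_range `[lo, hi]` mapped linearly onto levels 0..L-1.
#'   `NULL` (default) scales by the min/max of the supplied channel image —
#'   the self-scaling default of the classical graycomatrix routine, applied
#'   at image level so every region of one image shares a common gray scale.
#'   `"channel"` uses the channel's declared `value_range`.
#' @param pair_mode `"both_in_region"` counts only pairs with both pixels
#'   inside the region (background treated as excluded noise, the default);
#'   `"literal_product"` multiplies the image by the 0/1 mask over the region
#'   bounding box first, so background zeros enter the counts (the published
#'   element-by-element multiplication behavior).
#' @return object of class `glcm_spec`.
#' @export
glcm_spec <- function(dx = 1L, dy = 0L, levels = 8L, quantize_range = NULL,
                      pair_mode = c("both_in_region", "literal_product")) {
  if (dx == 0L && dy == 0L)
    abort2("offset (dx, dy) must be nonzero", "abruptcut_param_error")
  if (levels < 2L) abort2("levels must be >= 2", "abruptcut_param_error")
  structure(list(dx = as.integer(dx), dy = as.integer(dy),
                 levels = as.integer(levels), quantize_range = quantize_range,
                 pair_mode = match.arg(pair_mode)),
            class = "glcm_spec")
}

# quantize numeric values to integer levels 0..L-1 over [lo, hi];
# range = NULL scales to the data's own min/max (constant data -> level 0)
quantize_levels <- function(values, levels, range = NULL) {
  if (is.null(range)) range <- base::range(values)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) {
    q <- values * 0
  } else {
    q <- floor((values - lo) / (hi - lo) * levels)
    q[q < 0] <- 0
    q[q > levels - 1] <- levels - 1
  }
  storage.mode(q) <- "integer"
  q
}

# coerce channel input: returns list(values, range)
chan_input <- function(chan) {
  if (inherits(chan, "channel_image"))
    list(values = chan$values, range = chan$value_range)
  else list(values = as.matrix(chan), range = c(0, 255))
}

# coerce region input to a plain logical matrix over the full image
region_bits <- function(region, dims) {
  if (inherits(region, "region_mask")) return(region_full(region, dims))
  b <- as.matrix(region)
  storage.mode(b) <- "logical"
  b
}

#' Compute a gray-level co-occurrence matrix over a masked region
#'
#' Counts ordered pixel pairs `(p, q)` and `(p + dy, q + dx)` whose quantized
#' intensities are `(i, j)`. See [glcm_spec()] for the two pairing modes.
#'
#' @param chan a [channel_image()] or plain numeric matrix.
#' @param region logical matrix (TRUE = in region) or a `region_mask`.
#' @param spec a [glcm_spec()].
#' @return object of class `cooc_matrix`: list with `counts` (L x L integer
#'   matrix, dimnames are levels 0..L-1), `spec`, `n_pairs`, and
#'   `region_dims` (`M` = bounding-box columns, `N` = rows).
#' @export
compute_glcm <- function(chan, region, spec = glcm_spec()) {
  ci <- chan_input(chan)
  bits <- region_bits(region, dim(ci$values))
  if (!any(bits)) abort2("empty region", "abruptcut_data_error")
  if (!all(dim(bits) == dim(ci$values)))
    abort2("region and channel dimensions differ", "abruptcut_data_error")
  L <- spec$levels

  # restrict to the region bounding box
  rr <- range(which(rowSums(bits) > 0))
  cc <- range(which(colSums(bits) > 0))
  sub <- ci$values[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  bsub <- bits[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]

  if (spec$pair_mode == "literal_product") {
    sub <- sub * bsub  # published behavior: zeros injected by the mask
    bsub <- matrix(TRUE, nrow(sub), ncol(sub))
  }
  rng <- spec$quantize_range
  if (identical(rng, "channel")) rng <- ci$range
  if (is.null(rng)) rng <- range(ci$values)  # graycomatrix-style self-scaling
  q <- quantize_levels(sub, L, rng)

  nr <- nrow(q); nc <- ncol(q)
  dr <- spec$dy; dc <- spec$dx
  rs <- seq_len(nr); cs <- seq_len(nc)
  okr <- rs[rs + dr >= 1 & rs + dr <= nr]
  okc <- cs[cs + dc >= 1 & cs + dc <= nc]
  counts <- matrix(0L, L, L, dimnames = list(0:(L - 1), 0:(L - 1)))
  if (length(okr) && length(okc)) {
    a <- q[okr, okc, drop = FALSE]
    b <- q[okr + dr, okc + dc, drop = FALSE]
    keep <- bsub[okr, okc, drop = FALSE] & bsub[okr + dr, okc + dc, drop = FALSE]
    if (any(keep)) {
      code <- a[keep] * L + b[keep]
      tab <- tabulate(code + 1L, nbins = L * L)
      counts <- matrix(as.integer(tab), L, L, byrow = TRUE,
                       dimnames = list(0:(L - 1), 0:(L - 1)))
    }
  }
  n_pairs <- sum(counts)
  if (n_pairs == 0L)
    warning("region thinner than the GLCM offset: zero-pair matrix",
            call. = FALSE)
  structure(list(counts = counts, spec = spec, n_pairs = n_pairs,
                 region_dims = c(M = ncol(bsub), N = nrow(bsub))),
            class = "cooc_matrix")
}

#' Normalize a co-occurrence matrix to a probability matrix
#'
#' `denom_mode = "pair_count"` (default) divides by the number of valid pairs
#' so entries sum to 1. `"paper_dims"` reproduces the published
#' `(M - dx)(N - dy)` denominator computed from the region bounding box (or
#' from `dims` if supplied), which does not in general sum to 1.
#'
#' @param cm a [compute_glcm()] result.
#' @param denom_mode `"pair_count"` or `"paper_dims"`.
#' @param dims optional `c(M, N)` override for `"paper_dims"`.
#' @return object of class `prob_matrix`: list with `p` (numeric L x L) and
#'   `levels`.
#' @export
normalize_glcm <- function(cm, denom_mode = c("pair_count", "paper_dims"),
                           dims = NULL) {
  denom_mode <- match.arg(denom_mode)
  if (denom_mode == "pair_count") {
    if (cm$n_pairs == 0L)
      abort2("zero pairs: cannot normalize by pair count",
             "abruptcut_data_error")
    denom <- cm$n_pairs
  } else {
    d <- dims %||% cm$region_dims
    denom <- (d[[1]] - cm$spec$dx) * (d[[2]] - cm$spec$dy)
    if (denom <= 0)
      abort2("degenerate (M - dx)(N - dy) denominator", "abruptcut_data_error")
  }
  structure(list(p = cm$counts / denom, levels = cm$spec$levels),
            class = "prob_matrix")
}

#' GLCM homogeneity
#'
#' `mode = "standard"` computes `sum p(i, j) / (1 + |i - j|)`, the usual
#' inverse-difference weighting: 1 exactly when all co-occurring pairs share a
#' gray level, smaller the more mass sits far from the diagonal. The
#' published formula omits the `|i - j|` term (an apparent typographical
#' omission, under which any properly normalized matrix scores a constant 1);
#' it is kept verbatim behind `mode = "paper_literal"`.
#'
#' @param pm a [normalize_glcm()] result.
#' @param mode `"standard"` or `"paper_literal"`.
#' @return unitless scalar.
#' @export
glcm_homogeneity <- function(pm, mode = c("standard", "paper_literal")) {
  mode <- match.arg(mode)
  if (mode == "paper_literal") return(sum(pm$p))
  L <- pm$levels
  w <- 1 / (1 + abs(outer(0:(L - 1), 0:(L - 1), "-")))
  sum(pm$p * w)
}

#' Region mean and standard deviation
#'
#' Computed over region pixels only, on intensities rescaled to `[0, 1]` by
#' the channel's declared range (unit scaling is what makes the published
#' feature-table magnitudes comparable across channels). The standard
#' deviation is the population form (divisor `n`).
#'
#' @param chan a [channel_image()] or a plain matrix already in `[0, 1]`.
#' @param region logical matrix or `region_mask`.
#' @return named numeric `c(mean, std)`.
#' @export
region_mean_std <- function(chan, region) {
  if (inherits(chan, "channel_image")) {
    vals <- channel_unit(chan)
  } else {
    vals <- as.matrix(chan)
  }
  bits <- region_bits(region, dim(vals))
  v <- vals[bits]
  if (length(v) == 0L) abort2("empty region", "abruptcut_data_error")
  mu <- mean(v)
  c(mean = mu, std = sqrt(mean((v - mu)^2)))
}

# Fast path used by the feature extractor: standard homogeneity with
# pair-count normalization, straight from pre-quantized values at the pair
# index vectors of a region. Equivalent to
# glcm_homogeneity(normalize_glcm(compute_glcm(...))) for dx=1, dy=0 regions;
# the equivalence is asserted in the test suite.
fast_homogeneity <- function(qvals_a, qvals_b) {
  if (length(qvals_a) == 0L) return(NA_real_)
  mean(1 / (1 + abs(qvals_a - qvals_b)))
}
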