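# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no binary fixtures.

# logical H x W disk mask
disk_mask <- function(H, W, cy, cx, R) {
  outer(seq_len(H), seq_len(W), function(r, c) (r - cy)^2 + (c - cx)^2 <= R^2)
}

# crescent: disk minus an overlapping shifted disk (strongly concave)
crescent_mask <- function(H = 90, W = 90, R = 30) {
  big <- disk_mask(H, W, H / 2, W / 2, R)
  bite <- disk_mask(H, W, H / 2, W / 2 + R * 0.8, R * 0.6)
  big & !bite
}

# independent brute-force GLCM oracle: literal double loop over pixels,
# deliberately naive so it shares no code path with compute_glcm
bf_glcm <- function(values, bits, dx, dy, L, rng = NULL,
                    mode = c("both_in_region", "literal_product")) {
  mode <- match.arg(mode)
  rr <- range(which(apply(bits, 1, any)))
  cc <- range(which(apply(bits, 2, any)))
  v <- values[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  b <- bits[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  if (mode == "literal_product") {
    v <- v * b
    b <- matrix(TRUE, nrow(v), ncol(v))
  }
  if (is.null(rng)) rng <- range(values)
  qq <- function(x) {
    if (rng[2] <= rng[1]) return(0L)
    min(max(floor((x - rng[1]) / (rng[2] - rng[1]) * L), 0), L - 1)
  }
  counts <- matrix(0L, L, L, dimnames = list(0:(L - 1), 0:(L - 1)))
  for (r in seq_len(nrow(v))) {
    for (c in seq_len(ncol(v))) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 < 1 || r2 > nrow(v) || c2 < 1 || c2 > ncol(v)) next
      if (!b[r, c] || !b[r2, c2]) next
      i <- qq(v[r, c]); j <- qq(v[r2, c2])
      counts[i + 1, j + 1] <- counts[i + 1, j + 1] + 1L
    }
  }
  counts
}

# the worked intensity array printed with the co-occurrence example
# (4 printed rows x 5 columns, values 0..3)
worked_example_image <- function() {
  matrix(c(0, 1, 1, 3, 0,
           0, 1, 2, 3, 0,
           1, 2, 3, 2, 0,
           1, 1, 2, 2, 0), nrow = 4, ncol = 5, byrow = TRUE)
}

# quick flat-color rgb image
flat_rgb <- function(H, W, col) {
  rgb_image(array(rep(as.integer(col), each = H * W), dim = c(H, W, 3)))
}

# small labeled sample with a disk lesion for feature tests
quick_sample <- function(seed = 3, tau = rep(9, 8), size = 128, R0 = 40,
                         ...) {
  generate_lesion(synthetic_lesion_spec(
    image_size = c(size, size), base_radius = R0, sector_tau = tau,
    seed = seed, ...))
}

# tiny separable feature table: f1 carries the labels, the rest is noise
toy_table <- function(n = 20, p = 8, seed = 5, signal = 2) {
  set.seed(seed)
  y <- rep(c("malignant", "benign"), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- ifelse(y == "malignant", signal, -signal) + rnorm(n, sd = 0.1)
  colnames(x) <- paste0("f", seq_len(p))
  df <- data.frame(image_id = sprintf("im%02d", seq_len(n)), label = y, x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "normalized") <- FALSE
  df
}
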