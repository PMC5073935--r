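## channels: RGB image container and the ten-channel decomposition.

CHANNEL_LABELS <- c("Gra", "Red", "Gre", "Blu", "Y", "Cb", "Cr",
                    "Hue", "Sat", "V")

#' RGB image container
#'
#' @param pixels integer array of dimension `c(H, W, 3)` with values in
#'   0..255 (R, G, B planes).
#' @return an object of class `rgb_image` with elements `pixels`, `height`,
#'   `width`.
#' @export
rgb_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    abort2("pixels must be an H x W x 3 array", "abruptcut_input_error")
  if (min(pixels) < 0 || max(pixels) > 255)
    abort2("RGB components must lie in [0, 255]", "abruptcut_input_error")
  structure(list(pixels = pixels,
                 height = dim(pixels)[1], width = dim(pixels)[2]),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d>\n", x$height, x$width))
  invisible(x)
}

#' Load an RGB dermoscopy image from disk
#'
#' Reads a plain-text PNM file (P3 pixmap; P2 graymaps and P1 bitmaps are
#' promoted to RGB with a warning, mirroring the "converted, warning logged"
#' contract for non-RGB inputs).
#'
#' @param path path to a P1/P2/P3 PNM file.
#' @return an [rgb_image()].
#' @export
load_image <- function(path) {
  x <- read_pnm(path)
  if (inherits(x, "rgb_image")) return(x)
  warning("non-RGB image promoted to RGB by channel replication",
          call. = FALSE)
  if (is.logical(x)) x <- matrix(as.integer(x) * 255L, nrow(x), ncol(x))
  maxval <- attr(x, "maxval") %||% 255L
  if (maxval != 255L) x <- as.integer(round(x * (255 / maxval)))
  rgb_image(array(rep(as.integer(x), 3L), dim = c(nrow(x), ncol(x), 3L)))
}

#' A single scalar channel image
#'
#' @param values numeric matrix of channel values.
#' @param channel_label one of `Gra, Red, Gre, Blu, Y, Cb, Cr, Hue, Sat, V`.
#' @param value_range declared `[lo, hi]` range of the channel; used later for
#'   gray-level quantization and for rescaling intensities to `[0, 1]`.
#' @return object of class `channel_image`.
#' @export
channel_image <- function(values, channel_label, value_range) {
  stopifnot(is.matrix(values), length(value_range) == 2L)
  structure(list(values = values, channel_label = channel_label,
                 value_range = as.numeric(value_range)),
            class = "channel_image")
}

#' Decompose an RGB image into the ten analysis channels
#'
#' Produces Gra (luma), Red, Gre, Blu (pass-through), Y/Cb/Cr (full-range
#' ITU-R BT.601: `Y = 0.299 R + 0.587 G + 0.114 B`, Cb/Cr offset by 128) and
#' hexcone HSV with Hue in degrees `[0, 360)`, Sat in `[0, 1]`,
#' V = max(R,G,B) in `[0, 255]`. Gra and Y use the same luma weights. Hue of
#' achromatic pixels (Sat = 0) is defined as 0 so no NaN can reach the
#' texture statistics. Channels keep native precision; quantization happens
#' only in the GLCM module.
#'
#' @param img an [rgb_image()].
#' @return a `channel_stack`: named list of [channel_image()]s, one per label.
#' @export
extract_channels <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  H <- img$height; W <- img$width
  r <- matrix(img$pixels[, , 1] * 1.0, H, W)
  g <- matrix(img$pixels[, , 2] * 1.0, H, W)
  b <- matrix(img$pixels[, , 3] * 1.0, H, W)

  y  <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  cr <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b

  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- v - mn
  sat <- ifelse(v > 0, delta / v, 0)
  hue <- matrix(0, nrow(r), ncol(r))
  nz <- delta > 0
  hr <- nz & v == r
  hg <- nz & v == g & !hr
  hb <- nz & !hr & !hg
  hue[hr] <- 60 * (((g[hr] - b[hr]) / delta[hr]) %% 6)
  hue[hg] <- 60 * ((b[hg] - r[hg]) / delta[hg] + 2)
  hue[hb] <- 60 * ((r[hb] - g[hb]) / delta[hb] + 4)
  hue <- hue %% 360

  stack <- list(
    Gra = channel_image(y,   "Gra", c(0, 255)),
    Red = channel_image(r,   "Red", c(0, 255)),
    Gre = channel_image(g,   "Gre", c(0, 255)),
    Blu = channel_image(b,   "Blu", c(0, 255)),
    Y   = channel_image(y,   "Y",   c(0, 255)),
    Cb  = channel_image(cb,  "Cb",  c(0, 255)),
    Cr  = channel_image(cr,  "Cr",  c(0, 255)),
    Hue = channel_image(hue, "Hue", c(0, 360)),
    Sat = channel_image(sat, "Sat", c(0, 1)),
    V   = channel_image(v,   "V",   c(0, 255))
  )
  structure(stack, class = "channel_stack")
}

#' Rescale a channel to the unit interval using its declared range
#' @param chan a [channel_image()].
#' @return numeric matrix in `[0, 1]`.
#' @keywords internal
channel_unit <- function(chan) {
  rng <- chan$value_range
  (chan$values - rng[1]) / (rng[2] - rng[1])
}
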