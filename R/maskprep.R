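## maskprep: standardization of the binary lesion mask.
##
## Fixed stage order: complement -> clip -> open -> central cluster.
## Every stage except complement is anti-extensive (never adds foreground).

#' Construct a lesion mask
#' @param bits logical matrix, TRUE = lesion foreground.
#' @return object of class `lesion_mask` (a logical matrix).
#' @export
lesion_mask <- function(bits) {
  stopifnot(is.matrix(bits))
  storage.mode(bits) <- "logical"
  structure(bits, class = c("lesion_mask", "matrix", "array"))
}

as_mask <- function(m) if (inherits(m, "lesion_mask")) m else lesion_mask(m)

#' Complement a binary mask
#'
#' Segmenter output marks the lesion as background (a negative of the
#' standardized mask), so the very first standardization step flips every bit.
#'
#' @param m logical mask matrix.
#' @return complemented `lesion_mask`.
#' @export
complement_mask <- function(m) {
  m <- as_mask(m)
  lesion_mask(!unclass(m))
}

#' Central clipping rectangle
#'
#' Symmetric margins of `round(dim * p / 200)` pixels per side (total `p`
#' percent of each dimension split across its two sides), rounded half-up.
#' The published per-side formulas are dimensionally inconsistent (they give
#' `1 + 50 w / p`, larger than the image for p < 100); that literal form is
#' kept behind `literal = TRUE` for comparison only.
#'
#' @param w,h image width and height in pixels (both >= 4).
#' @param p percentage of each dimension to clip, in (0, 100).
#' @param literal use the literal published per-side formula.
#' @return a `clip_rect` list with 1-based `left`, `right`, `top`, `bottom`.
#' @export
compute_clip_rect <- function(w, h, p = 10, literal = FALSE) {
  if (w < 4 || h < 4) abort2("image too small to clip", "abruptcut_param_error")
  if (!(p > 0 && p < 100))
    abort2("clip percentage must lie in (0, 100)", "abruptcut_param_error")
  if (literal) {
    mw <- w / (2 * p / 100)
    mh <- h / (2 * p / 100)
  } else {
    mw <- round_half_up(w * p / 200)
    mh <- round_half_up(h * p / 200)
  }
  rect <- list(left = 1 + mw, right = w - mw, top = 1 + mh, bottom = h - mh)
  if (!literal && (rect$left >= rect$right || rect$top >= rect$bottom))
    abort2("clip rectangle collapsed; reduce p", "abruptcut_param_error")
  structure(rect, class = "clip_rect")
}

#' Clear foreground outside a clipping rectangle
#' @param m lesion mask.
#' @param rect a [compute_clip_rect()] result.
#' @return clipped `lesion_mask`.
#' @export
clip_outside <- function(m, rect) {
  m <- as_mask(m)
  out <- unclass(m)
  h <- nrow(out); w <- ncol(out)
  rows <- seq_len(h); cols <- seq_len(w)
  keep_r <- rows >= rect$top & rows <= rect$bottom
  keep_c <- cols >= rect$left & cols <= rect$right
  out[!keep_r, ] <- FALSE
  out[, !keep_c] <- FALSE
  lesion_mask(out)
}

# offsets (drow, dcol) of a structuring element
struct_el_offsets <- function(struct_el = c("disk", "n4", "n8"), radius = 2) {
  struct_el <- match.arg(struct_el)
  if (struct_el == "n4")
    return(cbind(dr = c(0, -1, 1, 0, 0), dc = c(0, 0, 0, -1, 1)))
  if (struct_el == "n8") {
    g <- expand.grid(dr = -1:1, dc = -1:1)
    return(as.matrix(g))
  }
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE])
}

shift_mask <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  okr <- rs >= 1 & rs <= h; okc <- cs >= 1 & cs <= w
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with the same structuring element; removes
#' foreground specks (hair, gel artifacts) smaller than the element while
#' leaving large blobs intact. Outside the image is treated as background.
#'
#' @param m lesion mask.
#' @param struct_el `"disk"` (default, see `radius`), `"n4"` (cross) or
#'   `"n8"` (3x3 square).
#' @param radius disk radius in pixels (default 2).
#' @return opened `lesion_mask`, a subset of the input foreground.
#' @export
morphological_open <- function(m, struct_el = c("disk", "n4", "n8"),
                               radius = 2) {
  m <- as_mask(m)
  off <- struct_el_offsets(match.arg(struct_el), radius)
  x <- unclass(m)
  er <- matrix(TRUE, nrow(x), ncol(x))
  for (i in seq_len(nrow(off)))
    er <- er & shift_mask(x, -off[i, 1], -off[i, 2], fill = FALSE)
  di <- matrix(FALSE, nrow(x), ncol(x))
  for (i in seq_len(nrow(off)))
    di <- di | shift_mask(er, off[i, 1], off[i, 2], fill = FALSE)
  lesion_mask(di)
}

# label 8-connected foreground components; returns list(labels=int matrix,
# n=count) with 0 = background
label_components <- function(bits) {
  h <- nrow(bits); w <- ncol(bits)
  idx <- which(bits)
  if (length(idx) == 0L) return(list(labels = matrix(0L, h, w), n = 0L))
  pos <- integer(h * w); pos[idx] <- seq_along(idx)
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r <- ((idx - 1L) %% h) + 1L
    c <- ((idx - 1L) %/% h) + 1L
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    hit <- bits[nb]
    if (any(hit))
      edges <- rbind(edges, cbind(pos[idx[ok][hit]], pos[nb[hit]]))
  }
  gr <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) gr <- igraph::add_edges(gr, t(edges))
  memb <- igraph::components(gr)$membership
  labels <- matrix(0L, h, w)
  labels[idx] <- memb
  list(labels = labels, n = max(memb))
}

#' Keep the central lesion cluster
#'
#' Retains exactly one 8-connected foreground component: the largest whose
#' bounding box intersects the central ninth of the image; if none does, the
#' component nearest the image center.
#'
#' @param m lesion mask with at least one foreground pixel.
#' @return `lesion_mask` with a single component.
#' @export
select_central_cluster <- function(m) {
  m <- as_mask(m)
  bits <- unclass(m)
  lab <- label_components(bits)
  if (lab$n == 0L)
    abort2("mask has no foreground: segmentation failed",
           "abruptcut_data_error")
  h <- nrow(bits); w <- ncol(bits)
  rc <- which(lab$labels > 0L, arr.ind = TRUE)
  comp <- lab$labels[lab$labels > 0L]
  r_lo <- h / 3; r_hi <- 2 * h / 3; c_lo <- w / 3; c_hi <- 2 * w / 3
  areas <- tabulate(comp, lab$n)
  bb <- vapply(seq_len(lab$n), function(k) {
    rs <- rc[comp == k, 1]; cs <- rc[comp == k, 2]
    c(min(rs), max(rs), min(cs), max(cs))
  }, numeric(4))
  central <- bb[2, ] >= r_lo & bb[1, ] <= r_hi & bb[4, ] >= c_lo & bb[3, ] <= c_hi
  if (any(central)) {
    keep <- which(central)[which.max(areas[central])]
  } else {
    ctr <- c(h, w) / 2
    d2 <- vapply(seq_len(lab$n), function(k) {
      rs <- rc[comp == k, , drop = FALSE]
      min((rs[, 1] - ctr[1])^2 + (rs[, 2] - ctr[2])^2)
    }, numeric(1))
    keep <- which.min(d2)
  }
  lesion_mask(lab$labels == keep)
}

#' Full mask standardization pipeline
#'
#' Applies, in fixed order: complement (optional; segmenters emit negative
#' masks), margin clipping, morphological opening, central-cluster selection.
#'
#' @param m binary mask matrix.
#' @param clip_percent percentage of each dimension to clip (default 10).
#' @param open_radius disk radius of the opening element (default 2).
#' @param complement whether the input is a negative mask that must be
#'   flipped first (default FALSE: the synthetic generator already emits
#'   positive masks).
#' @return standardized `lesion_mask` with exactly one 8-connected component.
#' @export
standardize_mask <- function(m, clip_percent = 10, open_radius = 2,
                             complement = FALSE) {
  m <- as_mask(m)
  if (complement) m <- complement_mask(m)
  rect <- compute_clip_rect(ncol(m), nrow(m), clip_percent)
  m <- clip_outside(m, rect)
  m <- morphological_open(m, "disk", open_radius)
  select_central_cluster(m)
}
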