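## sampling: peripheral circular regions for the three extraction methods.
##
## method 1 — full disks centered on the traced boundary itself;
## method 2 — disks on the "shadow border" obtained by shifting every
##            boundary point r pixels along its own unit vector toward the
##            centroid (fails on strongly concave lesions: points collapse);
## method 3 — disks on the shadow border obtained by uniform dynamic scaling
##            about the centroid so the starting point moves inward exactly r.
## Methods 2 and 3 intersect each disk with the lesion interior.

#' Compact region mask
#'
#' A binary pixel set stored over its bounding box with offsets into the
#' full image grid.
#'
#' @param bits logical matrix over the bounding box.
#' @param row0,col0 1-based full-image coordinates of `bits[1, 1]`.
#' @param dims full image `c(H, W)`.
#' @param provenance one of `method1_circle`, `method2_polygon`,
#'   `method3_polygon`.
#' @param center_index index of the generating center on the source path.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(bits, row0, col0, dims,
                        provenance = "method1_circle", center_index = NA) {
  structure(list(bits = bits, row0 = as.integer(row0),
                 col0 = as.integer(col0), dims = as.integer(dims),
                 provenance = provenance, center_index = center_index),
            class = "region_mask")
}

#' Expand a region mask to a full-image logical matrix
#' @param region a [region_mask()].
#' @param dims full image dims (defaults to the region's own).
#' @return logical H x W matrix.
#' @export
region_full <- function(region, dims = region$dims) {
  out <- matrix(FALSE, dims[1], dims[2])
  h <- nrow(region$bits); w <- ncol(region$bits)
  out[region$row0:(region$row0 + h - 1L),
      region$col0:(region$col0 + w - 1L)] <- region$bits
  out
}

# full-image linear (column-major) indices of the region pixels
region_lin_idx <- function(region) {
  idx <- which(region$bits, arr.ind = TRUE)
  (region$col0 + idx[, 2] - 2L) * region$dims[1] + (region$row0 + idx[, 1] - 1L)
}

#' Number of pixels in a region
#' @param region a [region_mask()].
#' @export
region_size <- function(region) sum(region$bits)

#' Place equally spaced circle centers along a cyclic path
#'
#' Centers sit at path indices `1, 1 + k, 1 + 2k, ...` with spacing
#' `k = round(1.5 r)` (half-up; a radius of 2 puts consecutive centers 3
#' chain-code pixels apart), stopping before wrapping past the start. The
#' first center is always the starting (upmost) pixel.
#'
#' @param path a `boundary_path` or inner-boundary matrix.
#' @param r circle radius in pixels.
#' @return integer vector of 1-based path indices.
#' @export
place_centers <- function(path, r) {
  n <- nrow(path)
  k <- round_half_up(1.5 * r)
  if (n < k) {
    warning("path shorter than the center spacing: single center",
            call. = FALSE)
    return(1L)
  }
  seq.int(1L, n, by = k)
}

# rasterize a disk: pixel (p, q) included iff (p - cy)^2 + (q - cx)^2 <= r^2,
# clipped to image bounds
rasterize_disk <- function(cx, cy, r, dims, provenance, center_index = NA) {
  r0 <- max(1L, as.integer(floor(cy - r)))
  r1 <- min(dims[1], as.integer(ceiling(cy + r)))
  c0 <- max(1L, as.integer(floor(cx - r)))
  c1 <- min(dims[2], as.integer(ceiling(cx + r)))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  bits <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r^2
  if (!any(bits)) return(NULL)
  region_mask(bits, r0, c0, dims, provenance, center_index)
}

#' Method-1 sampling regions: full disks on the boundary
#'
#' One disk per placed center, clipped to the image bounds but NOT
#' intersected with the lesion: this method deliberately includes
#' outside-border pixels (which is why it underperforms the shadow-border
#' methods).
#'
#' @param m lesion mask (supplies image dims).
#' @param path traced `boundary_path`.
#' @param r circle radius (one of the configured scales).
#' @return list of [region_mask()]s with provenance `method1_circle`.
#' @export
method1_regions <- function(m, path, r) {
  m <- as_mask(m)
  dims <- dim(unclass(m))
  centers <- place_centers(path, r)
  out <- list()
  for (i in centers) {
    reg <- rasterize_disk(path[i, 2], path[i, 1], r, dims,
                          "method1_circle", i)
    if (!is.null(reg)) out[[length(out) + 1L]] <- reg
  }
  out
}

path_xy <- function(path) cbind(x = path[, 2], y = path[, 1])

#' Method-2 inner boundary: per-point vector shift toward the centroid
#'
#' Every boundary point is moved `r` pixels along its own unit vector toward
#' the lesion centroid. If any boundary point lies within `r` of the centroid
#' the contraction is degenerate (the documented failure mode where regions
#' end up outside the lesion and many points collapse together); a classed
#' error `abruptcut_degenerate_contraction` is raised rather than silently
#' repaired. The minimum spacing between consecutive contracted points is
#' attached as attribute `min_spacing` so collapsing stretches can be
#' detected on shapes that pass the distance precondition.
#'
#' @param path traced `boundary_path`.
#' @param centroid `c(x, y)` from [mask_centroid()].
#' @param r contraction distance in pixels.
#' @return numeric matrix with columns `row`, `col` (sub-pixel), attributes
#'   `method = "vector_shift"`, `r`, `min_spacing`.
#' @export
method2_inner_boundary <- function(path, centroid, r) {
  xy <- path_xy(path)
  dx <- centroid[["x"]] - xy[, 1]
  dy <- centroid[["y"]] - xy[, 2]
  dist <- sqrt(dx^2 + dy^2)
  if (any(dist <= r))
    abort2(sprintf(
      "degenerate contraction: %d boundary point(s) within r = %g of the centroid",
      sum(dist <= r), r), "abruptcut_degenerate_contraction")
  nx <- xy[, 1] + dx / dist * r
  ny <- xy[, 2] + dy / dist * r
  out <- cbind(row = ny, col = nx)
  n <- nrow(out)
  if (n > 1L) {
    nxt <- c(2:n, 1L)
    sp <- sqrt((out[, 1] - out[nxt, 1])^2 + (out[, 2] - out[nxt, 2])^2)
    attr(out, "min_spacing") <- min(sp)
  } else attr(out, "min_spacing") <- NA_real_
  attr(out, "method") <- "vector_shift"
  attr(out, "r") <- r
  out
}

#' Method-3 scale factor
#'
#' `s = 1 - r / rho`, where `rho` is the distance from the starting boundary
#' point to the centroid (coordinates taken relative to the centroid; in
#' absolute coordinates the factor would depend on where the lesion sits in
#' the frame, which contradicts the perfect-circle derivation).
#'
#' @param start `(row, col)` starting boundary point.
#' @param centroid `c(x, y)`.
#' @param r contraction distance in pixels.
#' @return scalar `s` in (0, 1).
#' @export
method3_scale_factor <- function(start, centroid, r) {
  rho <- sqrt((start[[2]] - centroid[["x"]])^2 +
              (start[[1]] - centroid[["y"]])^2)
  if (rho <= r)
    abort2(sprintf("lesion too small: start-to-centroid distance %.2f <= r = %g",
                   rho, r), "abruptcut_degenerate_contraction")
  unname(1 - r / rho)
}

#' Method-3 inner boundary: dynamic scaling about the centroid
#'
#' All boundary points are scaled uniformly by `s` (from
#' [method3_scale_factor()]) and then translated by the difference vector
#' between the lesion centroid and the centroid of the scaled boundary, so
#' the net effect is a similarity transform about the centroid under which
#' the starting point moves inward by exactly `r`.
#'
#' @inheritParams method2_inner_boundary
#' @return numeric matrix with columns `row`, `col`, attributes
#'   `method = "dynamic_scale"`, `r`, `s`.
#' @export
method3_inner_boundary <- function(path, centroid, r) {
  s <- method3_scale_factor(path[1, ], centroid, r)
  xy <- path_xy(path)
  sx <- s * xy[, 1]
  sy <- s * xy[, 2]
  dvec <- c(centroid[["x"]] - mean(sx), centroid[["y"]] - mean(sy))
  out <- cbind(row = sy + dvec[2], col = sx + dvec[1])
  attr(out, "method") <- "dynamic_scale"
  attr(out, "r") <- r
  attr(out, "s") <- s
  out
}

#' Intersect a sampling circle with the lesion interior
#'
#' Raster intersection of the disk with the lesion foreground (equivalent to
#' polygon clipping up to rasterization, and robust to self-touching
#' contours). An empty intersection — the method-2 failure signature — is
#' skipped with a warning and `NULL` is returned so callers can log the count.
#'
#' @param center `c(x, y)` sub-pixel circle center.
#' @param r radius in pixels.
#' @param m lesion mask.
#' @param provenance provenance tag for the resulting region.
#' @param center_index index of the center on its source path.
#' @return a [region_mask()] subset of the lesion foreground, or `NULL`.
#' @export
intersect_with_lesion <- function(center, r, m,
                                  provenance = "method3_polygon",
                                  center_index = NA) {
  m <- as_mask(m)
  bits <- unclass(m)
  disk <- rasterize_disk(center[1], center[2], r, dim(bits), provenance,
                         center_index)
  if (is.null(disk)) {
    warning("circle falls outside the image: region skipped", call. = FALSE)
    return(NULL)
  }
  h <- nrow(disk$bits); w <- ncol(disk$bits)
  sub <- bits[disk$row0:(disk$row0 + h - 1L),
              disk$col0:(disk$col0 + w - 1L), drop = FALSE]
  disk$bits <- disk$bits & sub
  if (!any(disk$bits)) {
    warning("circle does not intersect the lesion: region skipped",
            call. = FALSE)
    return(NULL)
  }
  disk
}

#' Build all sampling regions for one method and radius
#'
#' @param m standardized lesion mask.
#' @param path traced `boundary_path`.
#' @param centroid `c(x, y)` lesion centroid.
#' @param method 1, 2 or 3.
#' @param r radius.
#' @return list of [region_mask()]s (possibly shorter than the number of
#'   placed centers if intersections were empty; skipped counts are attached
#'   as attribute `n_skipped`).
#' @export
method_regions <- function(m, path, centroid, method, r) {
  method <- as.integer(method)
  if (method == 1L) {
    out <- method1_regions(m, path, r)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  inner <- if (method == 2L) method2_inner_boundary(path, centroid, r)
           else method3_inner_boundary(path, centroid, r)
  centers <- place_centers(inner, r)
  prov <- if (method == 2L) "method2_polygon" else "method3_polygon"
  out <- list()
  skipped <- 0L
  for (i in centers) {
    reg <- withCallingHandlers(
      intersect_with_lesion(c(inner[i, 2], inner[i, 1]), r, m, prov, i),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(reg)) skipped <- skipped + 1L
    else out[[length(out) + 1L]] <- reg
  }
  if (skipped > 0L)
    warning(sprintf("%d of %d regions skipped (empty lesion intersection) at r = %g",
                    skipped, length(centers), r), call. = FALSE)
  attr(out, "n_skipped") <- skipped
  out
}
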