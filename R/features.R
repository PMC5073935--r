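## features: the 240-dimensional per-image feature vector and feature table.
##
## Naming follows the field's shorthand, e.g. "Blu-10-MM" = blue channel,
## radius 10, Minimum of the region Means; aggregate A/M = average/minimum,
## statistic H/M/S = homogeneity/mean/standard deviation.

FEATURE_RADII <- c(5, 7, 10, 15)
FEATURE_STATS <- c("AH", "MH", "AM", "MM", "AS", "MS")

#' Canonical feature names
#'
#' 10 channels x 4 radii x \{A, M\} x \{H, M, S\} = 240 names, rendered as
#' `"<channel>-<radius>-<agg><stat>"`.
#'
#' @param channels channel labels (default all ten).
#' @param radii circle radii (default 5, 7, 10, 15).
#' @return character vector of feature names.
#' @export
feature_names <- function(channels = CHANNEL_LABELS, radii = FEATURE_RADII) {
  as.vector(t(outer(channels, as.vector(t(outer(radii, FEATURE_STATS,
                                                paste, sep = "-"))),
                    paste, sep = "-")))
}

# split "Blu-10-MM" -> channel part
feature_channel <- function(names) sub("-.*$", "", names)

#' Extract the per-image feature vector
#'
#' For each channel and radius, statistics (GLCM homogeneity, mean, standard
#' deviation) are computed over every peripheral sampling region of the
#' chosen method, then aggregated over the regions by average and minimum.
#' Regions skipped because of empty lesion intersections, and regions too
#' thin to contain a single co-occurring pair (homogeneity undefined), are
#' excluded from the aggregates rather than imputed.
#'
#' @param stack a `channel_stack` from [extract_channels()].
#' @param m standardized lesion mask.
#' @param method sampling method 1, 2 or 3 (default 3, dynamic scaling).
#' @param radii circle radii (default `c(5, 7, 10, 15)`).
#' @param spec a [glcm_spec()]; the default (L = 8, right-neighbor offset,
#'   both-in-region pairing) matches the package defaults throughout.
#' @param homogeneity_mode `"standard"` or `"paper_literal"`.
#' @param image_id identifier stored on the result.
#' @return named numeric vector of `10 * length(radii) * 6` features with
#'   attributes `image_id` and `method`.
#' @export
extract_features <- function(stack, m, method = 3, radii = FEATURE_RADII,
                             spec = glcm_spec(),
                             homogeneity_mode = c("standard", "paper_literal"),
                             image_id = "image") {
  stopifnot(inherits(stack, "channel_stack"))
  homogeneity_mode <- match.arg(homogeneity_mode)
  m <- as_mask(m)
  bits <- unclass(m)
  path <- trace_boundary(m)
  ctr <- mask_centroid(m)
  H <- nrow(bits)

  fast_ok <- spec$pair_mode == "both_in_region" &&
    homogeneity_mode == "standard"

  # unit-scaled and quantized planes, computed once per channel; quantization
  # is at image level so all regions of an image share one gray scale
  umats <- lapply(stack, channel_unit)
  qmats <- lapply(stack, function(ch) {
    rng <- spec$quantize_range
    if (identical(rng, "channel")) rng <- ch$value_range
    if (is.null(rng)) rng <- range(ch$values)
    quantize_levels(ch$values, spec$levels, rng)
  })

  out <- numeric(0)
  for (r in radii) {
    regions <- withCallingHandlers(
      method_regions(m, path, ctr, method, r),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(regions) == 0L)
      abort2(sprintf("no valid sampling regions at radius %g (lesion too small)", r),
             "abruptcut_feature_error")
    # region pixel / pair index vectors, shared across channels
    pix <- lapply(regions, region_lin_idx)
    if (fast_ok) {
      pairs <- lapply(regions, function(reg) {
        b <- reg$bits
        nr <- nrow(b); nc <- ncol(b)
        dr <- spec$dy; dc <- spec$dx
        if (nr <= abs(dr) || nc <= abs(dc))
          return(list(a = integer(0), b = integer(0)))
        rs <- seq_len(nr); cs <- seq_len(nc)
        okr <- rs[rs + dr >= 1 & rs + dr <= nr]
        okc <- cs[cs + dc >= 1 & cs + dc <= nc]
        keep <- b[okr, okc, drop = FALSE] &
                b[okr + dr, okc + dc, drop = FALSE]
        w <- which(keep, arr.ind = TRUE)
        if (nrow(w) == 0L) return(list(a = integer(0), b = integer(0)))
        ra <- okr[w[, 1]] + reg$row0 - 1L
        ca <- okc[w[, 2]] + reg$col0 - 1L
        list(a = (ca - 1L) * H + ra,
             b = (ca + dc - 1L) * H + (ra + dr))
      })
    }
    for (ch in CHANNEL_LABELS) {
      u <- umats[[ch]]
      nreg <- length(regions)
      hom <- mu <- sdv <- numeric(nreg)
      for (k in seq_len(nreg)) {
        v <- u[pix[[k]]]
        mu[k] <- mean(v)
        sdv[k] <- sqrt(mean((v - mu[k])^2))
        if (fast_ok) {
          q <- qmats[[ch]]
          hom[k] <- fast_homogeneity(q[pairs[[k]]$a], q[pairs[[k]]$b])
        } else {
          cm <- withCallingHandlers(
            compute_glcm(stack[[ch]], region_full(regions[[k]]), spec),
            warning = function(w) invokeRestart("muffleWarning"))
          hom[k] <- if (cm$n_pairs == 0L) NA_real_
            else glcm_homogeneity(normalize_glcm(cm, "pair_count"),
                                  homogeneity_mode)
        }
      }
      ok <- !is.na(hom)
      if (!any(ok))
        abort2(sprintf("no region at radius %g supports a co-occurrence pair", r),
               "abruptcut_feature_error")
      vals <- c(mean(hom[ok]), min(hom[ok]), mean(mu), min(mu),
                mean(sdv), min(sdv))
      names(vals) <- paste(ch, r, FEATURE_STATS, sep = "-")
      out <- c(out, vals)
    }
  }
  out <- out[feature_names(CHANNEL_LABELS, radii)]  # canonical order
  attr(out, "image_id") <- image_id
  attr(out, "method") <- as.integer(method)
  out
}

#' Assemble a feature table from feature vectors and labels
#'
#' @param vectors list of [extract_features()] results.
#' @param labels character vector (`"malignant"` / `"benign"`), one per
#'   vector.
#' @return data.frame with columns `image_id`, `label`, then one column per
#'   feature; attribute `normalized = FALSE`.
#' @export
feature_table <- function(vectors, labels) {
  stopifnot(length(vectors) == length(labels))
  mat <- do.call(rbind, lapply(vectors, as.numeric))
  colnames(mat) <- names(vectors[[1]])
  ids <- vapply(vectors, function(v) as.character(attr(v, "image_id")),
                character(1))
  df <- data.frame(image_id = ids, label = labels, mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "normalized") <- FALSE
  df
}

ft_feature_cols <- function(t) setdiff(names(t), c("image_id", "label"))

#' Restrict a feature table to selected channels
#'
#' @param t a [feature_table()].
#' @param channels subset of the ten channel labels; each retained channel
#'   keeps its 24 features (4 radii x 6 statistics).
#' @return feature table with restricted columns.
#' @export
subset_channels <- function(t, channels) {
  unknown <- setdiff(channels, CHANNEL_LABELS)
  if (length(unknown))
    abort2(paste0("unknown channel label(s): ", paste(unknown, collapse = ", ")),
           "abruptcut_param_error")
  keep <- ft_feature_cols(t)[feature_channel(ft_feature_cols(t)) %in% channels]
  out <- t[, c("image_id", "label", keep), drop = FALSE]
  attr(out, "normalized") <- attr(t, "normalized") %||% FALSE
  out
}

#' Normalize feature columns to [-1, 1]
#'
#' Per column: `x' = 2 (x - min) / (max - min) - 1`; constant columns map to
#' 0. Idempotent. Fold-aware normalization for cross-validation is handled
#' inside [evaluate_classifier()], which learns min/max on the training rows
#' only.
#'
#' @param t a [feature_table()] with at least 2 rows.
#' @return normalized feature table (attribute `normalized = TRUE`).
#' @export
normalize_table <- function(t) {
  if (nrow(t) < 2L)
    abort2("need at least 2 rows to normalize", "abruptcut_data_error")
  cols <- ft_feature_cols(t)
  for (cl in cols) {
    x <- t[[cl]]
    lo <- min(x); hi <- max(x)
    t[[cl]] <- if (hi > lo) 2 * (x - lo) / (hi - lo) - 1 else rep(0, length(x))
  }
  attr(t, "normalized") <- TRUE
  t
}

#' Write / read a feature table as CSV
#' @param t a [feature_table()].
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(t, path) {
  write.csv(t, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "normalized") <- FALSE
  df
}
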