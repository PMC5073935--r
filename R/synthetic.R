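## synthetic: dermoscopy-like lesion images with controllable border
## abruptness, standing in for clinical data in tests and benchmarks.
##
## The border is a harmonic radial curve r(theta) = R0 (1 + sum a_k
## cos(k theta + phi_k)); the macro intensity profile across it is a logistic
## (sigmoid) edge whose width tau — per angular sector, the "virtual pie" —
## operationalizes abrupt cutoff. On top of the macro edge sits a
## band-limited pigment-pattern field (the reticular texture of a pigmented
## lesion) whose local contrast is modulated by the same edge envelope: in an
## abrupt sector the pattern keeps full contrast right up to the border, in a
## gradual sector it has already faded where the shadow border samples it —
## which is precisely what peripheral GLCM homogeneity reacts to. A lesion is
## malignant when at least one sector's edge width is at or below the
## abruptness threshold.

#' Synthetic lesion specification
#'
#' @param image_size `c(H, W)` in pixels.
#' @param base_radius mean border radius R0 in pixels.
#' @param harmonics matrix-like with columns `k`, `amplitude`, `phase`
#'   shaping the radial border; `NULL` for a perfect circle.
#' @param n_sectors number of angular sectors (default 8, the clinical
#'   virtual pie).
#' @param sector_tau numeric vector of per-sector border edge widths tau in
#'   pixels (> 0); recycled to `n_sectors`.
#' @param tau_abrupt abruptness threshold in pixels: the lesion is labeled
#'   malignant iff any sector has `tau <= tau_abrupt` (default 2).
#' @param lesion_color,skin_color RGB triples in 0..255; lesions are darker
#'   than the surrounding skin by dermoscopy convention.
#' @param noise_sigma additive Gaussian intensity noise (8-bit units).
#' @param pattern_contrast pigment-pattern strength as a fraction of the
#'   skin-lesion contrast per plane (default 0.4; 0 disables the pattern and
#'   recovers a pure sigmoid edge).
#' @param pattern_scale correlation length of the pattern field in pixels.
#' @param tau_channels which RGB planes respond to the per-sector tau
#'   (default all three). Non-responsive planes use `gradual_tau` for the
#'   macro edge and keep full-contrast pattern up to the border for every
#'   sample, so border-sharpness class contrast can be injected into a
#'   chosen plane while the others act as class-independent distractors.
#' @param gradual_tau edge width for planes outside `tau_channels`.
#' @param center_jitter `c(dx, dy)` displacement of the lesion center from
#'   the image center, in pixels.
#' @param seed RNG seed for the pixel noise.
#' @return object of class `synthetic_lesion_spec`.
#' @export
synthetic_lesion_spec <- function(image_size = c(256L, 256L),
                                  base_radius = 60,
                                  harmonics = NULL,
                                  n_sectors = 8L,
                                  sector_tau = 9,
                                  tau_abrupt = 2,
                                  lesion_color = c(90, 60, 50),
                                  skin_color = c(210, 170, 140),
                                  noise_sigma = 2,
                                  pattern_contrast = 0.4,
                                  pattern_scale = 1.5,
                                  tau_channels = c("R", "G", "B"),
                                  gradual_tau = 9,
                                  center_jitter = c(0, 0),
                                  seed = 1L) {
  sector_tau <- rep_len(sector_tau, n_sectors)
  if (any(sector_tau <= 0))
    abort2("every sector tau must be positive", "abruptcut_param_error")
  amp <- if (is.null(harmonics)) 0 else sum(abs(harmonics[, 2]))
  if (base_radius * (1 + amp) >= min(image_size) / 2 - 2)
    abort2("lesion border does not fit inside the frame",
           "abruptcut_param_error")
  structure(list(image_size = as.integer(image_size),
                 base_radius = base_radius, harmonics = harmonics,
                 n_sectors = as.integer(n_sectors), sector_tau = sector_tau,
                 tau_abrupt = tau_abrupt, lesion_color = lesion_color,
                 skin_color = skin_color, noise_sigma = noise_sigma,
                 pattern_contrast = pattern_contrast,
                 pattern_scale = pattern_scale,
                 tau_channels = tau_channels, gradual_tau = gradual_tau,
                 center_jitter = center_jitter, seed = as.integer(seed)),
            class = "synthetic_lesion_spec")
}

#' Ground-truth label of a spec
#'
#' Pure function of the specification: malignant iff at least one sector's
#' edge width is at or below `tau_abrupt`.
#'
#' @param spec a [synthetic_lesion_spec()].
#' @return `"malignant"` or `"benign"`.
#' @export
lesion_label <- function(spec) {
  if (any(spec$sector_tau <= spec$tau_abrupt)) "malignant" else "benign"
}

# zero-mean, unit-sd band-limited random field (separable Gaussian smoothing
# of white noise, edge-replicated)
pattern_field <- function(H, W, scale) {
  z <- matrix(rnorm(H * W), H, W)
  rad <- max(1L, ceiling(2 * scale))
  wgt <- exp(-((-rad):rad)^2 / (2 * scale^2))
  wgt <- wgt / sum(wgt)
  sm_rows <- function(m) {
    out <- m * 0
    for (i in seq_along(wgt)) {
      o <- i - rad - 1L
      out <- out + wgt[i] * m[pmin(pmax(seq_len(nrow(m)) + o, 1L), nrow(m)), ]
    }
    out
  }
  z <- sm_rows(z)
  z <- t(sm_rows(t(z)))
  (z - mean(z)) / sd(z)
}

#' Generate one synthetic lesion image, mask and label
#'
#' Per RGB plane, the noiseless intensity at signed radial distance `d`
#' outside the border is
#' `skin + (lesion - skin) * sigmoid(-d / tau) + A * pattern * env(d)`,
#' where `pattern` is a shared band-limited pigment-texture field with
#' amplitude `A = pattern_contrast * |skin - lesion|`, and
#' `env(d) = sigmoid(-(d + 2 tau) / max(tau/2, 0.5))` models the transition
#' band: a border of edge width `tau` is depleted of pigment pattern over a
#' band of about `2 tau` pixels, so an abrupt border carries full-contrast
#' texture essentially up to the lesion edge while a gradual border presents
#' an almost pattern-free rim to the peripheral sampling regions. Seeded
#' Gaussian noise is then added and values are rounded into 0..255. The
#' ground-truth mask is `d < 0`; with `pattern_contrast = 0` this coincides
#' with thresholding the noiseless image at the 50 % level of the edge
#' profile.
#'
#' @param spec a [synthetic_lesion_spec()].
#' @return a `labeled_sample`: list with `image` ([rgb_image()]), `mask`
#'   ([lesion_mask()]), `label`, and `spec`.
#' @export
generate_lesion <- function(spec) {
  stopifnot(inherits(spec, "synthetic_lesion_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cx <- (W + 1) / 2 + spec$center_jitter[1]
  cy <- (H + 1) / 2 + spec$center_jitter[2]
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  Y <- matrix(seq_len(H), H, W)
  rho <- sqrt((X - cx)^2 + (Y - cy)^2)
  theta <- atan2(Y - cy, X - cx) %% (2 * pi)
  rb <- rep(spec$base_radius, length(theta))
  if (!is.null(spec$harmonics)) {
    hm <- spec$harmonics
    for (i in seq_len(nrow(hm)))
      rb <- rb + spec$base_radius * hm[i, 2] * cos(hm[i, 1] * theta + hm[i, 3])
  }
  d <- rho - rb  # signed radial distance, > 0 outside the border
  sector <- pmin(floor(theta / (2 * pi / spec$n_sectors)),
                 spec$n_sectors - 1) + 1
  tau_map <- matrix(spec$sector_tau[sector], H, W)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  arr <- array(0L, dim = c(H, W, 3L))
  plane_names <- c("R", "G", "B")
  for (k in 1:3) {
    # independent per-plane pattern fields: chromophore density fluctuations
    # are only partially coupled across wavelengths, and a shared field would
    # let difference channels (Cb/Cr) cancel the gradual-sector texture
    pat <- if (spec$pattern_contrast > 0)
      pattern_field(H, W, spec$pattern_scale) else matrix(0, H, W)
    responsive <- plane_names[k] %in% spec$tau_channels
    tau_k <- if (responsive) tau_map
             else matrix(spec$gradual_tau, H, W)
    edge <- plogis(-d / tau_k)
    # responsive planes: pattern depleted over a band of ~2 tau inside the
    # border (the class signal); neutral planes keep full-contrast pattern up
    # to the border for every sample, a class-independent distractor
    env_pat <- if (responsive) plogis(-(d + 2 * tau_k) / pmax(tau_k / 2, 0.5))
               else plogis(-(d + 2) / 1)
    contrast <- spec$lesion_color[k] - spec$skin_color[k]
    v <- spec$skin_color[k] + contrast * edge +
      spec$pattern_contrast * abs(contrast) * pat * env_pat
    if (spec$noise_sigma > 0)
      v <- v + rnorm(length(v), sd = spec$noise_sigma)
    arr[, , k] <- matrix(as.integer(pmin(pmax(round(v), 0), 255)), H, W)
  }
  structure(list(image = rgb_image(arr), mask = lesion_mask(d < 0),
                 label = lesion_label(spec), spec = spec),
            class = "labeled_sample")
}

#' Generate a labeled synthetic dataset
#'
#' Benign samples draw every sector's tau uniformly from `gradual_range`;
#' malignant samples additionally set 1-3 randomly chosen sectors to an
#' abrupt tau drawn from `abrupt_range`. Lesion size, border harmonics,
#' center jitter and per-sample noise seeds are derived from the master
#' seed, so the whole dataset is reproducible. Sample order is shuffled.
#'
#' @param n_benign,n_malignant class counts (the reference benchmark uses
#'   69 benign and 31 malignant).
#' @param seed master RNG seed.
#' @param image_size `c(H, W)` (default 256 x 256).
#' @param radius_frac range of base radius as a fraction of `min(H, W)`.
#' @param gradual_range,abrupt_range tau ranges in pixels for gradual and
#'   abrupt sectors.
#' @param tau_abrupt label threshold in pixels.
#' @param noise_sigma Gaussian noise level.
#' @param tau_channels RGB planes carrying the sector tau (see
#'   [synthetic_lesion_spec()]).
#' @param n_sectors sectors per lesion.
#' @return list of `labeled_sample`s.
#' @export
generate_dataset <- function(n_benign, n_malignant, seed = 1L,
                             image_size = c(256L, 256L),
                             radius_frac = c(0.22, 0.30),
                             gradual_range = c(6, 12),
                             abrupt_range = c(0.5, 2),
                             tau_abrupt = 2,
                             noise_sigma = 2,
                             tau_channels = c("R", "G", "B"),
                             n_sectors = 8L) {
  stopifnot(n_benign + n_malignant >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- n_benign + n_malignant
  malignant <- sample(c(rep(TRUE, n_malignant), rep(FALSE, n_benign)))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    R0 <- runif(1, radius_frac[1], radius_frac[2]) * min(image_size)
    harmonics <- cbind(k = sample(2:5, 2),
                       amplitude = runif(2, 0.02, 0.08),
                       phase = runif(2, 0, 2 * pi))
    tau <- runif(n_sectors, gradual_range[1], gradual_range[2])
    if (malignant[i]) {
      nab <- sample(1:3, 1)
      tau[sample.int(n_sectors, nab)] <- runif(nab, abrupt_range[1],
                                               abrupt_range[2])
    }
    jit <- runif(2, -0.02, 0.02) * min(image_size)
    spec <- synthetic_lesion_spec(
      image_size = image_size, base_radius = R0, harmonics = harmonics,
      n_sectors = n_sectors, sector_tau = tau, tau_abrupt = tau_abrupt,
      noise_sigma = noise_sigma, tau_channels = tau_channels,
      center_jitter = jit, seed = sub_seeds[i])
    samples[[i]] <- generate_lesion(spec)
  }
  samples
}

#' Write a synthetic dataset to disk
#'
#' Images as P3 pixmaps (`<stem>.ppm`), masks as P1 bitmaps
#' (`<stem>_mask.pbm`), labels in `labels.csv`.
#'
#' @param samples list of `labeled_sample`s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- data.frame(image_id = character(0), label = character(0))
  for (i in seq_along(samples)) {
    stem <- sprintf("sample%03d", i)
    write_pnm(samples[[i]]$image, file.path(dir, paste0(stem, ".ppm")))
    write_pnm(unclass(samples[[i]]$mask),
              file.path(dir, paste0(stem, "_mask.pbm")))
    labs <- rbind(labs, data.frame(image_id = stem,
                                   label = samples[[i]]$label))
  }
  write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
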