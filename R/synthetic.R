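# Seeded generator of dermoscopy-like synthetic images. Each sample is a
# single pigmented-lesion blob — an ellipse with a low-frequency radial
# perturbation, so the region is star-convex (hence connected) but
# irregular — rendered darker than a skin-toned background. Boundary
# fuzziness (Gaussian blur of the blending alpha), global contrast, additive
# noise, and distractor artifacts (dark hair arcs, a bright glue halo,
# ruler ticks) emulate the traits that make real dermoscopy hard. Artifacts
# are composited AFTER the mask is fixed: they perturb the image only, the
# ground truth never changes.

#' Synthetic sample specification
#'
#' The defaults describe a moderately hard scene: visibly fuzzy boundary,
#' medium lesion/skin contrast, hair distractors and mild sensor noise.
#' Easy scenes (for threshold oracles) use `fuzziness = 0`, high `contrast`
#' and no artifacts.
#'
#' @param image_size square image side in pixels.
#' @param fuzziness Gaussian blur sigma (pixels) applied to the mask's
#'   blending alpha; 0 gives a crisp boundary.
#' @param contrast lesion/skin contrast in (0, 1]; higher is easier.
#' @param hair,glue,ruler artifact flags.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param irregularity amplitude of the radial boundary perturbation.
#' @param area_range admissible lesion area fraction range (subset of
#'   0.05 to 0.6).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(image_size = 128L, fuzziness = 1.5, contrast = 0.5,
                       hair = TRUE, glue = FALSE, ruler = FALSE,
                       noise_sd = 0.02, irregularity = 0.15,
                       area_range = c(0.08, 0.45), seed = NULL) {
  stopifnot(image_size >= 16, contrast > 0, contrast <= 1,
            fuzziness >= 0, noise_sd >= 0,
            area_range[1] >= 0.05, area_range[2] <= 0.6)
  structure(list(image_size = as.integer(image_size), fuzziness = fuzziness,
                 contrast = contrast, hair = hair, glue = glue,
                 ruler = ruler, noise_sd = noise_sd,
                 irregularity = irregularity, area_range = area_range,
                 seed = seed),
            class = "synth_spec")
}

blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Star-convex irregular blob mask; retries the perturbation if the area
# fraction leaves spec$area_range.
synth_mask <- function(spec) {
  s <- spec$image_size
  rr <- matrix(rep(seq_len(s), s), s, s)
  cc <- matrix(rep(seq_len(s), each = s), s, s)
  for (try in 1:12) {
    frac <- stats::runif(1, spec$area_range[1], spec$area_range[2])
    cen <- s / 2 + stats::runif(2, -s / 10, s / 10)
    r0 <- s * sqrt(frac / pi)
    ecc <- stats::runif(1, 0, 0.3)
    axes <- c(1 + ecc, 1 / (1 + ecc))
    k <- 2:5
    amp <- stats::rnorm(length(k), 0, spec$irregularity / sqrt(k))
    phs <- stats::runif(length(k), 0, 2 * pi)
    dr <- (rr - cen[1]) / axes[1]
    dc <- (cc - cen[2]) / axes[2]
    dist <- sqrt(dr^2 + dc^2)
    theta <- atan2(dc, dr)
    rad <- r0 * pmax(0.3, 1 + Reduce(`+`, lapply(seq_along(k), function(i)
      amp[i] * cos(k[i] * theta + phs[i]))))
    mask <- (dist <= rad) * 1
    got <- mean(mask)
    if (got >= spec$area_range[1] && got <= spec$area_range[2]) return(mask)
  }
  stop("generation error: could not reach an admissible lesion area fraction")
}

draw_hair <- function(img, s) {
  n <- sample(3:6, 1)
  for (i in seq_len(n)) {
    p <- matrix(stats::runif(6, 1, s), 3, 2)  # quadratic Bezier handles
    t <- seq(0, 1, length.out = 4L * s)
    br <- (1 - t)^2 * p[1, 1] + 2 * t * (1 - t) * p[2, 1] + t^2 * p[3, 1]
    bc <- (1 - t)^2 * p[1, 2] + 2 * t * (1 - t) * p[2, 2] + t^2 * p[3, 2]
    shade <- stats::runif(1, 0.05, 0.2)
    for (d in list(c(0, 0), c(1, 0), c(0, 1))) {
      r <- round(br) + d[1]; c <- round(bc) + d[2]
      ok <- r >= 1 & r <= s & c >= 1 & c <= s
      idx <- (c[ok] - 1) * s + r[ok]
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[idx] <- 0.35 * pl[idx] + 0.65 * shade
        img[, , ch] <- pl
      }
    }
  }
  img
}

draw_glue <- function(img, s) {
  rr <- matrix(rep(seq_len(s), s), s, s)
  cc <- matrix(rep(seq_len(s), each = s), s, s)
  cen <- stats::runif(2, s * 0.3, s * 0.7)
  rad <- stats::runif(1, s * 0.25, s * 0.45)
  width <- s * 0.04
  d <- sqrt(((rr - cen[1]) * stats::runif(1, 0.8, 1.2))^2 + (cc - cen[2])^2)
  band <- exp(-((d - rad) / width)^2)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.25 * band) + 0.25 * band
  img
}

draw_ruler <- function(img, s) {
  row0 <- sample(c(round(s * 0.1), round(s * 0.9)), 1)
  len <- max(3L, round(s * 0.05))
  at <- seq(round(s * 0.1), round(s * 0.9), by = max(4L, round(s * 0.06)))
  for (c0 in at) {
    rows <- row0:min(s, row0 + len)
    for (ch in 1:3) img[rows, c0, ch] <- 0.15
  }
  img
}

#' Generate one synthetic dermoscopy-like sample
#'
#' @param spec a [synth_spec()].
#' @param edge_thickness edge band thickness for the derived edge target.
#' @return an [image_sample()] with `$image`, binary `$mask`, derived
#'   `$edge`; reproducible bit-for-bit from `spec$seed`.
#' @export
generate_sample <- function(spec, edge_thickness = 2L) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    s <- spec$image_size
    mask <- synth_mask(spec)

    # skin background: warm base + smooth illumination gradient
    base <- c(0.85, 0.66, 0.58) + stats::runif(3, -0.05, 0.05)
    gdir <- stats::runif(2, -1, 1)
    rr <- matrix(rep(seq_len(s), s), s, s)
    cc <- matrix(rep(seq_len(s), each = s), s, s)
    grad <- (gdir[1] * (rr - s / 2) + gdir[2] * (cc - s / 2)) / s * 0.08
    img <- array(0, c(s, s, 3))
    for (ch in 1:3) img[, , ch] <- pmin(pmax(base[ch] + grad, 0), 1)

    # pigment fill, darker and browner than skin, with low-frequency texture
    lesion_col <- base * (1 - spec$contrast * c(0.55, 0.75, 0.7))
    texture <- blur_mat(matrix(stats::rnorm(s * s, 0, 1), s, s), s / 16)
    texture <- texture / max(abs(texture), 1e-8) * 0.05
    alpha <- if (spec$fuzziness > 0) blur_mat(mask, spec$fuzziness) else mask
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - alpha) +
        (lesion_col[ch] + texture) * alpha

    # distractor artifacts: image only, mask already fixed
    if (isTRUE(spec$hair)) img <- draw_hair(img, s)
    if (isTRUE(spec$glue)) img <- draw_glue(img, s)
    if (isTRUE(spec$ruler)) img <- draw_ruler(img, s)

    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- pmin(pmax(img, 0), 1)
    image_sample(img, mask, edge_thickness = edge_thickness)
  })
}

#' Simple thresholding oracle for generator difficulty
#'
#' Otsu-thresholds the grey-level image (lesion = darker side) and returns
#' the Jaccard index against the ground truth. High on crisp high-contrast
#' scenes, degrading with fuzziness/contrast loss — used to validate that
#' the generator spans easy to hard.
#'
#' @param sample an [image_sample()].
#' @return scalar Jaccard index of the Otsu baseline.
#' @export
otsu_baseline <- function(sample) {
  gray <- 0.299 * sample$image[, , 1] + 0.587 * sample$image[, , 2] +
    0.114 * sample$image[, , 3]
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  pred <- (gray < thr) * 1
  m <- metrics_from_counts(confusion(pred, sample$mask))
  m$JA
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` PNG image/mask pairs (8-bit RGB images; single-channel 0/255
#' masks) plus a CSV manifest recording each sample's spec and seed.
#' Per-sample seeds are `seed + i`, so the dataset is byte-identical across
#' runs of the same call.
#'
#' @param n number of samples.
#' @param spec a [synth_spec()] template (its `seed` field is ignored).
#' @param out_dir output directory (created if needed).
#' @param seed base seed.
#' @param train_frac fraction assigned `split = "train"`; the remainder is
#'   `"val"`. Id sets are disjoint.
#' @return invisibly, the manifest `data.frame` (also written as
#'   `manifest.csv`).
#' @export
generate_dataset <- function(n, spec = synth_spec(), out_dir, seed = 1L,
                             train_frac = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_train <- round(n * train_frac)
  rows <- lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- seed + i
    smp <- generate_sample(sp)
    id <- sprintf("img%05d", i)
    png::writePNG(aperm(smp$image, c(1, 2, 3)),
                  file.path(out_dir, paste0(id, ".png")))
    png::writePNG(smp$mask, file.path(out_dir, paste0(id, "_mask.png")))
    data.frame(image_id = id, image = paste0(id, ".png"),
               mask = paste0(id, "_mask.png"),
               split = if (i <= n_train) "train" else "val",
               seed = sp$seed, image_size = sp$image_size,
               fuzziness = sp$fuzziness, contrast = sp$contrast,
               hair = sp$hair, glue = sp$glue, ruler = sp$ruler,
               noise_sd = sp$noise_sd)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @param split optionally restrict to one split (`"train"` / `"val"`).
#' @param edge_thickness edge band thickness for derived edge targets.
#' @return list of [image_sample()] objects, named by image id.
#' @export
load_dataset <- function(dir, split = NULL, edge_thickness = 2L) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  if (!is.null(split)) manifest <- manifest[manifest$split == split, ]
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(file.path(dir, manifest$image[i]))
    msk <- png::readPNG(file.path(dir, manifest$mask[i]))
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    image_sample(img, round(msk), edge_thickness = edge_thickness)
  })
  names(out) <- manifest$image_id
  out
}
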