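# Ground-truth plumbing and geometric augmentation.
#
# The edge target is always derived from the segmentation mask (a thin band
# around the mask boundary obtained by morphological gradient), never
# supplied. Train-time augmentation composes flips, a centre crop at random
# scale, a small rotation, a ground-truth-box crop with zero padding, and a
# rigid moving-least-squares deformation into a SINGLE resampling: one
# coordinate map from the output grid back to the source image, applied
# bilinearly to the image and by nearest neighbour to the mask, so the pair
# stays exactly aligned and the mask stays binary. Test-time augmentation
# uses the six axis-aligned transforms, whose inverses are bit-exact.

## ---- samples -------------------------------------------------------------

#' Construct an image/mask/edge training sample
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param mask `(H, W)` binary matrix.
#' @param edge optional `(H, W)` binary edge map; derived from `mask` with
#'   [derive_edge()] when `NULL`.
#' @param edge_thickness thickness passed to [derive_edge()].
#' @param transforms record of geometric transforms applied so far.
#' @return an `image_sample` object.
#' @export
image_sample <- function(image, mask, edge = NULL, edge_thickness = 2L,
                         transforms = list()) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            all(dim(image)[1:2] == dim(mask)))
  mask <- binarize_mask(mask)
  if (is.null(edge)) edge <- derive_edge(mask, edge_thickness)
  structure(list(image = image, mask = mask, edge = edge,
                 transforms = transforms),
            class = "image_sample")
}

binarize_mask <- function(mask) {
  v <- as.numeric(mask)
  if (any(v != 0 & v != 1)) stop("validation error: mask must be binary (0/1)")
  m <- matrix(v, nrow(mask), ncol(mask))
  storage.mode(m) <- "double"
  m
}

## ---- edge derivation ------------------------------------------------------

# 4-neighbour shift-based binary morphology; pixels outside the frame count
# as background, so a full-frame mask erodes at the border.
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

dilate_cross <- function(m) {
  pmin(m + shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
         shift_mat(m, 0, 1) + shift_mat(m, 0, -1), 1)
}

erode_cross <- function(m) {
  m * shift_mat(m, 1, 0) * shift_mat(m, -1, 0) *
    shift_mat(m, 0, 1) * shift_mat(m, 0, -1)
}

#' Derive the edge ground truth from a segmentation mask
#'
#' Morphological gradient with a 3x3 cross: the edge band is
#' `dilate^k_out(mask) AND NOT erode^k_in(mask)` with
#' `k_out = floor(thickness/2)`, `k_in = ceiling(thickness/2)`, i.e. the
#' band straddles the boundary, biased one pixel inward for odd thickness
#' (thickness 1 is exactly the inner boundary). An empty mask yields an
#' empty edge.
#'
#' @param mask `(H, W)` binary matrix.
#' @param thickness band thickness in pixels (default 2).
#' @return `(H, W)` binary edge map.
#' @export
#' @examples
#' m <- matrix(0, 32, 32); m[12:21, 12:21] <- 1
#' sum(derive_edge(m, thickness = 1))  # the square's 36 boundary pixels
derive_edge <- function(mask, thickness = 2L) {
  m <- binarize_mask(mask)
  stopifnot(thickness >= 1)
  k_out <- thickness %/% 2L
  k_in <- as.integer(ceiling(thickness / 2))
  outer <- m
  for (i in seq_len(k_out)) outer <- dilate_cross(outer)
  inner <- m
  for (i in seq_len(k_in)) inner <- erode_cross(inner)
  outer * (1 - inner)
}

## ---- test-time augmentation ----------------------------------------------

swap_hw <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  aperm(x, c(2, 1, seq_along(d)[-(1:2)]))
}

index_rows <- function(x, i) {
  d <- dim(x)
  do.call(`[`, c(list(x, i), rep(list(quote(expr = )), length(d) - 1),
                 list(drop = FALSE)))
}

index_cols <- function(x, j) {
  d <- dim(x)
  do.call(`[`, c(list(x, quote(expr = ), j),
                 rep(list(quote(expr = )), length(d) - 2),
                 list(drop = FALSE)))
}

flip_v <- function(x) index_rows(x, rev(seq_len(dim(x)[1])))
flip_h <- function(x) index_cols(x, rev(seq_len(dim(x)[2])))
rot_ccw <- function(x) flip_v(swap_hw(x))
rot_cw <- function(x) swap_hw(flip_v(x))

#' The test-time augmentation transform set
#'
#' Identity, the three quarter-turn rotations and the two axis flips; each
#' with its exact inverse (`inverse(transform(x))` is bit-identical to `x`).
#'
#' @return data.frame with columns `name` and `inverse`.
#' @export
tta_transforms <- function() {
  data.frame(name = c("identity", "rot90", "rot180", "rot270",
                      "hflip", "vflip"),
             inverse = c("identity", "rot270", "rot180", "rot90",
                         "hflip", "vflip"),
             stringsAsFactors = FALSE)
}

#' Apply (or invert) one TTA transform
#'
#' Operates on the first two (spatial) dimensions of a matrix or array.
#' Rotations are counter-clockwise.
#'
#' @param x matrix or array with spatial dims first.
#' @param name one of `tta_transforms()$name`.
#' @return transformed array.
#' @export
tta_apply <- function(x, name) {
  m <- is.null(dim(x))
  if (m) stop("expected a matrix or array")
  switch(name,
         identity = x,
         rot90 = rot_ccw(x),
         rot180 = flip_h(flip_v(x)),
         rot270 = rot_cw(x),
         hflip = flip_h(x),
         vflip = flip_v(x),
         stop("unknown TTA transform: ", name))
}

#' @rdname tta_apply
#' @export
tta_invert <- function(x, name) {
  tt <- tta_transforms()
  inv <- tt$inverse[match(name, tt$name)]
  if (is.na(inv)) stop("unknown TTA transform: ", name)
  tta_apply(x, inv)
}

#' Test-time-augmented prediction
#'
#' Runs the model on the six transformed copies of the image, inverts each
#' prediction exactly, and averages pixel-wise.
#'
#' @param model a [build_lesion_net()] model, or a function
#'   `image -> (H, W)` probability matrix (used for oracles in tests).
#' @param image `(H, W, 3)` array.
#' @return `(H, W)` matrix, the averaged segmentation probability map.
#' @export
predict_tta <- function(model, image) {
  predict_one <- function(img) {
    if (is.function(model)) return(model(img))
    p <- predict_probability(model, img)$seg
    matrix(p, dim(p)[1], dim(p)[2])
  }
  acc <- NULL
  for (nm in tta_transforms()$name) {
    p <- predict_one(tta_apply(image, nm))
    p <- tta_invert(p, nm)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / nrow(tta_transforms())
}

## ---- resampling core ------------------------------------------------------

# Sample image (H,W[,C]) at fractional source coords (same-length matrices
# sr, sc, 1-based); zero outside the frame.
sample_bilinear_at <- function(img, sr, sc) {
  d <- dim(img)
  H <- d[1]; W <- d[2]; C <- if (length(d) >= 3) d[3] else 1L
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  out <- matrix(0, length(sr), C)
  at <- function(rr, cc) {
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    idx <- (pmin(pmax(cc, 1), W) - 1) * H + pmin(pmax(rr, 1), H)
    vapply(seq_len(C), function(ch) {
      v <- img[idx + (ch - 1) * H * W]
      v[!ok] <- 0
      v
    }, numeric(length(rr)))
  }
  v00 <- at(r0, c0); v10 <- at(r0 + 1, c0)
  v01 <- at(r0, c0 + 1); v11 <- at(r0 + 1, c0 + 1)
  out <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out
}

sample_nearest_at <- function(m, sr, sc) {
  H <- nrow(m); W <- ncol(m)
  rr <- round(sr); cc <- round(sc)
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  v <- m[(pmin(pmax(cc, 1), W) - 1) * H + pmin(pmax(rr, 1), H)]
  v[!ok] <- 0
  v
}

# Resample an (image, mask) pair through one coordinate map.
resample_pair <- function(image, mask, sr, sc, out_h, out_w) {
  img <- sample_bilinear_at(image, sr, sc)
  out_img <- array(img, c(out_h, out_w, dim(image)[3]))
  out_mask <- matrix(sample_nearest_at(mask, sr, sc), out_h, out_w)
  list(image = out_img, mask = out_mask)
}

## ---- rigid moving least squares -------------------------------------------

# Rigid MLS deformation (similarity-constrained weighted least squares):
# maps query coords v to f(v) given handles p -> q, with weights
# w_i = 1 / |p_i - v|^2. Coordinates are (row, col) matrices.
mls_rigid_map <- function(p, q, vr, vc, eps = 1e-9) {
  k <- nrow(p)
  wsum <- 0; psr <- 0; psc <- 0; qsr <- 0; qsc <- 0
  wlist <- vector("list", k)
  for (i in seq_len(k)) {
    d2 <- (vr - p[i, 1])^2 + (vc - p[i, 2])^2
    w <- 1 / pmax(d2, eps)
    wlist[[i]] <- w
    wsum <- wsum + w
    psr <- psr + w * p[i, 1]; psc <- psc + w * p[i, 2]
    qsr <- qsr + w * q[i, 1]; qsc <- qsc + w * q[i, 2]
  }
  pstar_r <- psr / wsum; pstar_c <- psc / wsum
  qstar_r <- qsr / wsum; qstar_c <- qsc / wsum
  dr <- vr - pstar_r; dc <- vc - pstar_c
  fr_r <- 0; fr_c <- 0
  for (i in seq_len(k)) {
    ar <- p[i, 1] - pstar_r; ac <- p[i, 2] - pstar_c
    br <- q[i, 1] - qstar_r; bc <- q[i, 2] - qstar_c
    w <- wlist[[i]]
    # A_i = w * [[ar, ac], [ac, -ar]] %*% [[dr, dc], [dc, -dr]]
    a11 <- w * (ar * dr + ac * dc); a12 <- w * (ar * dc - ac * dr)
    a21 <- w * (ac * dr - ar * dc); a22 <- w * (ac * dc + ar * dr)
    fr_r <- fr_r + br * a11 + bc * a21
    fr_c <- fr_c + br * a12 + bc * a22
  }
  nrm <- sqrt(fr_r^2 + fr_c^2)
  len <- sqrt(dr^2 + dc^2)
  safe <- nrm > eps
  out_r <- ifelse(safe, len * fr_r / pmax(nrm, eps), 0) + qstar_r
  out_c <- ifelse(safe, len * fr_c / pmax(nrm, eps), 0) + qstar_c
  list(r = out_r, c = out_c)
}

#' Rigid moving-least-squares image deformation
#'
#' Deforms the image (and mask, with nearest-neighbour sampling) so that
#' each control point moves by its displacement. Per output pixel a rigid
#' (rotation + translation) transform is fitted by weighted least squares
#' to the control handles, with weights falling off as the inverse squared
#' distance; warping uses the exact backward map (handles reversed), so the
#' deformation interpolates the handles.
#'
#' @param image `(H, W, 3)` array.
#' @param mask `(H, W)` binary matrix.
#' @param control_points `k x 2` matrix of (row, col) handle positions,
#'   `k >= 3`.
#' @param displacements `k x 2` matrix of (row, col) handle displacements.
#' @return list with warped `image`, binary `mask`, and the coordinate map
#'   (`sr`, `sc`, source coords per output pixel).
#' @export
rigid_mls_warp <- function(image, mask, control_points, displacements) {
  if (is.null(nrow(control_points)) || nrow(control_points) < 3)
    stop("validation error: rigid MLS needs at least 3 control points")
  stopifnot(all(dim(control_points) == dim(displacements)))
  H <- dim(image)[1]; W <- dim(image)[2]
  vr <- matrix(rep(seq_len(H), W), H, W)
  vc <- matrix(rep(seq_len(W), each = H), H, W)
  if (all(displacements == 0)) {
    sr <- vr; sc <- vc
  } else {
    # backward map: deformed handle positions map back to the originals
    m <- mls_rigid_map(control_points + displacements, control_points,
                       as.numeric(vr), as.numeric(vc))
    sr <- matrix(m$r, H, W); sc <- matrix(m$c, H, W)
  }
  out <- resample_pair(image, mask, as.numeric(sr), as.numeric(sc), H, W)
  list(image = out$image, mask = out$mask, sr = sr, sc = sc)
}

## ---- train-time augmentation ----------------------------------------------

#' Default augmentation parameters
#'
#' @param hflip,vflip enable random flips (probability 0.5 each).
#' @param scale_range centre-crop scale range (crop side = scale * frame
#'   side; scales > 1 zero-pad).
#' @param rot_range rotation range in degrees.
#' @param gt_crop crop to the mask bounding box expanded by `gt_pad` pixels
#'   (zero-padded where the expansion leaves the frame).
#' @param gt_pad expansion of the ground-truth box, in source pixels.
#' @param mls enable the rigid moving-least-squares deformation.
#' @param mls_grid control-point grid side (grid x grid handles).
#' @param mls_disp_frac maximum handle displacement as a fraction of the
#'   image side.
#' @return list of augmentation parameters.
#' @export
augment_params <- function(hflip = TRUE, vflip = TRUE,
                           scale_range = c(0.75, 1.25),
                           rot_range = c(-20, 20),
                           gt_crop = TRUE, gt_pad = 50L,
                           mls = TRUE, mls_grid = 4L, mls_disp_frac = 0.05) {
  list(hflip = hflip, vflip = vflip, scale_range = scale_range,
       rot_range = rot_range, gt_crop = gt_crop, gt_pad = gt_pad,
       mls = mls, mls_grid = mls_grid, mls_disp_frac = mls_disp_frac)
}

#' Randomised train-time augmentation
#'
#' Draws one composition of horizontal/vertical flip, centre crop at a
#' random scale, random rotation, ground-truth-box crop with zero padding,
#' and a rigid MLS deformation; applies it through a single resampling
#' (bilinear for the image, nearest for the mask), resizes to `out_size`,
#' and re-derives the edge target from the transformed mask. Reproducible:
#' the same `rng_seed` yields bit-identical output.
#'
#' @param sample an [image_sample()].
#' @param rng_seed integer seed; `NULL` draws from the current RNG stream.
#' @param params an [augment_params()] list.
#' @param out_size output side in pixels.
#' @param edge_thickness edge band thickness for the re-derived target.
#' @return augmented `image_sample` of size `out_size`, with the applied
#'   transform parameters recorded in `$transforms`.
#' @export
augment_train <- function(sample, rng_seed = NULL, params = augment_params(),
                          out_size = 448L, edge_thickness = 2L) {
  stopifnot(inherits(sample, "image_sample"))
  if (!is.null(rng_seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(rng_seed)
  }
  H <- dim(sample$image)[1]; W <- dim(sample$image)[2]
  rec <- list()

  do_h <- isTRUE(params$hflip) && stats::runif(1) < 0.5
  do_v <- isTRUE(params$vflip) && stats::runif(1) < 0.5
  scl <- if (is.null(params$scale_range)) 1
         else stats::runif(1, params$scale_range[1], params$scale_range[2])
  ang <- if (is.null(params$rot_range)) 0
         else stats::runif(1, params$rot_range[1], params$rot_range[2])
  rec$hflip <- do_h; rec$vflip <- do_v; rec$scale <- scl; rec$angle <- ang

  # Backward affine: intermediate frame coord -> source coord, about centre.
  th <- ang * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)  # R(-theta)
  fl <- diag(c(if (do_v) -1 else 1, if (do_h) -1 else 1))
  M <- scl * (rot %*% fl)
  cen_r <- (H + 1) / 2; cen_c <- (W + 1) / 2
  to_source <- function(ir, ic) {
    dr <- ir - cen_r; dc <- ic - cen_c
    list(r = cen_r + M[1, 1] * dr + M[1, 2] * dc,
         c = cen_c + M[2, 1] * dr + M[2, 2] * dc)
  }

  # Ground-truth-box crop window in the intermediate frame.
  win <- c(1, 1, H, W)  # r0, c0, r1, c1 (may exceed frame -> zero pad)
  if (isTRUE(params$gt_crop)) {
    ir <- matrix(rep(seq_len(H), W), H, W)
    ic <- matrix(rep(seq_len(W), each = H), H, W)
    sm <- to_source(as.numeric(ir), as.numeric(ic))
    inter_mask <- matrix(sample_nearest_at(sample$mask, sm$r, sm$c), H, W)
    if (any(inter_mask > 0)) {
      rows <- range(which(rowSums(inter_mask) > 0))
      cols <- range(which(colSums(inter_mask) > 0))
      pad <- params$gt_pad
      win <- c(rows[1] - pad, cols[1] - pad, rows[2] + pad, cols[2] + pad)
    } else {
      rec$gt_crop_skipped <- TRUE
      message("augment_train: empty mask, ground-truth crop skipped")
    }
  }
  rec$window <- win

  # Fast path: when the draw degenerates to pure axis flips at native size,
  # index flips reproduce the resampled result bit-exactly (the bilinear
  # weights are all at integer coordinates) at a fraction of the cost.
  S <- as.integer(out_size)
  if (scl == 1 && ang == 0 && !isTRUE(params$mls) &&
      identical(win, c(1, 1, H, W)) && S == H && S == W) {
    img <- sample$image
    msk <- sample$mask
    if (do_v) { img <- flip_v(img); msk <- flip_v(msk) }
    if (do_h) { img <- flip_h(img); msk <- flip_h(msk) }
    return(image_sample(img, matrix(msk, S, S),
                        edge_thickness = edge_thickness,
                        transforms = c(sample$transforms, list(rec))))
  }

  # Output grid -> window -> (MLS) -> affine -> source, one resampling.
  wh <- win[3] - win[1] + 1; ww <- win[4] - win[2] + 1
  og_r <- matrix(rep(seq_len(S), S), S, S)
  og_c <- matrix(rep(seq_len(S), each = S), S, S)
  ir <- win[1] - 0.5 + (as.numeric(og_r) - 0.5) * wh / S
  ic <- win[2] - 0.5 + (as.numeric(og_c) - 0.5) * ww / S

  if (isTRUE(params$mls)) {
    g <- params$mls_grid
    side <- max(H, W)
    gr <- seq(win[1], win[3], length.out = g)
    gc <- seq(win[2], win[4], length.out = g)
    cp <- cbind(rep(gr, each = g), rep(gc, g))
    disp <- matrix(stats::runif(2 * g * g, -1, 1) * params$mls_disp_frac * side,
                   ncol = 2)
    rec$mls_displacements <- disp
    m <- mls_rigid_map(cp + disp, cp, ir, ic)
    ir <- m$r; ic <- m$c
  }

  sm <- to_source(ir, ic)
  out <- resample_pair(sample$image, sample$mask, sm$r, sm$c, S, S)
  image_sample(out$image, out$mask, edge_thickness = edge_thickness,
               transforms = c(sample$transforms, list(rec)))
}

#' Plain resize of a sample (no randomness)
#'
#' @param sample an [image_sample()].
#' @param out_size output side in pixels.
#' @param edge_thickness edge band thickness for the re-derived target.
#' @return resized `image_sample`.
#' @export
resize_sample <- function(sample, out_size, edge_thickness = 2L) {
  H <- dim(sample$image)[1]; W <- dim(sample$image)[2]
  S <- as.integer(out_size)
  og_r <- rep(seq_len(S), S); og_c <- rep(seq_len(S), each = S)
  sr <- 0.5 + (og_r - 0.5) * H / S
  sc <- 0.5 + (og_c - 0.5) * W / S
  out <- resample_pair(sample$image, sample$mask, sr, sc, S, S)
  image_sample(out$image, out$mask, edge_thickness = edge_thickness,
               transforms = c(sample$transforms,
                              list(list(resize_to = S))))
}
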