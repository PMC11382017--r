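#' Visible-band Difference Vegetation Index
#'
#' VDVI = (2G - R - B) / (2G + R + B), computed per pixel in floating point.
#' High for green vegetation, at or below zero for typical soil. A pixel with
#' R = G = B = 0 has a zero denominator; by convention its VDVI is defined as
#' 0 (and such pixels are never classed as vegetation by
#' [vegetation_mask()]).
#'
#' @param rgb either an `H x W x 3` array or a length-3 numeric `(R, G, B)`.
#' @return Matrix (or scalar) of VDVI values in \[-1, 1\].
#' @export
#' @examples
#' vdvi(c(50, 100, 30)) # 120/280
vdvi <- function(rgb) {
  if (is.null(dim(rgb))) {
    stopifnot(length(rgb) == 3)
    rgb <- array(rgb, dim = c(1, 1, 3))
    drop_out <- TRUE
  } else drop_out <- FALSE
  R <- rgb[, , 1] * 1.0; G <- rgb[, , 2] * 1.0; B <- rgb[, , 3] * 1.0
  num <- 2 * G - R - B
  den <- 2 * G + R + B
  out <- ifelse(den > 0, num / den, 0)
  if (drop_out) as.numeric(out) else out
}

#' Segment vegetation by VDVI threshold and dark-pixel removal
#'
#' A pixel is vegetation when its VDVI exceeds `threshold` and its green
#' component is at least `min_green` (near-black pixels are removed even when
#' their VDVI is high). The published defaults are a VDVI threshold of 0.057
#' and a green floor of 10. Plots with an empty mask are flagged for
#' downstream exclusion.
#'
#' @param rgb `H x W x 3` image array.
#' @param threshold VDVI threshold (default 0.057).
#' @param min_green minimum 8-bit green component (default 10).
#' @return List with `mask` (logical H x W), `count` (vegetation pixels), and
#'   `excluded` (`TRUE` when the mask is empty).
#' @export
vegetation_mask <- function(rgb, threshold = 0.057, min_green = 10) {
  v <- vdvi(rgb)
  mask <- (v > threshold) & (rgb[, , 2] >= min_green) &
    (rgb[, , 1] + rgb[, , 2] + rgb[, , 3] > 0)
  list(mask = mask, count = sum(mask), excluded = !any(mask))
}

#' Overlap between two binary masks
#'
#' Jaccard index |A intersect B| / |A union B|; 1 for identical non-empty
#' masks, `NA` when both are empty.
#' @param a,b logical matrices of equal size.
#' @export
mask_overlap <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Align, mask, and pad a plot image pair to a standard size
#'
#' Rigid alignment: the vegetation-mask centroid is translated to the image
#' center and the mask's principal axis (second central moments) is rotated
#' to horizontal; the identical transform is applied to RGB, DSM, and mask by
#' nearest-neighbour inverse mapping, then the canvas is zero-padded/cropped
#' to `target_h x target_w`. Off-mask RGB is black; the DSM has the median
#' off-mask (soil) height subtracted first — yielding canopy height above
#' local ground — and off-mask DSM is set to 0. Near-isotropic masks skip the
#' rotation (the principal axis is undefined).
#'
#' @param pair a `plot_image_pair` whose `mask` field holds the vegetation
#'   mask to align on (see [vegetation_mask()]).
#' @param target_h,target_w output size in pixels.
#' @param rotate set `FALSE` for translation-only alignment.
#' @return A `plot_image_pair` of the target size.
#' @export
standardize_geometry <- function(pair, target_h, target_w, rotate = TRUE) {
  mask <- pair$mask
  if (!any(mask)) stop("empty vegetation mask for plot ", pair$plot_id)
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  theta <- 0
  if (rotate && nrow(idx) > 2) {
    dy <- idx[, 1] - cy; dx <- idx[, 2] - cx
    mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
    aniso <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    if (aniso > 1e-6 * (mu20 + mu02)) theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  }

  # warn if the aligned canopy cannot fit the target canvas
  rot_x <- (idx[, 2] - cx) * cos(-theta) - (idx[, 1] - cy) * sin(-theta)
  rot_y <- (idx[, 2] - cx) * sin(-theta) + (idx[, 1] - cy) * cos(-theta)
  if (diff(range(rot_x)) > target_w || diff(range(rot_y)) > target_h)
    warning("canopy larger than target canvas for plot ", pair$plot_id,
            "; center-cropping")

  ground <- median(pair$dsm[!mask])
  if (!is.finite(ground)) ground <- 0

  oy <- matrix(seq_len(target_h), target_h, target_w) - (target_h + 1) / 2
  ox <- matrix(seq_len(target_w), target_h, target_w, byrow = TRUE) -
    (target_w + 1) / 2
  # inverse map: rotate output offsets by +theta back into input coordinates;
  # floor(x + 0.5) rounds half-pixel offsets consistently upward so a pure
  # translation of the input reproduces the identical output
  sx <- floor(cx + ox * cos(theta) - oy * sin(theta) + 0.5)
  sy <- floor(cy + ox * sin(theta) + oy * cos(theta) + 0.5)
  inb <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  lin <- (pmin(pmax(sx, 1), W) - 1) * H + pmin(pmax(sy, 1), H)

  samp <- function(m, fill = 0) {
    out <- matrix(fill, target_h, target_w)
    out[inb] <- m[lin[inb]]
    out
  }
  new_mask <- samp(mask) > 0
  rgb <- array(0L, dim = c(target_h, target_w, 3))
  for (ch in 1:3) {
    v <- samp(pair$rgb[, , ch])
    v[!new_mask] <- 0L
    rgb[, , ch] <- as.integer(v)
  }
  dsm <- samp(pair$dsm - ground)
  dsm[!new_mask] <- 0
  structure(list(rgb = rgb, dsm = dsm, mask = new_mask,
                 plot_id = pair$plot_id, traits = pair$traits),
            class = "plot_image_pair")
}

flip_pair <- function(pair, vflip, hflip) {
  f <- function(m) {
    if (vflip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (hflip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    m
  }
  rgb <- pair$rgb
  for (ch in 1:3) rgb[, , ch] <- f(pair$rgb[, , ch])
  out <- pair
  out$rgb <- rgb
  out$dsm <- f(pair$dsm)
  out$mask <- f(pair$mask)
  out
}

#' Flip-based data augmentation
#'
#' For each input pair returns the identity, vertical flip, horizontal flip,
#' and double flip — quadrupling the dataset. Flips are applied consistently
#' to RGB, DSM, and mask; any attached trait labels are carried unchanged.
#'
#' @param pairs list of `plot_image_pair` (a single pair is accepted).
#' @return List of `4 * length(pairs)` pairs, ordered input-major.
#' @export
augment <- function(pairs) {
  if (inherits(pairs, "plot_image_pair")) pairs <- list(pairs)
  out <- vector("list", 4 * length(pairs))
  flips <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  for (i in seq_along(pairs)) {
    for (j in 1:4) {
      p <- flip_pair(pairs[[i]], flips[[j]][1], flips[[j]][2])
      p$augmentation <- c("identity", "vflip", "hflip", "vhflip")[j]
      out[[(i - 1) * 4 + j]] <- p
    }
  }
  out
}

#' Z-score normalization of trait measurements
#'
#' Per-trait mean and SD are computed on `fit_rows` only and applied to every
#' row, so held-out plots can be normalized with training statistics. The
#' stored statistics make the transform exactly invertible via
#' [denormalize_traits()].
#'
#' @param raw plot x trait numeric matrix (or data frame of the five trait
#'   columns).
#' @param fit_rows integer or logical index of rows used to fit the
#'   statistics (default: all rows).
#' @return A `trait_table`: list with `raw`, `normalized`, `norm_mean`,
#'   `norm_sd`, `fit_rows`.
#' @export
normalize_traits <- function(raw, fit_rows = seq_len(nrow(raw))) {
  raw <- as.matrix(raw)
  if (length(fit_rows) == 0 || (is.logical(fit_rows) && !any(fit_rows)))
    stop("fit_rows must be non-empty")
  mu <- colMeans(raw[fit_rows, , drop = FALSE])
  sdv <- apply(raw[fit_rows, , drop = FALSE], 2, sd)
  if (any(sdv == 0))
    stop("zero variance on fitting rows for trait(s): ",
         paste(colnames(raw)[sdv == 0], collapse = ", "))
  normalized <- sweep(sweep(raw, 2, mu), 2, sdv, `/`)
  structure(list(raw = raw, normalized = normalized,
                 norm_mean = mu, norm_sd = sdv, fit_rows = fit_rows),
            class = "trait_table")
}

#' @rdname normalize_traits
#' @param table a `trait_table`.
#' @param normalized matrix on the normalized scale to map back.
#' @export
denormalize_traits <- function(table, normalized = table$normalized) {
  sweep(sweep(as.matrix(normalized), 2, table$norm_sd, `*`), 2,
        table$norm_mean, `+`)
}

#' Preprocess a synthetic field into a model-ready dataset
#'
#' Runs the full published preprocessing chain on every rendered plot:
#' vegetation segmentation ([vegetation_mask()]), rigid alignment and
#' padding ([standardize_geometry()]), and trait z-score normalization
#' (pooled across treatments by default). Plots with an empty vegetation mask
#' are excluded, mirroring the manual removal of failed plots.
#'
#' @param field an `lsp_field` from [simulate_field()].
#' @param target_h,target_w standardized image size (defaults: the field's
#'   render size).
#' @param threshold,min_green segmentation parameters.
#' @return An `lsp_dataset`: list with `rgb` (`H x W x 3 x N` array scaled to
#'   \[0, 1\]), `dsm` (`H x W x N`, meters), `mask` (`H x W x N` logical),
#'   `meta` (plot metadata), `traits` (a `trait_table`), `excluded`
#'   (character plot ids), `dsm_scale` (height used to scale DSM inputs).
#' @export
prepare_dataset <- function(field, target_h = field$cfg$image_height,
                            target_w = field$cfg$image_width,
                            threshold = 0.057, min_green = 10) {
  stopifnot(inherits(field, "lsp_field"), !is.null(field$images))
  keep <- character(); pairs <- list()
  for (pid in names(field$images)) {
    img <- field$images[[pid]]
    vm <- vegetation_mask(img$rgb, threshold, min_green)
    if (vm$excluded) next
    img$mask <- vm$mask
    pairs[[pid]] <- standardize_geometry(img, target_h, target_w)
    keep <- c(keep, pid)
  }
  if (length(keep) == 0) stop("all plots excluded: no vegetation found")
  meta <- field$plots[match(keep, field$plots$plot_id), , drop = FALSE]
  n <- length(keep)
  rgb <- array(0, dim = c(target_h, target_w, 3, n))
  dsm <- array(0, dim = c(target_h, target_w, n))
  msk <- array(FALSE, dim = c(target_h, target_w, n))
  for (i in seq_len(n)) {
    rgb[, , , i] <- pairs[[i]]$rgb / 255
    dsm[, , i] <- pairs[[i]]$dsm
    msk[, , i] <- pairs[[i]]$mask
  }
  traits <- normalize_traits(as.matrix(meta[, TRAITS]))
  structure(list(rgb = rgb, dsm = dsm, mask = msk, meta = meta,
                 traits = traits,
                 excluded = setdiff(field$plots$plot_id, keep),
                 dsm_scale = max(dsm, 1e-6)),
            class = "lsp_dataset")
}
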