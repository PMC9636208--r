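#' Segmentation configuration
#'
#' All tunable constants of the automated collagen segmentation. Spatial
#' cleanup parameters are specified in micrometres (or square micrometres)
#' and converted to pixels per slide, so the segmentation behaves identically
#' on 20X (0.452 um/px) and 40X (0.226 um/px) scans of the same section.
#'
#' @param eps_intensity floor for the log argument of the optical density,
#'   on the 0-255 intensity scale.
#' @param background_percentile percentile (in (50, 100\]) of each channel
#'   used to estimate the incident (glass) intensity I0.
#' @param od_tissue_threshold pixels whose OD L2 norm is at or above this are
#'   tissue candidates.
#' @param morph_close_radius_um disc radius of the morphological closing
#'   applied to the tissue mask.
#' @param min_component_um2 tissue components smaller than this are dropped.
#' @param hole_fill_um2 holes in tissue up to this area are filled; larger
#'   holes (vessel lumina) stay open.
#' @param collagen_threshold global threshold on the third-singular-vector
#'   projection; held fixed across all slides of a study. The default was
#'   calibrated once, by maximising IoU against ground truth on a synthetic
#'   calibration set (see the methods vignette), and is not adapted per
#'   slide.
#' @param subsample_stride pixel stride (per dimension) when accumulating the
#'   OD Gram matrix; 1 uses every tissue pixel.
#' @param tile_px tile side for the per-tile projection pass. Results are
#'   independent of the tile size: all statistics entering the segmentation
#'   (I0, tissue mask, stain basis) are global.
#' @return An object of class `seg_config`.
#' @export
segmentation_config <- function(eps_intensity = 0.5,
                                background_percentile = 99,
                                od_tissue_threshold = 0.08,
                                morph_close_radius_um = 2,
                                min_component_um2 = 60,
                                hole_fill_um2 = 150,
                                collagen_threshold = 0.05,
                                subsample_stride = 1L,
                                tile_px = 2048L) {
  stopifnot(eps_intensity > 0, background_percentile > 50,
            background_percentile <= 100, od_tissue_threshold > 0,
            morph_close_radius_um >= 0, min_component_um2 >= 0,
            hole_fill_um2 >= 0, is.finite(collagen_threshold),
            subsample_stride >= 1, tile_px >= 1)
  structure(list(eps_intensity = eps_intensity,
                 background_percentile = background_percentile,
                 od_tissue_threshold = od_tissue_threshold,
                 morph_close_radius_um = morph_close_radius_um,
                 min_component_um2 = min_component_um2,
                 hole_fill_um2 = hole_fill_um2,
                 collagen_threshold = collagen_threshold,
                 subsample_stride = as.integer(subsample_stride),
                 tile_px = as.integer(tile_px)),
            class = "seg_config")
}

#' Estimate incident (background) intensity
#'
#' Per-channel high percentile of the whole raster, clamped to at least 1.
#' On a PSR slide the brightest percentiles are clean glass, so this is
#' robust to dust and to slides that are mostly tissue.
#'
#' @param slide a [wsi].
#' @param cfg a [segmentation_config].
#' @return Numeric RGB triplet I0.
#' @export
estimate_background <- function(slide, cfg = segmentation_config()) {
  stopifnot(inherits(slide, "wsi"))
  p <- cfg$background_percentile / 100
  I0 <- vapply(1:3, function(ch)
    stats::quantile(slide$pixels[, , ch], p, names = FALSE, type = 7),
    numeric(1))
  pmax(I0, 1)
}

#' Optical density (absorbance) transform
#'
#' `OD_c = log10(I0_c / max(I_c, eps))` per channel: the Beer-Lambert
#' absorbance, which is linear in stain concentration. Accepts a length-3
#' vector, an N x 3 matrix, or an h x w x 3 array; returns the same shape.
#'
#' @param rgb intensities on the 0-255 scale.
#' @param I0 incident intensity triplet (channels >= 1).
#' @param eps positive floor for the log argument.
#' @return Optical densities, same shape as `rgb`.
#' @export
to_optical_density <- function(rgb, I0, eps = 0.5) {
  stopifnot(all(I0 >= 1), eps > 0)
  if (is.null(dim(rgb))) {
    stopifnot(length(rgb) == 3L)
    return(log10(I0 / pmax(rgb, eps)))
  }
  d <- dim(rgb)
  if (length(d) == 2L) {
    stopifnot(d[2] == 3L)
    out <- log10(matrix(I0, d[1], 3L, byrow = TRUE) / pmax(rgb, eps))
  } else {
    stopifnot(d[3] == 3L)
    out <- array(0, dim = d)
    for (ch in 1:3) out[, , ch] <- log10(I0[ch] / pmax(rgb[, , ch], eps))
  }
  out
}

## logical matrix -> EBImage and back (EBImage stores x = first dim)
.as_ebi <- function(m) EBImage::Image(t(m))
.from_ebi <- function(img) t(EBImage::imageData(img)) > 0.5

## drop connected components below min_px; fill holes up to max_hole_px
.clean_mask <- function(mask, close_radius_px, min_px, max_hole_px) {
  if (close_radius_px >= 1) {
    sz <- 2L * floor(close_radius_px) + 1L
    mask <- .from_ebi(EBImage::closing(.as_ebi(mask),
                                       EBImage::makeBrush(sz, "disc")))
  }
  if (max_hole_px > 0 && any(mask)) {
    filled <- .from_ebi(EBImage::fillHull(.as_ebi(mask)))
    holes <- filled & !mask
    if (any(holes)) {
      lab <- EBImage::bwlabel(.as_ebi(holes))
      sizes <- tabulate(as.integer(lab))
      keep <- which(sizes <= max_hole_px)          # small holes get filled
      if (length(keep)) {
        hm <- t(as.matrix(lab))
        mask[hm %in% keep] <- TRUE
      }
    }
  }
  if (min_px > 0 && any(mask)) {
    lab <- EBImage::bwlabel(.as_ebi(mask))
    sizes <- tabulate(as.integer(lab))
    drop <- which(sizes < min_px)
    if (length(drop)) {
      lm <- t(as.matrix(lab))
      mask[lm %in% drop] <- FALSE
    }
  }
  mask
}

#' Delineate the tissue area of a slide
#'
#' A pixel is a tissue candidate when the L2 norm of its OD vector reaches
#' `od_tissue_threshold`; the candidate mask is then closed with a disc of
#' radius `morph_close_radius_um`, holes up to `hole_fill_um2` are filled
#' (larger lumina stay open), and components below `min_component_um2` are
#' removed. An empty result (blank slide) is returned as-is, with a message.
#'
#' @param slide a [wsi].
#' @param I0 background triplet from [estimate_background].
#' @param cfg a [segmentation_config].
#' @return Logical matrix `height x width`.
#' @export
delineate_tissue <- function(slide, I0, cfg = segmentation_config()) {
  stopifnot(inherits(slide, "wsi"))
  um <- slide$um_per_pixel
  px_area_um2 <- um^2
  od <- to_optical_density(slide$pixels, I0, cfg$eps_intensity)
  nrm <- sqrt(od[, , 1]^2 + od[, , 2]^2 + od[, , 3]^2)
  mask <- nrm >= cfg$od_tissue_threshold
  mask <- .clean_mask(mask,
                      close_radius_px = cfg$morph_close_radius_um / um,
                      min_px = cfg$min_component_um2 / px_area_um2,
                      max_hole_px = cfg$hole_fill_um2 / px_area_um2)
  if (!any(mask)) message("delineate_tissue: no tissue detected (blank slide?)")
  mask
}

#' Stain basis from SVD of the tissue OD cloud
#'
#' Right singular vectors of the (uncentered) N x 3 matrix of OD vectors of
#' tissue pixels, with singular values in descending order. Computed from the
#' 3 x 3 Gram matrix accumulated over fixed row strips in one pass, so the
#' result does not depend on the processing tile size. The third vector v3 is
#' the least-variance axis of the tissue OD cloud; on PSR sections the
#' sirius-red collagen contrast loads on it. Its sign is fixed so that the OD
#' of `sign_reference` (default pure red) projects nonnegatively; v1 and v2
#' signs are fixed by making their largest-magnitude component positive.
#'
#' @param slide a [wsi].
#' @param tissue_mask logical matrix from [delineate_tissue].
#' @param I0 background triplet.
#' @param cfg a [segmentation_config]; `subsample_stride` thins the pixels
#'   entering the Gram matrix deterministically.
#' @param sign_reference RGB triplet used to orient v3.
#' @param min_pixels refuse to fit on fewer tissue pixels than this. The
#'   whole-slide pipeline keeps the default of 1000; smaller floors are
#'   useful for controlled numerical comparisons.
#' @return An object of class `stain_basis`: `V` (3 x 3, columns v1..v3),
#'   `s` (singular values), `sign_reference`.
#' @export
fit_stain_axes <- function(slide, tissue_mask, I0,
                           cfg = segmentation_config(),
                           sign_reference = c(255, 0, 0),
                           min_pixels = 1000L) {
  stopifnot(inherits(slide, "wsi"), is.logical(tissue_mask),
            all(dim(tissue_mask) == dim(slide$pixels)[1:2]))
  h <- slide$height_px
  stride <- cfg$subsample_stride
  sub <- tissue_mask
  if (stride > 1L) {
    keep_r <- (seq_len(nrow(sub)) - 1L) %% stride == 0L
    keep_c <- (seq_len(ncol(sub)) - 1L) %% stride == 0L
    sub <- sub & outer(keep_r, keep_c)
  }
  n <- sum(sub)
  if (n < min_pixels)
    stop("too few tissue pixels for stain estimation (", n,
         " after stride subsampling; need >= ", min_pixels, ")")
  ## accumulate the Gram matrix over fixed 512-row strips
  G <- matrix(0, 3, 3)
  strip <- 512L
  for (r0 in seq.int(1L, h, by = strip)) {
    r1 <- min(r0 + strip - 1L, h)
    sel <- sub[r0:r1, , drop = FALSE]
    if (!any(sel)) next
    odm <- cbind(slide$pixels[r0:r1, , 1][sel],
                 slide$pixels[r0:r1, , 2][sel],
                 slide$pixels[r0:r1, , 3][sel])
    odm <- to_optical_density(odm, I0, cfg$eps_intensity)
    G <- G + crossprod(odm)
  }
  e <- eigen(G, symmetric = TRUE)
  V <- e$vectors
  s <- sqrt(pmax(e$values, 0))
  for (j in 1:2) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  od_ref <- to_optical_density(as.numeric(sign_reference), I0, cfg$eps_intensity)
  if (sum(od_ref * V[, 3]) < 0) V[, 3] <- -V[, 3]
  structure(list(V = V, s = s, sign_reference = as.numeric(sign_reference)),
            class = "stain_basis")
}

#' @export
print.stain_basis <- function(x, ...) {
  cat("<stain_basis> singular values:", signif(x$s, 6), "\n")
  cat("v3:", signif(x$V[, 3], 4), "\n")
  invisible(x)
}

#' Project OD vectors on the third singular vector
#'
#' Signed scalar projection `od . v3`. The red collagen signal projects
#' positively (by the basis sign convention); counterstained parenchyma
#' projects near zero.
#'
#' @param od length-3 vector, N x 3 matrix, or h x w x 3 array of ODs.
#' @param basis a `stain_basis`.
#' @return Scalar, vector, or matrix of projections matching the input.
#' @export
project_third_axis <- function(od, basis) {
  stopifnot(inherits(basis, "stain_basis"))
  v3 <- basis$V[, 3]
  if (is.null(dim(od))) return(sum(od * v3))
  d <- dim(od)
  if (length(d) == 2L) return(as.numeric(od %*% v3))
  od[, , 1] * v3[1] + od[, , 2] * v3[2] + od[, , 3] * v3[3]
}

#' Threshold the projection into a collagen mask
#'
#' A pixel is collagen iff it is tissue and its third-axis projection is at
#' or above the (global, study-wide) threshold. The returned mask is nested
#' in the tissue mask by construction.
#'
#' @param projection numeric matrix of third-axis projections.
#' @param tissue_mask logical matrix.
#' @param threshold finite numeric.
#' @return Logical matrix.
#' @export
threshold_collagen <- function(projection, tissue_mask, threshold) {
  stopifnot(is.finite(threshold), all(dim(projection) == dim(tissue_mask)))
  tissue_mask & (projection >= threshold)
}

#' Segment a PSR slide into tissue and collagen
#'
#' The full automated pipeline, in two passes. Pass 1 computes the global
#' statistics: background I0, the tissue mask, and the stain basis (SVD of
#' the tissue OD cloud). Pass 2 walks the slide tile by tile, projects each
#' pixel's OD on the third singular vector and applies the global collagen
#' threshold. The pipeline is a pure function of the pixel data and the
#' configuration: repeated runs are bit-identical, and because every
#' statistic is global, the result does not depend on `tile_px`.
#'
#' @param slide a [wsi].
#' @param cfg a [segmentation_config].
#' @return An object of class `segmentation_result`: `tissue_mask`,
#'   `collagen_mask` (nested), `basis`, `background_I0`, `tissue_px`,
#'   `collagen_px`.
#' @export
segment_slide <- function(slide, cfg = segmentation_config()) {
  stopifnot(inherits(slide, "wsi"), inherits(cfg, "seg_config"))
  I0 <- estimate_background(slide, cfg)
  tissue <- delineate_tissue(slide, I0, cfg)
  if (!any(tissue)) {
    return(structure(list(tissue_mask = tissue,
                          collagen_mask = tissue,
                          basis = NULL, background_I0 = I0,
                          tissue_px = 0L, collagen_px = 0L),
                     class = "segmentation_result"))
  }
  basis <- fit_stain_axes(slide, tissue, I0, cfg)
  collagen <- matrix(FALSE, slide$height_px, slide$width_px)
  tiles <- iter_tiles(slide, cfg$tile_px)
  for (i in seq_len(nrow(tiles))) {
    rr <- (tiles$y0[i] + 1L):tiles$y1[i]
    cc <- (tiles$x0[i] + 1L):tiles$x1[i]
    tsub <- tissue[rr, cc, drop = FALSE]
    if (!any(tsub)) next
    od <- to_optical_density(slide$pixels[rr, cc, , drop = FALSE], I0,
                             cfg$eps_intensity)
    proj <- project_third_axis(od, basis)
    collagen[rr, cc] <- threshold_collagen(proj, tsub, cfg$collagen_threshold)
  }
  structure(list(tissue_mask = tissue, collagen_mask = collagen,
                 basis = basis, background_I0 = I0,
                 tissue_px = sum(tissue), collagen_px = sum(collagen)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> tissue %d px, collagen %d px (CPA %.3f%%)\n",
              x$tissue_px, x$collagen_px,
              if (x$tissue_px > 0) 100 * x$collagen_px / x$tissue_px else NA))
  invisible(x)
}

#' Calibrate the global collagen threshold on slides with ground truth
#'
#' Scans a threshold grid and returns the value maximising the mean
#' intersection-over-union between the segmented collagen mask and the
#' ground-truth mask across the supplied synthetic slides. Used once to fix
#' the study-wide default; not applied per slide.
#'
#' @param slides list of [synthetic_slide].
#' @param thresholds numeric grid to scan.
#' @param cfg base [segmentation_config] (its `collagen_threshold` is ignored).
#' @return list with `threshold` (best value) and `iou` (grid of mean IoU).
#' @export
calibrate_collagen_threshold <- function(slides,
                                         thresholds = seq(0.02, 0.12, by = 0.005),
                                         cfg = segmentation_config()) {
  stopifnot(length(slides) >= 1)
  ious <- matrix(NA_real_, length(slides), length(thresholds))
  for (i in seq_along(slides)) {
    sl <- slides[[i]]
    I0 <- estimate_background(sl$image, cfg)
    tissue <- delineate_tissue(sl$image, I0, cfg)
    basis <- fit_stain_axes(sl$image, tissue, I0, cfg)
    od <- to_optical_density(sl$image$pixels, I0, cfg$eps_intensity)
    proj <- project_third_axis(od, basis)
    truth <- sl$collagen_truth
    for (j in seq_along(thresholds)) {
      m <- threshold_collagen(proj, tissue, thresholds[j])
      ious[i, j] <- sum(m & truth) / max(sum(m | truth), 1L)
    }
  }
  mi <- colMeans(ious)
  list(threshold = thresholds[which.max(mi)],
       iou = stats::setNames(mi, thresholds))
}
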