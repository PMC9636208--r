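#' Parameters for a synthetic PSR slide
#'
#' Describes one synthetic picrosirius-red-like liver section: raster size,
#' physical pixel size, fibrosis pattern and target collagen proportionate
#' area, plus the color model. Colors are given as rendered 8-bit RGB at
#' reference stain concentration; the generator works in optical density, so
#' collagen is laid down as a sirius-red absorbance contrast over the
#' picric-yellow parenchyma background rather than as a flat fill.
#'
#' @param width_px,height_px raster size in pixels.
#' @param um_per_pixel physical pixel size (micrometres per pixel). 0.452
#'   corresponds to a 20X scan, 0.226 to 40X.
#' @param pattern `"septal"` (random-walk bridging bands, CCl4-like),
#'   `"perisinusoidal"` (thin chicken-wire strands, steatohepatitis-like) or
#'   `"none"`.
#' @param target_cpa target collagen proportionate area, percent in \[0, 100\].
#'   The achieved ground-truth CPA lands within 1.5 percentage points.
#' @param glass_level background (glass) RGB triplet.
#' @param collagen_color rendered collagen RGB at reference concentration.
#' @param parenchyma_color rendered counterstained parenchyma RGB.
#' @param color_jitter_sd per-pixel RGB stain texture SD (applied before the
#'   optical point-spread blur).
#' @param noise_sd per-pixel RGB sensor noise SD (applied after the blur).
#' @param seed integer; fully determines the slide.
#' @return An object of class `slide_gen_params`.
#' @export
slide_gen_params <- function(width_px = 1024, height_px = 1024,
                             um_per_pixel = 0.452,
                             pattern = c("septal", "perisinusoidal", "none"),
                             target_cpa = 5,
                             glass_level = c(245, 245, 245),
                             collagen_color = c(205, 125, 85),
                             parenchyma_color = c(200, 150, 60),
                             color_jitter_sd = 3, noise_sd = 2, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(width_px >= 64, height_px >= 64, um_per_pixel > 0,
            target_cpa >= 0, target_cpa <= 100,
            color_jitter_sd >= 0, noise_sd >= 0)
  for (col in list(glass_level, collagen_color, parenchyma_color))
    if (length(col) != 3L || any(col < 0) || any(col > 255))
      stop("colors must be RGB triplets in 0..255")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 um_per_pixel = um_per_pixel, pattern = pattern,
                 target_cpa = target_cpa,
                 glass_level = as.numeric(glass_level),
                 collagen_color = as.numeric(collagen_color),
                 parenchyma_color = as.numeric(parenchyma_color),
                 color_jitter_sd = color_jitter_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "slide_gen_params")
}

## Run `expr` under a private, seeded RNG stream; restores the caller's RNG.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

## Smooth Gaussian random field, h x w, correlation length ~scale_px,
## exact N(0,1) pixel marginals (bilinear upsample of an iid coarse grid,
## renormalised by the positionwise bilinear variance factor).
.smooth_field <- function(h, w, scale_px) {
  scale_px <- max(scale_px, 1)
  nyc <- ceiling((h - 1) / scale_px) + 2L
  nxc <- ceiling((w - 1) / scale_px) + 2L
  z <- matrix(rnorm(nyc * nxc), nyc, nxc)
  gy <- (seq_len(h) - 1) / scale_px + 1
  gx <- (seq_len(w) - 1) / scale_px + 1
  iy <- pmin(floor(gy), nyc - 1L); fy <- gy - iy
  ix <- pmin(floor(gx), nxc - 1L); fx <- gx - ix
  zx <- z[, ix] * rep(1 - fx, each = nyc) + z[, ix + 1L] * rep(fx, each = nyc)
  fld <- zx[iy, ] * (1 - fy) + zx[iy + 1L, ] * fy
  vy <- (1 - fy)^2 + fy^2
  vx <- (1 - fx)^2 + fx^2
  fld / sqrt(outer(vy, vx))
}

## Smoothed random-polygon tissue silhouette with optional vessel lumina.
## Returns a logical h x w matrix.
.tissue_silhouette <- function(h, w, um_per_pixel) {
  cy <- h / 2 + runif(1, -0.04, 0.04) * h
  cx <- w / 2 + runif(1, -0.04, 0.04) * w
  r0 <- 0.40 * min(h, w)
  kmax <- 6L
  a <- rnorm(kmax, 0, 0.07 / seq_len(kmax))
  b <- rnorm(kmax, 0, 0.07 / seq_len(kmax))
  tot <- sum(abs(a)) + sum(abs(b))
  if (tot > 0.18) { a <- a * 0.18 / tot; b <- b * 0.18 / tot }
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  th <- atan2(yy, xx)
  r <- r0
  for (k in seq_len(kmax)) r <- r + r0 * (a[k] * cos(k * th) + b[k] * sin(k * th))
  tis <- (yy^2 + xx^2) < r^2
  ## vessel lumina: a few circular holes, radii 10-20 um (larger than the
  ## segmenter's default hole-fill area, so they stay open in the truth)
  for (i in seq_len(rpois(1, 1.5))) {
    ang <- runif(1, 0, 2 * pi); d <- runif(1, 0.1, 0.5) * r0
    ly <- cy + d * sin(ang); lx <- cx + d * cos(ang)
    lr <- runif(1, 10, 20) / um_per_pixel
    sel <- (yy + cy - ly)^2 + (xx + cx - lx)^2 < lr^2
    tis[sel] <- FALSE
  }
  tis
}

## Pixel (row, col) index pairs of a disc of radius r around integer centres.
.disc_offsets <- function(r) {
  ri <- max(0L, floor(r))
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

## Stamp a wobbly band between two points into `collagen`, clipped to
## `tissue`. Returns the updated mask and the count of newly set pixels.
.stamp_band <- function(collagen, tissue, p0, p1, width_px, um_per_pixel,
                        wobble = TRUE) {
  h <- nrow(collagen); w <- ncol(collagen)
  L <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(L))
  t <- seq(0, 1, length.out = n)
  ys <- p0[1] + t * (p1[1] - p0[1])
  xs <- p0[2] + t * (p1[2] - p0[2])
  if (wobble && L > 8) {
    m <- max(3L, ceiling(L * um_per_pixel / 40))
    kn <- rnorm(m, 0, 0.05 * L)
    off <- stats::spline(seq_len(m), kn, n = n)$y * sin(pi * t)
    nrm <- c(-(p1[2] - p0[2]), p1[1] - p0[1]) / L
    ys <- ys + off * nrm[1]
    xs <- xs + off * nrm[2]
  }
  offs <- .disc_offsets(width_px / 2)
  py <- round(outer(ys, offs$dy, "+"))
  px <- round(outer(xs, offs$dx, "+"))
  keep <- py >= 1 & py <= h & px >= 1 & px <= w
  lin <- unique((px[keep] - 1L) * h + py[keep])
  lin <- lin[tissue[lin] & !collagen[lin]]
  collagen[lin] <- TRUE
  list(mask = collagen, added = length(lin))
}

## Draw collagen for a septal pattern until `target_cnt` pixels are set.
## `collagen` may carry an existing pattern to build bridging septa onto.
.draw_septal <- function(tissue, target_cnt, um,
                         collagen = matrix(FALSE, nrow(tissue), ncol(tissue))) {
  h <- nrow(tissue); w <- ncol(tissue)
  tissue_px <- sum(tissue)
  ## scatter "vein" seed points inside tissue, ~1 per (120 um)^2
  lambda <- max(4, tissue_px * (um / 120)^2)
  n_seed <- max(4L, rpois(1, lambda))
  seeds <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(seeds) < n_seed && tries < 50L * n_seed) {
    y <- runif(1, 1, h); x <- runif(1, 1, w); tries <- tries + 1L
    if (tissue[round(y), round(x)]) seeds <- rbind(seeds, c(y, x))
  }
  if (nrow(seeds) < 2L) stop("tissue region too small to place septa")
  cnt <- sum(collagen); iter <- 0L; zerorun <- 0L
  while (cnt < target_cnt && iter < 20000L) {
    iter <- iter + 1L
    i <- sample.int(nrow(seeds), 1)
    d <- sqrt(rowSums((seeds - matrix(seeds[i, ], nrow(seeds), 2, byrow = TRUE))^2))
    d[i] <- Inf
    j <- order(d)[min(sample.int(3L, 1), nrow(seeds) - 1L)]
    wd <- runif(1, 3, 10) * 0.452 / um
    p0 <- seeds[i, ]; p1 <- seeds[j, ]
    remaining <- target_cnt - cnt
    max_len <- remaining / max(wd, 1) * 1.2 + 2
    L <- sqrt(sum((p1 - p0)^2))
    if (L > max_len) {
      ## truncate final strokes (random span of the path) to land on target
      wd <- min(wd, 3 * 0.452 / um)
      t0 <- runif(1, 0, 1 - max_len / L)
      pa <- p0 + t0 * (p1 - p0)
      p1 <- p0 + (t0 + max_len / L) * (p1 - p0)
      p0 <- pa
    }
    st <- .stamp_band(collagen, tissue, p0, p1, wd, um)
    collagen <- st$mask; cnt <- cnt + st$added
    zerorun <- if (st$added == 0L) zerorun + 1L else 0L
    if (zerorun > 50L) {
      remaining <- target_cnt - cnt
      if (remaining > max(0.002 * tissue_px, 500) && iter < 18000L) {
        ## corridors between current seeds are saturated: scatter fresh
        ## vein points so new septa can bridge elsewhere
        tries2 <- 0L
        while (tries2 < 200L && nrow(seeds) < 5000L) {
          y <- runif(1, 1, h); x <- runif(1, 1, w); tries2 <- tries2 + 1L
          if (tissue[round(y), round(x)] && !collagen[round(y), round(x)])
            seeds <- rbind(seeds, c(y, x))
          if (tries2 %% 20L == 0L && nrow(seeds) >= n_seed + 10L) break
        }
        zerorun <- 0L
        next
      }
      ## finish the last sliver of the burden as scattered fiber
      ## cross-sections (single-pixel fragments)
      cand <- which(tissue & !collagen)
      if (length(cand) >= remaining && remaining <= max(0.002 * tissue_px, 500)) {
        collagen[cand[sample.int(length(cand), remaining)]] <- TRUE
        cnt <- cnt + remaining
      }
      break
    }
  }
  if (cnt < target_cnt) attr(collagen, "saturated") <- TRUE
  collagen
}

## Chicken-wire lattice of thin strands for a perisinusoidal pattern; once
## the lattice is exhausted, remaining burden is laid down as bridging septa
## (advanced perisinusoidal fibrosis progresses to bridging).
.draw_perisinusoidal <- function(tissue, target_cnt, um) {
  h <- nrow(tissue); w <- ncol(tissue)
  collagen <- matrix(FALSE, h, w)
  sp <- 26 / um                                    # hepatocyte cord spacing
  gy <- seq(1, h, by = sp); gx <- seq(1, w, by = sp)
  ny <- length(gy); nx <- length(gx)
  nodes <- cbind(rep(gy, nx) + rnorm(ny * nx, 0, 0.22 * sp),
                 rep(gx, each = ny) + rnorm(ny * nx, 0, 0.22 * sp))
  idx <- function(iy, ix) (ix - 1L) * ny + iy
  edges <- rbind(
    cbind(idx(rep(1:(ny - 1), nx), rep(1:nx, each = ny - 1)),
          idx(rep(2:ny, nx), rep(1:nx, each = ny - 1))),
    cbind(idx(rep(1:ny, nx - 1), rep(1:(nx - 1), each = ny)),
          idx(rep(1:ny, nx - 1), rep(2:nx, each = ny))))
  edges <- edges[sample.int(nrow(edges)), , drop = FALSE]
  wd <- max(1, round(0.9 / um))
  cnt <- 0L; k <- 0L
  while (cnt < target_cnt && k < nrow(edges)) {
    k <- k + 1L
    p0 <- nodes[edges[k, 1], ]; p1 <- nodes[edges[k, 2], ]
    remaining <- target_cnt - cnt
    max_len <- remaining / wd * 1.2 + 2
    L <- sqrt(sum((p1 - p0)^2))
    if (L > max_len) p1 <- p0 + (p1 - p0) * max_len / L
    st <- .stamp_band(collagen, tissue, p0, p1, wd, um)
    collagen <- st$mask; cnt <- cnt + st$added
  }
  if (cnt < target_cnt)
    collagen <- .draw_septal(tissue, target_cnt, um, collagen)
  collagen
}

## Internal OD-space texture constants of the renderer. The parenchyma
## concentration field and the one-sided red mottle are what give the tissue
## OD cloud its two leading principal axes; the collagen contrast then loads
## on the third axis, which is what the segmenter relies on. The
## concentration spread is bounded so the darkest tissue stays above ~25 DN
## on the 8-bit scale (bright-field scanners do not render tissue opaque).
.TEX <- list(conc_sd = 0.10, conc_scale_um = 45,
             mottle_sd = 0.22, mottle_scale_um = 65,
             fiber_sd = 0.12, fiber_scale_um = 30,
             psf_sigma_px = 0.5)

## 3x3 Gaussian point-spread kernel
.psf_kernel <- function(sigma) {
  k <- outer(dnorm(-1:1, sd = sigma), dnorm(-1:1, sd = sigma))
  k / sum(k)
}

## Render the color image from class masks. Returns integer h x w x 3.
.render_psr <- function(tissue, collagen, params) {
  h <- nrow(tissue); w <- ncol(tissue)
  um <- params$um_per_pixel
  g <- params$glass_level
  p_od <- log10(g / pmax(params$parenchyma_color, 0.5))
  c_od <- log10(g / pmax(params$collagen_color, 0.5))
  k_od <- c_od - p_od                       # sirius-red contrast over background
  conc <- exp(.smooth_field(h, w, .TEX$conc_scale_um / um) * .TEX$conc_sd)
  mottle <- abs(.smooth_field(h, w, .TEX$mottle_scale_um / um)) * .TEX$mottle_sd
  fiber <- exp(.smooth_field(h, w, .TEX$fiber_scale_um / um) * .TEX$fiber_sd)
  kern <- .psf_kernel(.TEX$psf_sigma_px)
  out <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) {
    od <- matrix(0, h, w)
    od[tissue] <- p_od[ch] * conc[tissue]
    if (ch == 1L) od[tissue] <- od[tissue] + mottle[tissue]
    od[collagen] <- od[collagen] + k_od[ch] * fiber[collagen]
    img <- g[ch] * 10^(-od)
    if (params$color_jitter_sd > 0)
      img <- img + matrix(rnorm(h * w, 0, params$color_jitter_sd), h, w)
    img <- t(as.matrix(EBImage::filter2(EBImage::Image(t(img)), kern)))
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(h * w, 0, params$noise_sd), h, w)
    out[, , ch] <- as.integer(pmin(pmax(round(img), 0), 255))
  }
  out
}

#' Generate a synthetic PSR slide with exact ground truth
#'
#' Draws a tissue silhouette, lays down a collagen pattern until the
#' ground-truth pixel ratio reaches the requested CPA (within 1.5 percentage
#' points), and renders a PSR-like RGB image over it. The ground-truth CPA is
#' the exact mask pixel ratio, and the whole slide is a deterministic
#' function of the parameters (including the seed).
#'
#' @param params a [slide_gen_params].
#' @return An object of class `synthetic_slide`: list with `image` (a [wsi]),
#'   logical matrices `tissue_truth` and `collagen_truth`
#'   (`collagen_truth` is nested inside `tissue_truth`), `true_cpa`
#'   (percent), and `params`.
#' @export
make_slide <- function(params) {
  stopifnot(inherits(params, "slide_gen_params"))
  if (params$pattern == "none" && params$target_cpa > 0)
    stop("target_cpa = ", params$target_cpa,
         " is unreachable with pattern 'none'; achievable range: 0")
  .with_seed(params$seed, {
    h <- params$height_px; w <- params$width_px; um <- params$um_per_pixel
    tissue <- .tissue_silhouette(h, w, um)
    tissue_px <- sum(tissue)
    target_cnt <- round(params$target_cpa / 100 * tissue_px)
    collagen <-
      if (params$pattern == "none" || target_cnt == 0L) matrix(FALSE, h, w)
      else if (params$pattern == "septal") .draw_septal(tissue, target_cnt, um)
      else .draw_perisinusoidal(tissue, target_cnt, um)
    true_cpa <- 100 * sum(collagen) / tissue_px
    if (isTRUE(attr(collagen, "saturated")) ||
        abs(true_cpa - params$target_cpa) > 1.5)
      stop(sprintf(
        "could not reach target CPA %.2f%% with pattern '%s' at %dx%d px; achievable range approximately [0, %.2f]%%",
        params$target_cpa, params$pattern, w, h, true_cpa))
    attr(collagen, "saturated") <- NULL
    img <- .render_psr(tissue, collagen, params)
    structure(list(image = wsi(img, um),
                   tissue_truth = tissue, collagen_truth = collagen,
                   true_cpa = true_cpa, params = params),
              class = "synthetic_slide")
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> %d x %d px, %.4g um/px, pattern %s, true CPA %.3f%%\n",
              x$image$width_px, x$image$height_px, x$image$um_per_pixel,
              x$params$pattern, x$true_cpa))
  invisible(x)
}

## block-reduce a matrix by integer factor k with function applied over blocks
.block_mean <- function(m, k) {
  h2 <- nrow(m) %/% k; w2 <- ncol(m) %/% k
  a <- array(m[seq_len(h2 * k), seq_len(w2 * k)], dim = c(k, h2, k, w2))
  s <- colMeans(a)                       # (h2, k, w2)
  colMeans(aperm(s, c(2, 1, 3)))         # (h2, w2)
}

#' Re-render a synthetic slide at a coarser resolution
#'
#' Emulates scanning the same physical section at a lower magnification:
#' the color image is resampled by area averaging and the ground-truth masks
#' by per-block majority vote (exact ties broken by a fixed checkerboard,
#' which is area-unbiased and preserves the collagen-inside-tissue nesting).
#' Only integer downscale factors are
#' supported; the ground-truth CPA is recomputed from the resampled masks.
#'
#' @param slide a [synthetic_slide].
#' @param um_per_pixel requested pixel size; must be the native size times a
#'   positive integer.
#' @return A [synthetic_slide] at the new resolution.
#' @export
render_at_resolution <- function(slide, um_per_pixel) {
  stopifnot(inherits(slide, "synthetic_slide"))
  um0 <- slide$image$um_per_pixel
  fac <- um_per_pixel / um0
  if (fac < 1 - 1e-9)
    stop("cannot upsample: requested ", um_per_pixel,
         " um/px is finer than the native ", um0, " um/px")
  if (abs(fac - 1) < 1e-9) return(slide)
  k <- round(fac)
  if (abs(fac - k) > 1e-6)
    stop("only integer downscale factors are supported (requested factor ",
         signif(fac, 4), ")")
  img0 <- slide$image$pixels
  h2 <- dim(img0)[1] %/% k; w2 <- dim(img0)[2] %/% k
  img <- array(0L, dim = c(h2, w2, 3L))
  for (ch in 1:3)
    img[, , ch] <- as.integer(pmin(pmax(round(.block_mean(img0[, , ch], k)), 0), 255))
  ## majority vote; exact ties broken by a checkerboard so thin diagonal
  ## structures are neither inflated nor eroded on average. Because the
  ## collagen block count never exceeds the tissue block count, the shared
  ## tie rule preserves collagen-inside-tissue nesting.
  cb <- outer(seq_len(h2), seq_len(w2), function(i, j) (i + j) %% 2L == 0L)
  maj <- function(m) {
    s <- .block_mean(m + 0, k)
    tie <- abs(s - 0.5) < 1e-9
    (s > 0.5 & !tie) | (tie & cb)
  }
  tissue <- maj(slide$tissue_truth)
  collagen <- maj(slide$collagen_truth) & tissue
  params <- slide$params
  params$um_per_pixel <- um_per_pixel
  params$width_px <- w2; params$height_px <- h2
  structure(list(image = wsi(img, um_per_pixel),
                 tissue_truth = tissue, collagen_truth = collagen,
                 true_cpa = 100 * sum(collagen) / max(sum(tissue), 1L),
                 params = params),
            class = "synthetic_slide")
}

#' Design of a synthetic cohort
#'
#' Describes an animal study whose fibrosis burden rises over time: treatment
#' groups with group sizes, a week-to-mean-CPA trajectory, between-animal
#' variability, a linear CPA-to-hydroxyproline link, and CPA cutpoints that
#' generate histological stage labels per scoring system.
#'
#' The defaults emulate a chronic-injury time course: a small control group
#' and treated groups sampled over 18 weeks, 3 sections per animal, mean CPA
#' rising from under 1% to about 7%, and hydroxyproline (ug per g liver)
#' increasing linearly with CPA plus assay noise.
#'
#' @param groups data.frame with columns `label`, `week`, `n_animals`.
#' @param sections_per_animal sections cut per animal (default 3).
#' @param cpa_trajectory named numeric: mean true CPA (%) per week.
#' @param cpa_between_animal_sd between-animal variability of the CPA target,
#'   as a log-scale SD (multiplicative).
#' @param hyp_slope,hyp_intercept,hyp_noise_sd linear CPA-to-HYP link:
#'   `HYP = slope * meanCPA + intercept + N(0, noise_sd)`, in ug/g liver.
#' @param stage_thresholds named list of strictly increasing CPA cutpoints
#'   (%), one vector per scoring system (`ishak`, `ishak_modified`,
#'   `nash_crn`); an animal's stage is the number of cutpoints below its
#'   mean true CPA.
#' @param seed integer.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(
    groups = data.frame(
      label = c("ctrl", "w1", "w3", "w6", "w12", "w18"),
      week = c(0, 1, 3, 6, 12, 18),
      n_animals = c(4, 6, 6, 6, 6, 6)),
    sections_per_animal = 3L,
    cpa_trajectory = c(`0` = 0.8, `1` = 0.9, `3` = 2.2, `6` = 3.2,
                       `12` = 4.6, `18` = 6.7),
    cpa_between_animal_sd = 0.25,
    hyp_slope = 45, hyp_intercept = 130, hyp_noise_sd = 55,
    stage_thresholds = list(
      ishak = c(0.9, 1.5, 2.5, 3.5, 5, 7),
      ishak_modified = c(0.9, 1.5, 2.5, 3.5, 5, 7),
      nash_crn = c(0.9, 1.3, 1.8, 2.5, 4, 6)),
    seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("label", "week", "n_animals") %in% names(groups)),
            all(groups$n_animals >= 1), sections_per_animal >= 1,
            all(as.character(groups$week) %in% names(cpa_trajectory)),
            cpa_between_animal_sd >= 0, hyp_noise_sd >= 0)
  for (th in stage_thresholds)
    if (is.unsorted(th, strictly = TRUE)) stop("stage_thresholds must be strictly increasing")
  structure(list(groups = groups,
                 sections_per_animal = as.integer(sections_per_animal),
                 cpa_trajectory = cpa_trajectory,
                 cpa_between_animal_sd = cpa_between_animal_sd,
                 hyp_slope = hyp_slope, hyp_intercept = hyp_intercept,
                 hyp_noise_sd = hyp_noise_sd,
                 stage_thresholds = stage_thresholds,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

## map a mean CPA to a stage label given cutpoints and the system's labels
.stage_label <- function(mean_cpa, cutpoints, labels) {
  labels[sum(mean_cpa > cutpoints) + 1L]
}

#' Generate a synthetic cohort of PSR slides with metadata
#'
#' Generates one synthetic slide per section for every animal of the design,
#' writes them (PNG plus JSON sidecar) under `output_dir/slides/`, and writes
#' `metadata.csv` with one row per section: `animal_id`, `group`, `week`,
#' `section_index`, `slide_path` (relative to `output_dir`), `true_cpa`,
#' `hyp_ug_per_g`, `ishak`, `ishak_modified`, `nash_crn`, `um_per_pixel`.
#' Stage labels are obtained by thresholding the animal's mean true CPA at
#' the design cutpoints; hydroxyproline is the design's linear function of
#' mean true CPA plus noise. Generation parameters are echoed to
#' `cohort_params.json`. Fully deterministic given the design seed.
#'
#' @param design a [cohort_design].
#' @param output_dir directory to create/write into.
#' @param slide_template a [slide_gen_params] providing raster size,
#'   resolution, pattern and color model for every section (its `target_cpa`
#'   and `seed` are overridden per section).
#' @param write_slides if `FALSE`, skip writing image files (metadata only;
#'   slides are still returned).
#' @return Invisibly, a list with `metadata` (data.frame as written) and
#'   `slides` (list of [synthetic_slide], one per metadata row).
#' @export
make_cohort <- function(design, output_dir,
                        slide_template = slide_gen_params(width_px = 512,
                                                          height_px = 512),
                        write_slides = TRUE) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(slide_template, "slide_gen_params"))
  dir.create(file.path(output_dir, "slides"), recursive = TRUE,
             showWarnings = FALSE)
  sys_labels <- list(ishak = as.character(0:6),
                     ishak_modified = as.character(0:6),
                     nash_crn = c("0", "1A", "1B", "1C", "2", "3", "4"))
  .with_seed(design$seed, {
    g <- design$groups
    n_animals <- sum(g$n_animals)
    n_sections <- n_animals * design$sections_per_animal
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sections)
    rows <- list(); slides <- list(); si <- 0L
    for (gi in seq_len(nrow(g))) {
      traj <- design$cpa_trajectory[[as.character(g$week[gi])]]
      for (ai in seq_len(g$n_animals[gi])) {
        animal_id <- sprintf("%s_m%02d", g$label[gi], ai)
        a_target <- traj * exp(rnorm(1, 0, design$cpa_between_animal_sd))
        a_target <- min(a_target, 40)
        sec_targets <- pmin(pmax(a_target * exp(rnorm(
          design$sections_per_animal, 0, 0.08)), 0), 45)
        sec_cpa <- numeric(design$sections_per_animal)
        sec_rows <- list()
        for (k in seq_len(design$sections_per_animal)) {
          si <- si + 1L
          p <- slide_template
          p$target_cpa <- sec_targets[k]
          p$seed <- sub_seeds[si]
          if (p$pattern == "none" && p$target_cpa > 0) p$pattern <- "septal"
          sl <- make_slide(p)
          rel <- file.path("slides", sprintf("%s_s%d.png", animal_id, k))
          if (write_slides) write_slide(sl$image, file.path(output_dir, rel))
          sec_cpa[k] <- sl$true_cpa
          slides[[si]] <- sl
          sec_rows[[k]] <- data.frame(
            animal_id = animal_id, group = g$label[gi], week = g$week[gi],
            section_index = k, slide_path = rel, true_cpa = sl$true_cpa,
            um_per_pixel = p$um_per_pixel, stringsAsFactors = FALSE)
        }
        mean_cpa <- mean(sec_cpa)
        hyp <- max(0, design$hyp_slope * mean_cpa + design$hyp_intercept +
                     rnorm(1, 0, design$hyp_noise_sd))
        for (k in seq_len(design$sections_per_animal)) {
          sec_rows[[k]]$hyp_ug_per_g <- hyp
          for (sys in names(design$stage_thresholds))
            sec_rows[[k]][[sys]] <- .stage_label(
              mean_cpa, design$stage_thresholds[[sys]], sys_labels[[sys]])
        }
        rows <- c(rows, sec_rows)
      }
    }
    md <- do.call(rbind, rows)
    md <- md[, c("animal_id", "group", "week", "section_index", "slide_path",
                 "true_cpa", "hyp_ug_per_g", "ishak", "ishak_modified",
                 "nash_crn", "um_per_pixel")]
    utils::write.csv(md, file.path(output_dir, "metadata.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(design = list(groups = design$groups,
                         sections_per_animal = design$sections_per_animal,
                         cpa_trajectory = as.list(design$cpa_trajectory),
                         cpa_between_animal_sd = design$cpa_between_animal_sd,
                         hyp_slope = design$hyp_slope,
                         hyp_intercept = design$hyp_intercept,
                         hyp_noise_sd = design$hyp_noise_sd,
                         stage_thresholds = design$stage_thresholds,
                         seed = design$seed),
           slide_template = unclass(slide_template)),
      file.path(output_dir, "cohort_params.json"),
      auto_unbox = TRUE, digits = NA)
    invisible(list(metadata = md, slides = slides))
  })
}
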