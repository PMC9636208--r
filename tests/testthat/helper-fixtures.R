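## Shared synthetic fixtures, built once per test run and memoised.
.fixture_env <- new.env(parent = emptyenv())

fixture_slide <- function(key = "septal10", ...) {
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  args <- switch(key,
    septal10 = list(width_px = 512, height_px = 512, pattern = "septal",
                    target_cpa = 10, seed = 42),
    peri5 = list(width_px = 512, height_px = 512,
                 pattern = "perisinusoidal", target_cpa = 5, seed = 43),
    blank = list(width_px = 256, height_px = 256, pattern = "none",
                 target_cpa = 0, seed = 44),
    fine8 = list(width_px = 768, height_px = 768, um_per_pixel = 0.226,
                 pattern = "septal", target_cpa = 8, seed = 45),
    stop("unknown fixture key: ", key))
  sl <- do.call(slide_gen_params, utils::modifyList(args, list(...)))
  .fixture_env[[key]] <- make_slide(sl)
  .fixture_env[[key]]
}

fixture_cohort <- function() {
  if (!is.null(.fixture_env$cohort)) return(.fixture_env$cohort)
  dir <- file.path(tempdir(), "fibrocpa-test-cohort")
  des <- cohort_design(
    groups = data.frame(label = c("ctrl", "w6", "w18"), week = c(0, 6, 18),
                        n_animals = c(2, 2, 2)),
    seed = 11)
  .fixture_env$cohort <- make_cohort(
    des, dir, slide_template = slide_gen_params(width_px = 320, height_px = 320))
  .fixture_env$cohort$dir <- dir
  .fixture_env$cohort
}

## uniform-color test slide
flat_slide <- function(rgb, h = 64, w = 64, um = 0.452) {
  px <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- as.integer(rgb[ch])
  wsi(px, um)
}
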