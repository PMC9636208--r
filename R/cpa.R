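#' Collagen proportionate area of a segmented slide
#'
#' CPA is the ratio of segmented collagen area to the area of the entire
#' delineated liver section, in percent. The raw pixel counts are carried
#' along for audit.
#'
#' @param result a `segmentation_result` from [segment_slide].
#' @param slide_id identifier carried into the output.
#' @return An object of class `cpa_measurement`: `slide_id`, `collagen_px`,
#'   `tissue_px`, `cpa_percent`.
#' @export
compute_cpa <- function(result, slide_id = NA_character_) {
  stopifnot(inherits(result, "segmentation_result"))
  if (result$tissue_px == 0L)
    stop("no tissue detected in slide ", slide_id, "; CPA is undefined")
  structure(list(slide_id = slide_id,
                 collagen_px = result$collagen_px,
                 tissue_px = result$tissue_px,
                 cpa_percent = 100 * result$collagen_px / result$tissue_px),
            class = "cpa_measurement")
}

#' @export
print.cpa_measurement <- function(x, ...) {
  cat(sprintf("<cpa_measurement> %s: %.4f%% (%d / %d px)\n",
              x$slide_id, x$cpa_percent, x$collagen_px, x$tissue_px))
  invisible(x)
}

#' Per-animal CPA: arithmetic mean over sections
#'
#' One mean per subject is computed from its sections (three per animal in
#' the reference design). Fewer sections than expected trigger a warning,
#' never silent imputation.
#'
#' @param section_cpas numeric vector of per-section CPA percentages.
#' @param expected_sections warn when fewer sections are supplied.
#' @return The mean CPA (percent).
#' @export
aggregate_animal <- function(section_cpas, expected_sections = 3L) {
  if (length(section_cpas) == 0L) stop("no section CPA values supplied")
  if (anyNA(section_cpas)) stop("section CPA values contain NA")
  if (length(section_cpas) < expected_sections)
    warning("only ", length(section_cpas), " section(s) available (expected ",
            expected_sections, "); mean over available sections")
  mean(section_cpas)
}

#' Repeatability of the segmentation pixel count
#'
#' Segments the same slide `n_runs` times and returns the standard error of
#' the collagen pixel counts. The pipeline is deterministic, so the contract
#' is exactly 0. The `perturb` hook (test use) can alter the configuration
#' between runs to verify that the harness can detect non-repeatability.
#'
#' @param slide a [wsi].
#' @param cfg a [segmentation_config].
#' @param n_runs number of repeat runs (>= 2).
#' @param perturb optional `function(cfg, run_index)` returning a config.
#' @return list: `counts` (per-run collagen pixel counts), `se` (their
#'   standard error).
#' @export
repeatability_check <- function(slide, cfg = segmentation_config(),
                                n_runs = 5L, perturb = NULL) {
  stopifnot(n_runs >= 2L)
  counts <- vapply(seq_len(n_runs), function(i) {
    ci <- if (is.null(perturb)) cfg else perturb(cfg, i)
    segment_slide(slide, ci)$collagen_px
  }, numeric(1))
  list(counts = counts, se = stats::sd(counts) / sqrt(n_runs))
}
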