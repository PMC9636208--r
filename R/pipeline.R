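#' Segment a batch of slides to a per-section table
#'
#' Runs [segment_slide] on every input slide, writes one CSV row per slide
#' (`slide_id`, `tissue_px`, `collagen_px`, `cpa_percent`, `um_per_pixel`,
#' singular values and background I0), the tissue/collagen masks, and a run
#' manifest (config snapshot, input checksums, package version, per-slide
#' wall time). Per-slide failures are logged and skipped; their count is
#' returned in the summary.
#'
#' @param inputs directory containing slides, or explicit file paths.
#' @param cfg a [segmentation_config].
#' @param output_dir destination directory.
#' @param um_per_pixel optional override passed to [read_slide].
#' @param write_masks write collagen/tissue masks next to the CSV.
#' @return Invisibly, list with `sections` (data.frame), `n_failed`,
#'   `manifest_path`.
#' @export
run_segment <- function(inputs, cfg = segmentation_config(), output_dir,
                        um_per_pixel = NULL, write_masks = FALSE) {
  paths <- if (length(inputs) == 1L && dir.exists(inputs))
    list.files(inputs, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
               recursive = TRUE)
  else inputs[file.exists(inputs)]
  if (length(paths) == 0L) stop("no input slides found")
  root <- if (length(inputs) == 1L && dir.exists(inputs)) inputs else "."
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_masks)
    dir.create(file.path(output_dir, "masks"), showWarnings = FALSE)
  rows <- list(); times <- numeric(0); failed <- character(0)
  for (p in paths) {
    rel <- sub(paste0("^", root, "/?"), "", p)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      sl <- read_slide(p, um_per_pixel)
      seg <- segment_slide(sl, cfg)
      cpa <- compute_cpa(seg, slide_id = rel)
      if (write_masks) {
        base <- gsub("[/\\\\]", "_", tools::file_path_sans_ext(rel))
        write_mask(seg$collagen_mask,
                   file.path(output_dir, "masks", paste0(base, "_collagen.png")))
        write_mask(seg$tissue_mask,
                   file.path(output_dir, "masks", paste0(base, "_tissue.png")))
      }
      data.frame(slide_id = rel, tissue_px = seg$tissue_px,
                 collagen_px = seg$collagen_px, cpa_percent = cpa$cpa_percent,
                 um_per_pixel = sl$um_per_pixel,
                 s1 = seg$basis$s[1], s2 = seg$basis$s[2], s3 = seg$basis$s[3],
                 I0_r = seg$background_I0[1], I0_g = seg$background_I0[2],
                 I0_b = seg$background_I0[3], stringsAsFactors = FALSE)
    }, error = function(e) {
      message("run_segment: skipping ", rel, ": ", conditionMessage(e))
      NULL
    })
    times <- c(times, proc.time()[["elapsed"]] - t0)
    if (is.null(res)) failed <- c(failed, rel) else rows[[length(rows) + 1L]] <- res
  }
  sections <- do.call(rbind, rows)
  utils::write.csv(sections, file.path(output_dir, "sections.csv"),
                   row.names = FALSE)
  manifest <- list(
    config = unclass(cfg),
    inputs = data.frame(path = paths, md5 = unname(tools::md5sum(paths)),
                        stringsAsFactors = FALSE),
    failed = failed,
    version = as.character(utils::packageVersion("fibroCPA")),
    wall_time_s = times,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mp <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(list(sections = sections, n_failed = length(failed),
                 manifest_path = mp))
}

#' Join section CPA with cohort metadata and run the validation statistics
#'
#' Joins the per-section table from [run_segment] to the cohort metadata on
#' the relative slide path, aggregates per animal (mean CPA over sections,
#' highest stage across sections per scoring system), attaches
#' hydroxyproline, writes the per-animal CSV and the [correlation_report]
#' (CSV and JSON). When sections are present at two resolutions, the
#' 20X-vs-40X regression of per-animal mean CPA is included.
#'
#' @param sections data.frame or path to `sections.csv`.
#' @param metadata data.frame or path to the cohort `metadata.csv`.
#' @param output_dir destination directory.
#' @return Invisibly, list with `animals`, `report`, and `regression`
#'   (`NULL` unless two resolutions are present).
#' @export
run_analyze <- function(sections, metadata, output_dir) {
  if (is.character(sections)) sections <- utils::read.csv(sections)
  if (is.character(metadata)) metadata <- utils::read.csv(metadata,
                                                          colClasses = "character")
  for (cc in c("week", "section_index", "true_cpa", "hyp_ug_per_g",
               "um_per_pixel"))
    if (cc %in% names(metadata)) metadata[[cc]] <- as.numeric(metadata[[cc]])
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  m <- merge(metadata, sections, by.x = "slide_path", by.y = "slide_id")
  unjoined <- setdiff(sections$slide_id, metadata$slide_path)
  if (length(unjoined))
    stop("sections not present in metadata: ", paste(unjoined, collapse = ", "))
  score_cols <- intersect(c("ishak", "ishak_modified", "nash_crn"), names(m))
  ## per-animal aggregation, per resolution when several are present
  m$um_key <- signif(m$um_per_pixel.y %||% m$um_per_pixel, 6)
  split_keys <- interaction(m$animal_id, m$um_key, drop = TRUE)
  agg <- lapply(split(m, split_keys), function(d) {
    row <- data.frame(animal_id = d$animal_id[1], group = d$group[1],
                      week = d$week[1], um_per_pixel = d$um_key[1],
                      n_sections = nrow(d),
                      mean_cpa = aggregate_animal(d$cpa_percent,
                                                  expected_sections = 1L),
                      hyp_ug_per_g = as.numeric(d$hyp_ug_per_g[1]),
                      stringsAsFactors = FALSE)
    for (sc in score_cols)
      row[[sc]] <- aggregate_scores(d[[sc]], sc)
    row
  })
  animals <- do.call(rbind, agg)
  rownames(animals) <- NULL
  utils::write.csv(animals, file.path(output_dir, "animals.csv"),
                   row.names = FALSE)
  ums <- sort(unique(animals$um_per_pixel))
  primary <- animals[animals$um_per_pixel == ums[1], ]
  report <- correlation_report(primary, score_cols)
  regression <- NULL
  if (length(ums) == 2L) {
    fine <- animals[animals$um_per_pixel == ums[1], ]
    coarse <- animals[animals$um_per_pixel == ums[2], ]
    j <- merge(fine[, c("animal_id", "mean_cpa")],
               coarse[, c("animal_id", "mean_cpa")], by = "animal_id")
    regression <- linreg_r2(j$mean_cpa.x, j$mean_cpa.y)
  }
  utils::write.csv(report, file.path(output_dir, "correlation_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(report = report,
         regression = if (is.null(regression)) NULL else unclass(regression),
         variant = "steiger_dependent"),
    file.path(output_dir, "correlation_report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(animals = animals, report = report, regression = regression))
}

#' Built-in validation suite
#'
#' Recomputes the pipeline's three headline engineering properties on small
#' synthetic fixtures: (1) repeatability of the collagen pixel count over 5
#' runs (standard error must be exactly 0); (2) ground-truth CPA recovery
#' within 1 percentage point on fixtures at 1, 5, 10 and 20% CPA; (3)
#' agreement of CPA between renders at 0.226 and 0.452 um/px. Prints a
#' PASS/FAIL line per check.
#'
#' @param cfg a [segmentation_config].
#' @param seed fixture seed.
#' @param quick use smaller fixtures (faster, for smoke testing).
#' @return Invisibly, TRUE when all checks pass, FALSE otherwise.
#' @export
run_validate <- function(cfg = segmentation_config(), seed = 7L,
                         quick = FALSE) {
  sz <- if (quick) 512L else 1024L
  ok <- TRUE
  note <- function(pass, fmt, ...) {
    cat(sprintf("[%s] ", if (pass) "PASS" else "FAIL"), sprintf(fmt, ...), "\n",
        sep = "")
    ok <<- ok && pass
  }
  sl <- make_slide(slide_gen_params(width_px = sz, height_px = sz,
                                    pattern = "septal", target_cpa = 10,
                                    seed = seed))
  rep5 <- repeatability_check(sl$image, cfg, n_runs = 5L)
  note(rep5$se == 0, "repeatability: SE of collagen px over 5 runs = %g", rep5$se)
  for (tc in c(1, 5, 10, 20)) {
    sli <- make_slide(slide_gen_params(width_px = sz, height_px = sz,
                                       pattern = "septal", target_cpa = tc,
                                       seed = seed + tc))
    est <- compute_cpa(segment_slide(sli$image, cfg))$cpa_percent
    note(abs(est - sli$true_cpa) <= 1.0,
         "recovery at %g%%: estimated %.3f%% vs true %.3f%%", tc, est,
         sli$true_cpa)
  }
  n_mag <- if (quick) 3L else 6L
  fine <- coarse <- numeric(n_mag)
  for (i in seq_len(n_mag)) {
    sli <- make_slide(slide_gen_params(width_px = sz, height_px = sz,
                                       um_per_pixel = 0.226,
                                       pattern = if (i %% 2) "septal" else "perisinusoidal",
                                       target_cpa = c(2, 6, 12, 18, 9, 4)[i],
                                       seed = seed + 100 + i))
    fine[i] <- compute_cpa(segment_slide(sli$image, cfg))$cpa_percent
    coarse[i] <- compute_cpa(segment_slide(
      render_at_resolution(sli, 0.452)$image, cfg))$cpa_percent
  }
  dmax <- max(abs(fine - coarse))
  note(dmax <= 1.0,
       "magnification equivalence: max |CPA(40X) - CPA(20X)| = %.3f pp", dmax)
  invisible(ok)
}
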