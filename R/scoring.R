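#' Fibrosis staging systems
#'
#' Ordered encodings of the three histological staging systems used to
#' validate CPA: Ishak (0-6, portal-anchored), a modified Ishak variant
#' re-anchored on centrilobular areas for CCl4-type injury (0-6), and the
#' NASH CRN fibrosis score (0, 1A, 1B, 1C, 2, 3, 4).
#'
#' NASH CRN substages 1A/1B/1C are substages of stage 1; by default all
#' three encode to numeric 1 ("collapsed") while the substage letter is kept
#' as the label, so no information is destroyed. A "fractional" coding
#' (1, 1.33, 1.67) is available for sensitivity analyses.
#'
#' @param name `"ishak"`, `"ishak_modified"` or `"nash_crn"`.
#' @param nash_substage_coding `"collapsed"` (default) or `"fractional"`.
#' @return An object of class `score_system`: `name`, `labels`,
#'   `numeric_values`.
#' @export
score_system <- function(name = c("ishak", "ishak_modified", "nash_crn"),
                         nash_substage_coding = c("collapsed", "fractional")) {
  name <- match.arg(name)
  nash_substage_coding <- match.arg(nash_substage_coding)
  if (name == "nash_crn") {
    labels <- c("0", "1A", "1B", "1C", "2", "3", "4")
    values <- if (nash_substage_coding == "collapsed")
      c(0, 1, 1, 1, 2, 3, 4)
    else c(0, 1, 1 + 1 / 3, 1 + 2 / 3, 2, 3, 4)
  } else {
    labels <- as.character(0:6)
    values <- 0:6
  }
  structure(list(name = name, labels = labels,
                 numeric_values = as.numeric(values)),
            class = "score_system")
}

#' Encode a stage label to its numeric value
#'
#' @param system a [score_system] or a system name.
#' @param label stage label (character; numerics are coerced).
#' @return Numeric stage value.
#' @export
encode_score <- function(system, label) {
  if (is.character(system)) system <- score_system(system)
  stopifnot(inherits(system, "score_system"))
  label <- toupper(trimws(as.character(label)))
  i <- match(label, system$labels)
  if (anyNA(i))
    stop("unknown ", system$name, " label(s) ",
         paste(sQuote(label[is.na(i)]), collapse = ", "),
         "; valid labels: ", paste(system$labels, collapse = ", "))
  system$numeric_values[i]
}

#' Aggregate per-section stage labels for one animal
#'
#' All sections of an animal are scored and the highest individual value is
#' used for statistical analysis.
#'
#' @param section_labels character vector of stage labels (one per section).
#' @param system a [score_system] or system name.
#' @return The maximum encoded value across sections.
#' @export
aggregate_scores <- function(section_labels, system) {
  if (length(section_labels) == 0L) stop("no section labels supplied")
  max(encode_score(system, section_labels))
}
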