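#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank), with
#' a two-sided p value from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Missing pairs are removed pairwise.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return An object of class `correlation_result`: `r`, `n`, `method`,
#'   `p_two_sided`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs (got ", n, ")")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(r = r, n = n, method = "spearman", p_two_sided = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s r = %.4f (n = %d, p = %.3g)\n",
              x$method, x$r, x$n, x$p_two_sided))
  invisible(x)
}

#' Fisher z transform
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`; defined for |r| < 1.
#'
#' @param r correlation(s) strictly inside (-1, 1).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1")
  0.5 * log((1 + r) / (1 - r))
}

#' Compare two dependent correlations sharing one variable
#'
#' Tests whether variable 1 (e.g. the histological stage, taken as the
#' reference) correlates more strongly with variable 2 (CPA) than with
#' variable 3 (hydroxyproline), when all three are measured on the same
#' subjects. The default is Steiger's (1980) Z for dependent correlations,
#' which uses the correlation `r23` between the two competing measurements:
#' \deqn{Z = (z_{12} - z_{13}) \sqrt{(n-3) / (2 (1 - \bar s))}}
#' with \eqn{\bar s = \bar\psi / (1 - \bar r^2)^2},
#' \eqn{\bar\psi = r_{23}(1 - 2\bar r^2) - \tfrac12 \bar r^2 (1 - 2\bar r^2 - r_{23}^2)},
#' \eqn{\bar r = (r_{12} + r_{13})/2}, and \eqn{z} the Fisher transform.
#' The naive independent-samples statistic
#' `(z12 - z13) / sqrt(2 / (n - 3))` is available as an explicit variant for
#' comparison; it ignores the dependence induced by `r23`.
#'
#' @param r12 correlation of the reference with measurement A.
#' @param r13 correlation of the reference with measurement B.
#' @param r23 correlation between the two measurements (ignored by the
#'   `fisher_independent` variant).
#' @param n number of subjects (>= 4).
#' @param alternative `"greater"` (one-sided, r12 > r13), `"less"`, or
#'   `"two_sided"`.
#' @param variant `"steiger_dependent"` (default) or `"fisher_independent"`.
#' @return An object of class `dependent_correlation_comparison` with fields
#'   `r12`, `r13`, `r23`, `n`, `z_stat`, `p_one_sided` (or two-sided when
#'   requested; the field `p` always holds the reported p value),
#'   `alternative`, `variant`.
#' @export
compare_dependent_correlations <- function(r12, r13, r23, n,
                                           alternative = c("greater", "less",
                                                           "two_sided"),
                                           variant = c("steiger_dependent",
                                                       "fisher_independent")) {
  alternative <- match.arg(alternative)
  variant <- match.arg(variant)
  stopifnot(n >= 4)
  if (any(abs(c(r12, r13, r23)) >= 1))
    stop("degenerate input: all correlations must satisfy |r| < 1")
  dz <- fisher_z(r12) - fisher_z(r13)
  z_stat <- if (variant == "steiger_dependent") {
    rbar <- (r12 + r13) / 2
    psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
    sbar <- psi / (1 - rbar^2)^2
    dz * sqrt((n - 3) / (2 * (1 - sbar)))
  } else {
    dz / sqrt(2 / (n - 3))
  }
  p <- switch(alternative,
              greater = stats::pnorm(z_stat, lower.tail = FALSE),
              less = stats::pnorm(z_stat),
              two_sided = 2 * stats::pnorm(-abs(z_stat)))
  structure(list(r12 = r12, r13 = r13, r23 = r23, n = as.integer(n),
                 z_stat = z_stat, p = p,
                 p_one_sided = if (alternative != "two_sided") p else NA_real_,
                 alternative = alternative, variant = variant),
            class = "dependent_correlation_comparison")
}

#' @export
print.dependent_correlation_comparison <- function(x, ...) {
  cat(sprintf(
    "<dependent_correlation_comparison> %s: Z = %.4f, p(%s) = %.4g (r12 = %.3f, r13 = %.3f, r23 = %.3f, n = %d)\n",
    x$variant, x$z_stat, x$alternative, x$p, x$r12, x$r13, x$r23, x$n))
  invisible(x)
}

#' Ordinary least-squares regression with r-squared
#'
#' Used to compare CPA measured on 20X and 40X scans of the same sections;
#' `r_squared` is the squared Pearson correlation.
#'
#' @param x,y numeric vectors (n >= 3; x non-constant).
#' @return An object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
linreg_r2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L) stop("regression undefined for constant x")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4f x + %.4f, r^2 = %.5f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Correlation report for an animal-level cohort table
#'
#' For each staging system present, computes the Spearman correlation of the
#' (aggregated numeric) stage with mean CPA and with hydroxyproline, the
#' CPA-HYP correlation `r23`, and Steiger's one-sided Z comparing the two
#' stage correlations with the stage as reference.
#'
#' @param animals data.frame with one row per animal, columns `mean_cpa`,
#'   `hyp_ug_per_g`, and one numeric column per scoring system (aggregated
#'   stage values).
#' @param score_cols character vector of scoring-system column names present
#'   in `animals`.
#' @return data.frame with columns `system`, `r_CPA`, `r_HYP`, `r23`, `n`,
#'   `Z`, `p_one_sided`.
#' @export
correlation_report <- function(animals,
                               score_cols = intersect(
                                 c("ishak", "ishak_modified", "nash_crn"),
                                 names(animals))) {
  stopifnot(all(c("mean_cpa", "hyp_ug_per_g") %in% names(animals)),
            length(score_cols) >= 1)
  if (nrow(animals) < 4)
    stop("need at least 4 animals for the correlation report (got ",
         nrow(animals), ")")
  r23 <- spearman_cor(animals$mean_cpa, animals$hyp_ug_per_g)
  out <- lapply(score_cols, function(sc) {
    r12 <- spearman_cor(animals[[sc]], animals$mean_cpa)
    r13 <- spearman_cor(animals[[sc]], animals$hyp_ug_per_g)
    cmp <- compare_dependent_correlations(r12$r, r13$r, r23$r, nrow(animals),
                                          alternative = "greater")
    data.frame(system = sc, r_CPA = r12$r, r_HYP = r13$r, r23 = r23$r,
               n = nrow(animals), Z = cmp$z_stat, p_one_sided = cmp$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
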