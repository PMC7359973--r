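#' Paired dose samples
#'
#' A pair of dose measurements per procedure: `x` is the reference arm
#' (Ho-166-only) and `y` the dual-isotope arm.
#'
#' @param x,y Numeric vectors of equal length (Gy).
#' @param labels Optional procedure identifiers.
#' @return A `paired_sample` (also a tibble with columns `label`, `x`, `y`).
#' @export
paired_sample <- function(x, y, labels = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_along(x))
  out <- tibble::tibble(label = labels, x = as.numeric(x), y = as.numeric(y))
  class(out) <- c("paired_sample", class(out))
  out
}

as_paired <- function(s, x = NULL, y = NULL) {
  if (inherits(s, "paired_sample")) return(s)
  paired_sample(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Computes the paired differences `d = y - x`, their mean and sample
#' standard deviation (n - 1 denominator), the coefficient of
#' reproducibility `CRP = 1.96 * SD`, and the limits of agreement
#' `LoA = mean(d) -/+ CRP`.
#'
#' @param s A [paired_sample()].
#' @return A `bland_altman` result with fields `mean_diff`, `sd_diff`,
#'   `crp`, `loa_lower`, `loa_upper`, `n` and the sample.
#' @export
bland_altman <- function(s) {
  s <- as_paired(s)
  d <- s$y - s$x
  m <- mean(d)
  sd_d <- stats::sd(d)
  crp <- 1.96 * sd_d
  structure(list(mean_diff = m, sd_diff = sd_d, crp = crp,
                 loa_lower = m - crp, loa_upper = m + crp,
                 n = length(d), sample = s),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean diff %.2f, SD %.2f, CRP %.2f\n",
              x$n, x$mean_diff, x$sd_diff, x$crp))
  cat(sprintf("  limits of agreement: [%.2f, %.2f]\n", x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff, crp = x$crp,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper, n = x$n)
}

#' @export
glance.bland_altman <- function(x, ...) tidy(x)

#' Bland-Altman plot
#'
#' @param object A `bland_altman` result.
#' @param ... Ignored.
#' @return A ggplot: per-pair mean vs difference with the mean-difference
#'   line (solid) and limits of agreement (dashed).
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(avg = (object$sample$x + object$sample$y) / 2,
                       diff = object$sample$y - object$sample$x)
  ggplot2::ggplot(df, ggplot2::aes(x = avg, y = diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired doses [Gy]",
                  y = "Difference (DI - Ho-only) [Gy]") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Pearson correlation of a paired sample
#'
#' @param s A [paired_sample()].
#' @return The product-moment correlation coefficient.
#' @export
pearson_r <- function(s) {
  s <- as_paired(s)
  if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(s$x, s$y)
}

#' Two-sided paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the differences `d = y - x`, with
#' `n - 1` degrees of freedom and a two-sided p-value.
#'
#' @param s A [paired_sample()].
#' @return A list with `statistic`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t_test <- function(s) {
  s <- as_paired(s)
  d <- s$y - s$x
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("degenerate differences: zero variance", call. = FALSE)
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(statistic = t_stat, df = n - 1,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
       mean_diff = mean(d))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two categorical rating vectors:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the raters' marginal distributions.
#'
#' @param ratings_a,ratings_b Equal-length vectors over a shared category
#'   set.
#' @return A `kappa_result` with `kappa`, `observed_agreement`,
#'   `expected_agreement`, `n`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have equal length", call. = FALSE)
  cats <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = cats)
  b <- factor(as.character(ratings_b), levels = cats)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12)
    stop("both raters constant and identical: kappa undefined", call. = FALSE)
  structure(list(kappa = (p_o - p_e) / (1 - p_e),
                 observed_agreement = p_o, expected_agreement = p_e, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (p_o = %.3f, p_e = %.3f, n = %d)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, observed_agreement = x$observed_agreement,
                 expected_agreement = x$expected_agreement, n = x$n)
}

#' Median and quartile deviation
#'
#' Summary used for dose distributions: the median and half the
#' interquartile range, with quartiles by linear interpolation
#' (`stats::quantile` type 7).
#'
#' @param values Numeric vector.
#' @return A list with `median` and `qd` (IQR/2).
#' @export
summarize_median_qd <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], qd = (q[3] - q[1]) / 2)
}
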