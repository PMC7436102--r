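# Evaluation statistics: median absolute error with quartiles, MARE,
# Pearson correlation, Bland-Altman agreement, and the one-sided Welch
# two-sample t-test used to compare two methods' absolute errors.

#' Evaluate estimates against ground truth
#'
#' For each quantity (column): median absolute error with 25th/75th
#' percentiles (linear-interpolation convention, R quantile type 7), Mean
#' Absolute Relative Error (items with non-positive truth are excluded with
#' a warning), Pearson correlation, and Bland-Altman mean difference with
#' 95% limits of agreement (+/- 1.96 SD).
#'
#' @param estimates,truths numeric vectors, or data.frames with matching
#'   numeric columns (e.g. kcal, cho_g, pro_g, fat_g); at least 2 pairs
#'   (Pearson r is degenerate below 3).
#' @return object of class `mv_evaluation`: one row per quantity with
#'   columns `median_abs_err`, `q25`, `q75`, `mare`, `pearson_r`,
#'   `ba_mean_diff`, `ba_lo`, `ba_hi`, `n`.
#' @export
evaluate_against_truth <- function(estimates, truths) {
  if (is.numeric(estimates)) estimates <- data.frame(value = estimates)
  if (is.numeric(truths)) truths <- data.frame(value = truths)
  stopifnot(nrow(estimates) == nrow(truths), nrow(estimates) >= 2,
            all(names(estimates) == names(truths)))
  rows <- lapply(names(estimates), function(cn) {
    e <- estimates[[cn]]; g <- truths[[cn]]
    err <- abs(e - g)
    pos <- g > 0
    if (any(!pos)) {
      warning(sum(!pos), " item(s) with non-positive truth excluded from ",
              "MARE for ", cn)
    }
    mare <- mean(err[pos] / g[pos])
    d <- e - g
    sdd <- stats::sd(d)
    data.frame(quantity = cn,
               median_abs_err = stats::median(err),
               q25 = as.numeric(stats::quantile(err, 0.25, type = 7)),
               q75 = as.numeric(stats::quantile(err, 0.75, type = 7)),
               mare = mare,
               pearson_r = if (stats::sd(e) > 0 && stats::sd(g) > 0)
                 stats::cor(e, g) else NA_real_,
               ba_mean_diff = mean(d),
               ba_lo = mean(d) - 1.96 * sdd,
               ba_hi = mean(d) + 1.96 * sdd,
               n = length(e))
  })
  structure(do.call(rbind, rows), class = c("mv_evaluation", "data.frame"))
}

#' One-sided Welch two-sample t-test on absolute errors
#'
#' Tests whether method A's absolute errors exceed method B's (H1:
#' `mean(errors_a) > mean(errors_b)`, Welch unequal-variance statistic).
#' A small p-value therefore means A is the worse method. Zero-variance
#' degenerate samples take an exact-equality fast path instead of dividing
#' by zero.
#'
#' @param errors_a,errors_b numeric vectors of absolute errors, n >= 3 each.
#' @param alpha significance threshold reported alongside (default 0.05).
#' @return list: `p_value`, `t`, `df`, `mean_a`, `mean_b`, `alpha`,
#'   `significant`.
#' @export
compare_methods <- function(errors_a, errors_b, alpha = 0.05) {
  stopifnot(length(errors_a) >= 3, length(errors_b) >= 3)
  na <- length(errors_a); nb <- length(errors_b)
  va <- stats::var(errors_a); vb <- stats::var(errors_b)
  ma <- mean(errors_a); mb <- mean(errors_b)
  if (va + vb < 1e-300) {
    p <- if (ma == mb) 0.5 else if (ma > mb) 0 else 1
    t <- if (ma == mb) 0 else sign(ma - mb) * Inf
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    t <- (ma - mb) / se
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- stats::pt(t, df, lower.tail = FALSE)
  }
  list(p_value = p, t = t, df = df, mean_a = ma, mean_b = mb,
       alpha = alpha, significant = p < alpha)
}

#' Bland-Altman agreement statistics (and optional plot)
#'
#' @param a,b paired measurements from two methods.
#' @param plot_file optional path; when given, the classic mean-vs-difference
#'   plot with the +/- 1.96 SD limits is written there as a PDF.
#' @return list: `mean_diff`, `sd_diff`, `loa` (length-2 limits of
#'   agreement), `frac_within` (fraction of differences inside the limits).
#' @export
bland_altman <- function(a, b, plot_file = NULL) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d); sdd <- stats::sd(d)
  loa <- c(md - 1.96 * sdd, md + 1.96 * sdd)
  if (!is.null(plot_file)) {
    grDevices::pdf(plot_file, width = 5, height = 4)
    on.exit(grDevices::dev.off())
    graphics::plot(m, d, pch = 19, col = "steelblue",
                   xlab = "mean of methods", ylab = "difference",
                   main = "Bland-Altman")
    graphics::abline(h = md, lty = 1)
    graphics::abline(h = loa, lty = 2)
  }
  list(mean_diff = md, sd_diff = sdd, loa = loa,
       frac_within = mean(d >= loa[1] & d <= loa[2]))
}
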