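# ggplot2 visualisations.

#' @importFrom ggplot2 ggplot aes geom_point geom_ribbon geom_abline
#'   geom_tile geom_line labs scale_fill_gradient theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' QQ plot of association P values
#'
#' Observed against expected -log10 P with the identity line; the standard
#' visual check for test-statistic inflation.
#'
#' @param object A `cpacor_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpacor_result
#' @export
autoplot.cpacor_result <- function(object, ...) {
  p <- sort(object$p[!is.na(object$p)])
  df <- tibble::tibble(expected = -log10((seq_along(p) - 0.5) / length(p)),
                       observed = -log10(rev(p)))
  df$observed <- sort(df$observed)
  ggplot(df, aes(x = .data$expected, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(size = 0.6) +
    labs(x = expression(Expected ~ -log[10](italic(P))),
         y = expression(Observed ~ -log[10](italic(P))),
         title = sprintf("lambda = %.2f", genomic_inflation(object$p))) +
    theme_minimal()
}

#' QQ prediction interval under the permutation null
#'
#' Per-rank 2.5%/97.5% envelope of the ordered -log10 P values across
#' phenotype permutations, around the expected uniform quantiles.
#'
#' @param object A `cpacor_null` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpacor_null
#' @export
autoplot.cpacor_null <- function(object, ...) {
  env <- object$envelope[!is.na(object$envelope$lo), ]
  s <- object$lambda_summary
  ggplot(env, aes(x = .data$expected)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi),
                fill = "steelblue", alpha = 0.4) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = expression(Expected ~ -log[10](italic(P))),
         y = expression(Observed ~ -log[10](italic(P))),
         title = sprintf("lambda median %.2f (%.2f-%.2f), %d permutations",
                         s["median"], s["q2.5"], s["q97.5"], object$n_perm)) +
    theme_minimal()
}

#' Heatmap of PC-factor associations
#'
#' Bonferroni-corrected -log10 P of association between principal
#' components and sample factors.
#'
#' @param object A `cpacor_pc_assoc` tibble from [factor_pc_heatmap()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpacor_pc_assoc
#' @export
autoplot.cpacor_pc_assoc <- function(object, ...) {
  df <- object
  df$pc <- factor(df$pc, levels = unique(df$pc))
  ggplot(df, aes(x = .data$pc, y = .data$covariate,
                 fill = .data$neg_log10_p)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        name = expression(-log[10](italic(P)[adj]))) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Smoothed local correlation against genomic distance
#'
#' @param object A `local_correlation` object.
#' @param ... Unused.
#' @return A ggplot of the sliding-window mean correlation.
#' @method autoplot local_correlation
#' @export
autoplot.local_correlation <- function(object, ...) {
  ggplot(object$smoothed, aes(x = .data$distance, y = .data$mean_r)) +
    geom_line(colour = "steelblue") +
    geom_point(data = object$pairs, aes(y = .data$r),
               alpha = 0.2, size = 0.5, colour = "grey40") +
    labs(x = "Distance (bp)", y = "Pearson r") +
    theme_minimal()
}
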