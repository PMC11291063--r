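## Basic base-graphics exports: score distribution, funnel scatter, heatmap.

#' Plot a score distribution with its fitted Gaussian components
#'
#' @param scores Numeric scores.
#' @param fit A [fit_score_distribution()] result.
#' @param main Plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_score_distribution <- function(scores, fit, main = "Enrichment scores") {
  x <- scores[is.finite(scores)]
  graphics::hist(x, breaks = 60, freq = FALSE, main = main,
                 xlab = "log2 enrichment score", col = "grey85",
                 border = "grey60")
  xs <- seq(min(x), max(x), length.out = 400)
  dens <- rep(0, length(xs))
  for (k in seq_len(fit$n_components)) {
    comp <- fit$weight[k] * stats::dnorm(xs, fit$mean[k], fit$sd[k])
    graphics::lines(xs, comp, col = "steelblue", lwd = 1.5, lty = 2)
    dens <- dens + comp
  }
  graphics::lines(xs, dens, col = "firebrick", lwd = 2)
  graphics::abline(v = c(fit$lo, fit$hi), col = "grey30", lty = 3)
  invisible(NULL)
}

#' Funnel scatter of FL vs PTP scores colored by region
#'
#' @param funnel A [funnel_table()] data.frame.
#' @param main Plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_funnel <- function(funnel, main = "FL vs PTP enrichment") {
  regions <- c("I", "II", "III", "IV", "neutral", "unclassified")
  cols <- stats::setNames(
    c("#D55E00", "#0072B2", "#009E73", "#CC79A7", "grey70", "grey40"),
    regions)
  col <- cols[ifelse(is.na(funnel$region), "unclassified", funnel$region)]
  graphics::plot(funnel$ptp_score, funnel$fl_score, col = col, pch = 16,
                 cex = 0.5, xlab = "PTP-domain score (strong kinase)",
                 ylab = "full-length score (weak kinase)", main = main)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::legend("topleft", legend = regions, col = cols, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(NULL)
}

#' Image plot of a heatmap matrix
#'
#' @param hm A [heatmap_matrix()] result.
#' @param main Plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_heatmap <- function(hm, main = "Enrichment heatmap") {
  m <- hm$score
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::hcl.colors(51, "Blue-Red 3"),
                  xlab = "position", ylab = "", axes = FALSE, main = main)
  graphics::axis(1)
  graphics::axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  invisible(NULL)
}
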