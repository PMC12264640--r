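cpcub_category_colors <- function() {
  c(photosynthesis = "#2E7D32", `self-replication` = "#1565C0",
    other = "#EF6C00", unknown = "#757575")
}

#' Diagnostic plots for codon-usage bias
#'
#' Base-graphics versions of the four standard diagnostics, coloured by
#' functional category: the ENC-plot with the mutation-pressure expected
#' curve, the PR2 scatter with centre lines, the neutrality scatter with
#' its fitted line, and the ENC-ratio histogram.
#'
#' @param table A [gene_metrics_table()] result.
#' @param ... Passed to the underlying plot call.
#' @return Invisibly, `NULL`; called for the side effect.
#' @export
plot_enc <- function(table, ...) {
  cols <- cpcub_category_colors()
  plot(table$gc3s, table$enc_obs, col = cols[table$category], pch = 19,
       xlab = "GC3s (synonymous third-position GC)", ylab = "ENC",
       xlim = c(0, 1), ylim = c(20, 62), ...)
  g <- seq(0.01, 0.99, by = 0.01)
  graphics::lines(g, pmin(enc_expected(g), 61), lwd = 2)
  graphics::legend("bottomright", legend = names(cols), col = cols,
                   pch = 19, cex = 0.8, bty = "n")
  invisible(NULL)
}

#' @rdname plot_enc
#' @export
plot_pr2 <- function(table, ...) {
  cols <- cpcub_category_colors()
  plot(table$pr2_x, table$pr2_y, col = cols[table$category], pch = 19,
       xlab = "G3 / (G3 + C3)", ylab = "A3 / (A3 + T3)",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 2)
  invisible(NULL)
}

#' @rdname plot_enc
#' @param fit Optional [neutrality_fit()]; computed from `table` if absent.
#' @export
plot_neutrality <- function(table, fit = NULL, ...) {
  if (is.null(fit)) fit <- neutrality_fit(table)
  cols <- cpcub_category_colors()
  plot(table$gc3, table$gc12, col = cols[table$category], pch = 19,
       xlab = "GC3", ylab = "GC12", ...)
  graphics::abline(a = fit$intercept, b = fit$slope, lwd = 2)
  graphics::abline(a = 0, b = 1, lty = 3)
  invisible(NULL)
}

#' @rdname plot_enc
#' @param hist An [enc_ratio_histogram()] result; computed if absent.
#' @export
plot_enc_ratio_hist <- function(table, hist = NULL, ...) {
  if (is.null(hist)) hist <- enc_ratio_histogram(table)
  mids <- (utils::head(hist$breaks, -1) + utils::tail(hist$breaks, -1)) / 2
  graphics::barplot(hist$counts, names.arg = sprintf("%.2f", mids),
                    xlab = "ENC ratio", ylab = "genes", ...)
  invisible(NULL)
}
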