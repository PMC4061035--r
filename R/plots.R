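# Standard chemometric displays: scores plot with the Hotelling ellipse,
# back-scaled loadings "pseudo-spectrum", and the enrichment bubble plot.

#' Scores plot with 95% Hotelling ellipse
#'
#' @param model a `"latent_model"`; for OPLS-DA the predictive score is
#'   plotted against the first orthogonal score.
#' @param groups optional factor colouring the samples.
#' @param alpha confidence level of the ellipse.
#' @param ... passed to [graphics::plot()].
#' @export
plot_scores <- function(model, groups = NULL, alpha = 0.05, ...) {
  T <- if (model$kind == "OPLS-DA" && length(model$scores_orth))
    cbind(model$scores[, 1], model$scores_orth[, 1])
  else model$scores[, 1:2]
  labs <- if (model$kind == "OPLS-DA") c("t[1]", "to[1]") else c("t[1]", "t[2]")
  col <- if (is.null(groups)) 1 else as.integer(factor(groups)) + 1
  graphics::plot(T[, 1], T[, 2], col = col, pch = 19,
                 xlab = labs[1], ylab = labs[2], ...)
  N <- nrow(T)
  v <- apply(T, 2, stats::var)
  lim <- 2 * (N^2 - 1) / (N * (N - 2)) * stats::qf(1 - alpha, 2, N - 2)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(sqrt(lim * v[1]) * cos(th), sqrt(lim * v[2]) * sin(th),
                  lty = 2)
  invisible(T)
}

#' Back-scaled loadings plot
#'
#' Plots the back-scaled loading profile against chemical shift (axis
#' reversed, as a spectrum) with point colour encoding the model weight.
#'
#' @param series a [backscale_loadings()] data frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot_backscaled <- function(series, ...) {
  pal <- grDevices::colorRampPalette(c("grey70", "orange", "red"))(100)
  w <- series$weight
  col <- pal[pmax(1, ceiling(99 * (w - min(w)) / (max(w) - min(w) + 1e-12)) + 1)]
  graphics::plot(series$bucket, series$backscaled, type = "h", col = col,
                 xlim = rev(range(series$bucket)),
                 xlab = "chemical shift (ppm)", ylab = "back-scaled loading",
                 ...)
  invisible(series)
}

#' Enrichment bubble plot
#'
#' Pathway impact (horizontal) against fold enrichment -ln(P) (vertical);
#' circle size tracks impact and significant pathways (P < 0.05) are
#' numbered.
#'
#' @param results an `"enrichment_result"` table.
#' @param ... passed to [graphics::plot()].
#' @export
plot_enrichment <- function(results, ...) {
  graphics::plot(results$impact, results$fold_enrichment,
                 cex = 1 + 3 * results$impact,
                 pch = 21, bg = ifelse(results$significant, "tomato", "grey80"),
                 xlab = "pathway impact", ylab = "-ln(P)", ...)
  sig <- which(results$significant)
  if (length(sig))
    graphics::text(results$impact[sig], results$fold_enrichment[sig],
                   labels = sig, pos = 3, cex = 0.8)
  invisible(results)
}
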