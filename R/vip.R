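#' Variable importance in the projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a[ SSY_a * w_ja^2 ] / sum_a SSY_a )` with
#' unit-norm component weights `w_a` and `SSY_a` the Y-variance explained
#' by component a. The mean squared VIP over variables is exactly 1, so
#' VIP > 1 marks variables with above-average influence on the response.
#' For OPLS-DA models the VIP is computed on the predictive component
#' (the part of the model that carries the class information).
#'
#' @param model a supervised `"latent_model"` (PLS-DA or OPLS-DA).
#' @return named numeric vector of VIPs (names from the X columns when
#'   available).
#' @export
compute_vip <- function(model) {
  if (model$kind == "PCA")
    stop("VIP is defined for supervised models only")
  if (model$kind == "PLS-DA") {
    W <- model$fit$weights
    ssy <- model$fit$r2y                     # proportional to explained SSY
    p <- nrow(W)
    num <- drop(W^2 %*% ssy)
    vip <- sqrt(p * num / sum(ssy))
    names(vip) <- rownames(W)
  } else {                                   # OPLS-DA: predictive component
    w <- drop(model$fit$weights)
    vip <- sqrt(length(w) * w^2)
    names(vip) <- names(w)
  }
  vip
}

#' Back-scaled loadings for spectrum-like plotting
#'
#' Multiplies each bucket's model loading by the bucket's pre-scaling
#' standard deviation, undoing the Pareto scaling so the loadings profile
#' resembles a spectrum; the absolute model weight is attached as the
#' colour value conventionally superimposed on such plots. Buckets are
#' ordered by descending chemical shift.
#'
#' @param model a supervised `"latent_model"`.
#' @param table the Pareto-scaled `"bucket_table"` the model was fitted on
#'   (it stores the per-bucket SDs).
#' @param component which predictive component (default 1).
#' @return data frame `bucket` (center shift), `loading`,
#'   `backscaled`, `weight`, sorted by descending shift.
#' @export
backscale_loadings <- function(model, table, component = 1) {
  if (!inherits(table, "bucket_table") || !identical(table$scaling, "pareto"))
    stop("table must be Pareto scaled (per-bucket SDs are required)")
  sdv <- table$col_sd
  p <- model$loadings[, component]
  w <- model$weights[, component]
  df <- data.frame(bucket = table$centers, loading = p,
                   backscaled = p * sdv, weight = abs(w))
  df[order(-df$bucket), ]
}
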