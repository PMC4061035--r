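# Latent-variable modelling: NIPALS PCA, PLS2 and O-PLS, with the
# supporting bookkeeping (R2X/R2Y accounting, sign convention, prediction).

as_x_matrix <- function(table) {
  if (inherits(table, "bucket_table")) table$X else as.matrix(table)
}

# Build the 0/1 response table for a comparison from sample metadata.
# wild-type = 0 / Callipyge = 1; 8 wk = 0 / 12 wk = 1; M = 0 / F = 1.
#' Class (Y) table for a supervised comparison
#'
#' @param meta data frame with `genotype`, `age_wk`, `gender` columns.
#' @param comparison one or more of `"genotype"`, `"age"`, `"gender"`;
#'   each becomes a 0/1 column (Callipyge, 12 weeks and female coded 1).
#' @return numeric matrix, samples x responses.
#' @export
class_table <- function(meta, comparison) {
  cols <- lapply(comparison, function(cc) {
    switch(cc,
           genotype = as.numeric(meta$genotype == "NC"),
           age = as.numeric(meta$age_wk == 12),
           gender = as.numeric(meta$gender == "F"),
           stop("unknown comparison: ", cc))
  })
  Y <- do.call(cbind, cols)
  colnames(Y) <- comparison
  Y
}

fix_sign <- function(scores, loadings) {
  # reproducible orientation: the loading of largest magnitude is positive
  s <- sign(loadings[which.max(abs(loadings))])
  if (s < 0) list(t = -scores, p = -loadings) else list(t = scores, p = loadings)
}

.pca_fit <- function(X, ncomp, center = TRUE, tol = 1e-12, maxit = 500) {
  X <- as.matrix(X)
  x_mean <- if (center) colMeans(X) else rep(0, ncol(X))
  E <- sweep(X, 2, x_mean)
  ssx <- sum(E^2)
  n <- nrow(E); p <- ncol(E)
  if (ncomp > min(n - 1, p)) stop("too many components for the data dimensions")
  T <- matrix(0, n, ncomp); P <- matrix(0, p, ncomp)
  r2x <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    t <- E[, which.max(colSums(E^2))]
    if (sum(t^2) < tol * ssx) { ncomp <- a - 1; break }
    for (it in seq_len(maxit)) {
      pv <- drop(crossprod(E, t)) / sum(t^2)
      pv <- pv / sqrt(sum(pv^2))
      t_new <- drop(E %*% pv)
      if (sum((t_new - t)^2) < tol * sum(t_new^2)) { t <- t_new; break }
      t <- t_new
    }
    fs <- fix_sign(t, pv)
    t <- fs$t; pv <- fs$p
    E <- E - tcrossprod(t, pv)
    T[, a] <- t; P[, a] <- pv
    r2x[a] <- sum(t^2) / ssx
  }
  T <- T[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  list(x_mean = x_mean, scores = T, loadings = P, r2x = r2x[seq_len(ncomp)],
       ssx = ssx, ncomp = ncomp)
}

.pls_fit <- function(X, Y, ncomp, tol = 1e-12, maxit = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  E <- sweep(X, 2, x_mean); F_ <- sweep(Y, 2, y_mean)
  if (all(abs(F_) < 1e-14)) stop("degenerate response: Y is constant")
  ssx <- sum(E^2); ssy <- sum(F_^2)
  n <- nrow(E); p <- ncol(E); m <- ncol(F_)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, m, ncomp); T <- matrix(0, n, ncomp)
  r2x <- r2y <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- F_[, which.max(colSums(F_^2))]
    if (sum(u^2) < tol * ssy) { ncomp <- a - 1; break }
    t <- u
    for (it in seq_len(maxit)) {
      w <- drop(crossprod(E, u))
      w <- w / sqrt(sum(w^2))
      t_new <- drop(E %*% w)
      cvec <- drop(crossprod(F_, t_new)) / sum(t_new^2)
      u <- drop(F_ %*% cvec) / sum(cvec^2)
      if (sum((t_new - t)^2) < tol * sum(t_new^2)) { t <- t_new; break }
      t <- t_new
    }
    pv <- drop(crossprod(E, t)) / sum(t^2)
    W[, a] <- w; P[, a] <- pv; C[, a] <- cvec; T[, a] <- t
    r2x[a] <- sum(t^2) * sum(pv^2) / ssx
    r2y[a] <- sum(t^2) * sum(cvec^2) / ssy
    E <- E - tcrossprod(t, pv)
    F_ <- F_ - tcrossprod(t, cvec)
  }
  keep <- seq_len(ncomp)
  list(x_mean = x_mean, y_mean = y_mean,
       weights = W[, keep, drop = FALSE], loadings = P[, keep, drop = FALSE],
       y_weights = C[, keep, drop = FALSE], scores = T[, keep, drop = FALSE],
       r2x = r2x[keep], r2y = r2y[keep], ssx = ssx, ssy = ssy, ncomp = ncomp)
}

.pls_predict <- function(fit, Xnew) {
  E <- sweep(as.matrix(Xnew), 2, fit$x_mean)
  n <- nrow(E)
  Yhat <- matrix(rep(fit$y_mean, each = n), n)
  for (a in seq_len(fit$ncomp)) {
    t <- drop(E %*% fit$weights[, a])
    Yhat <- Yhat + tcrossprod(t, fit$y_weights[, a])
    E <- E - tcrossprod(t, fit$loadings[, a])
  }
  Yhat
}

# Trygg-Wold O-PLS for a single response. The predictive weight is
# recomputed from the deflated X after each orthogonal extraction, which
# makes every orthogonal score exactly uncorrelated with y.
.opls_fit <- function(X, y, n_orth, tol = 1e-12) {
  X <- as.matrix(X); y <- drop(as.matrix(y))
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2, x_mean); f <- y - y_mean
  if (all(abs(f) < 1e-14)) stop("degenerate response: y is constant")
  ssx <- sum(E^2); ssy <- sum(f^2)
  p <- ncol(E); n <- nrow(E)
  if (n_orth >= min(n - 1, p)) stop("n_orth >= rank of X")
  W_o <- matrix(0, p, n_orth); P_o <- matrix(0, p, n_orth)
  T_o <- matrix(0, n, n_orth)
  r2x_orth <- numeric(n_orth)
  for (o in seq_len(n_orth)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    pv <- drop(crossprod(E, t)) / sum(t^2)
    w_o <- pv - drop(crossprod(w, pv)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < tol) stop("no orthogonal variation left to extract")
    w_o <- w_o / nw
    t_o <- drop(E %*% w_o)
    p_o <- drop(crossprod(E, t_o)) / sum(t_o^2)
    E <- E - tcrossprod(t_o, p_o)
    W_o[, o] <- w_o; P_o[, o] <- p_o; T_o[, o] <- t_o
    r2x_orth[o] <- sum(t_o^2) * sum(p_o^2) / ssx
  }
  w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
  t <- drop(E %*% w)
  pv <- drop(crossprod(E, t)) / sum(t^2)
  cc <- sum(f * t) / sum(t^2)
  fs <- fix_sign(t, pv)
  if (!identical(fs$t, t)) { t <- fs$t; pv <- fs$p; w <- -w; cc <- -cc }
  list(x_mean = x_mean, y_mean = y_mean,
       weights = w, loadings = pv, y_weight = cc, scores = t,
       weights_orth = W_o, loadings_orth = P_o, scores_orth = T_o,
       r2x_pred = sum(t^2) * sum(pv^2) / ssx, r2x_orth = r2x_orth,
       r2y = sum((t * cc)^2) / ssy, ssx = ssx, ssy = ssy, n_orth = n_orth)
}

.opls_predict <- function(fit, Xnew) {
  E <- sweep(as.matrix(Xnew), 2, fit$x_mean)
  for (o in seq_len(fit$n_orth)) {
    t_o <- drop(E %*% fit$weights_orth[, o])
    E <- E - tcrossprod(t_o, fit$loadings_orth[, o])
  }
  t <- drop(E %*% fit$weights)
  list(yhat = t * fit$y_weight + fit$y_mean, scores = t)
}

new_latent_model <- function(kind, fit, extra = list()) {
  structure(c(list(kind = kind, fit = fit), extra), class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat("<latent_model>", x$kind)
  if (!is.null(x$structure)) cat(" A:", x$structure)
  if (!is.null(x$r2x)) cat(sprintf("  R2X = %.3f", sum(x$r2x)))
  if (!is.null(x$r2y)) cat(sprintf("  R2Y = %.3f", sum(x$r2y)))
  if (!is.null(x$q2)) cat(sprintf("  Q2 = %.3f", x$q2))
  cat("\n")
  invisible(x)
}

#' Principal components analysis (NIPALS)
#'
#' Fits successive principal components by the NIPALS power iteration,
#' matching a singular value decomposition up to sign (the sign convention
#' fixes the largest-magnitude loading positive). Used for the initial
#' sample-outlier screen of the pipeline.
#'
#' @param table a `"bucket_table"` (ordinarily Pareto scaled) or plain
#'   matrix.
#' @param n_components number of components.
#' @param center center columns before decomposition (default TRUE; a
#'   Pareto-scaled table is already centered, in which case this is a
#'   no-op).
#' @return `"latent_model"` of kind `"PCA"` with `scores`, `loadings`,
#'   per-component `r2x`.
#' @export
fit_pca <- function(table, n_components = 2, center = TRUE) {
  X <- as_x_matrix(table)
  fit <- .pca_fit(X, n_components, center = center)
  rownames(fit$loadings) <- colnames(X)
  new_latent_model("PCA", fit,
                   list(scores = fit$scores, loadings = fit$loadings,
                        r2x = fit$r2x, sample_ids = rownames(X),
                        n_components = fit$ncomp))
}

#' Hotelling T-squared outlier detection
#'
#' Computes each sample's Hotelling T2 over the model's score space,
#' `T2_i = sum_a t_ia^2 / var(t_a)`, and flags samples beyond the
#' F-distribution-based confidence bound
#' `A (N^2 - 1) / (N (N - A)) * F(1 - alpha; A, N - A)` (the ellipse
#' convention of standard chemometrics software).
#'
#' @param model a fitted [fit_pca()] (or other latent) model.
#' @param alpha significance level of the confidence range (0.05 gives the
#'   95% ellipse).
#' @return list with `t2` (named vector), `threshold`, `flagged` (sample
#'   ids), `alpha`.
#' @export
hotelling_outliers <- function(model, alpha = 0.05) {
  T <- model$scores
  A <- ncol(T); N <- nrow(T)
  if (A < 1) stop("model has no components")
  if (N <= A) stop("Hotelling threshold undefined for N <= A")
  v <- apply(T, 2, stats::var)
  t2 <- rowSums(sweep(T^2, 2, v, "/"))
  names(t2) <- model$sample_ids
  threshold <- A * (N^2 - 1) / (N * (N - A)) *
    stats::qf(1 - alpha, A, N - A)
  list(t2 = t2, threshold = threshold,
       flagged = names(t2)[t2 > threshold], alpha = alpha)
}

#' Partial least squares discriminant analysis (PLS2 NIPALS)
#'
#' Regresses the bucket matrix against a 0/1 class table using the NIPALS
#' PLS2 algorithm with unit-norm X-weights. When `n_components` is omitted
#' the component count is chosen by 7-fold cross-validation (the component
#' count with maximal cumulative Q2).
#'
#' @param table `"bucket_table"` or matrix.
#' @param y class matrix from [class_table()] (or a numeric vector).
#' @param n_components number of PLS components, or `NULL` to optimize by
#'   cross-validation.
#' @param max_components search bound when optimizing.
#' @param k_folds folds for the optimization.
#' @return `"latent_model"` of kind `"PLS-DA"`.
#' @export
fit_pls_da <- function(table, y, n_components = NULL, max_components = 6,
                       k_folds = 7) {
  X <- as_x_matrix(table)
  Y <- as.matrix(y)
  if (any(apply(Y, 2, stats::sd) == 0))
    stop("degenerate response: constant y column")
  if (is.null(n_components)) {
    amax <- min(max_components, nrow(X) - 2, ncol(X))
    q2 <- vapply(seq_len(amax), function(a)
      cross_validate(X, Y, method = "plsda", n_components = a,
                     k_folds = k_folds)$q2, 0)
    n_components <- which.max(q2)
  }
  fit <- .pls_fit(X, Y, n_components)
  rownames(fit$loadings) <- rownames(fit$weights) <- colnames(X)
  new_latent_model("PLS-DA", fit,
                   list(scores = fit$scores, loadings = fit$loadings,
                        weights = fit$weights, y_weights = fit$y_weights,
                        r2x = fit$r2x, r2y = fit$r2y,
                        sample_ids = rownames(X),
                        n_components = fit$ncomp,
                        structure = as.character(fit$ncomp)))
}

#' Orthogonal PLS discriminant analysis (O-PLS)
#'
#' Trygg-Wold O-PLS for a single 0/1 response: orthogonal components
#' (variation in X uncorrelated with y) are stripped before the single
#' predictive component is fitted, giving models labelled
#' `"1+n_orth+0"`. With `n_orth = 0` the model coincides with a
#' one-component PLS.
#'
#' @param table `"bucket_table"` or matrix.
#' @param y single 0/1 response (vector or one-column matrix).
#' @param n_orth number of X-orthogonal components.
#' @return `"latent_model"` of kind `"OPLS-DA"` with predictive
#'   `scores`/`loadings`/`weights`, orthogonal `scores_orth` etc., and the
#'   R2X split into predictive and orthogonal parts.
#' @export
fit_opls_da <- function(table, y, n_orth = 1) {
  X <- as_x_matrix(table)
  y <- drop(as.matrix(y))
  if (NCOL(y) != 1) stop("OPLS-DA takes a single response column")
  fit <- .opls_fit(X, y, n_orth)
  fit$loadings <- stats::setNames(fit$loadings, colnames(X))
  fit$weights <- stats::setNames(fit$weights, colnames(X))
  new_latent_model("OPLS-DA", fit,
                   list(scores = cbind(fit$scores), loadings = cbind(fit$loadings),
                        weights = cbind(fit$weights),
                        scores_orth = fit$scores_orth,
                        loadings_orth = fit$loadings_orth,
                        r2x = fit$r2x_pred, r2x_orth = fit$r2x_orth,
                        r2y = fit$r2y, sample_ids = rownames(X),
                        n_orth = n_orth,
                        structure = sprintf("1+%d+0", n_orth)))
}

#' Predict responses from a fitted supervised latent model
#'
#' @param object a `"latent_model"` of kind PLS-DA or OPLS-DA.
#' @param newdata matrix or `"bucket_table"` with the same buckets.
#' @param ... unused.
#' @return predicted response matrix (PLS-DA) or vector (OPLS-DA).
#' @export
predict.latent_model <- function(object, newdata, ...) {
  X <- as_x_matrix(newdata)
  switch(object$kind,
         "PLS-DA" = .pls_predict(object$fit, X),
         "OPLS-DA" = .opls_predict(object$fit, X)$yhat,
         stop("prediction not defined for ", object$kind))
}
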