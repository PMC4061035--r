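# Model validation: stratified venetian-blinds cross-validation (Q2),
# permutation testing, and CV-ANOVA.

# Deterministic fold assignment: samples ordered by (class of the first
# response, id) and dealt round-robin across folds ("venetian blinds").
assign_folds <- function(y, ids, k) {
  y1 <- as.matrix(y)[, 1]
  ord <- order(y1, ids)
  folds <- integer(length(ids))
  folds[ord] <- rep_len(seq_len(k), length(ids))
  folds
}

#' Cross-validated predictive ability Q2
#'
#' Runs k-fold cross-validation with deterministic, class-stratified
#' venetian-blinds fold assignment (samples sorted by class then id and
#' dealt round-robin) and reports `Q2 = 1 - PRESS / SS`, with PRESS summed
#' over held-out predictions and `SS = sum((y - mean(y))^2)`.
#'
#' @param table `"bucket_table"` or matrix.
#' @param y response matrix (PLS-DA) or single column (OPLS-DA).
#' @param method `"plsda"` or `"oplsda"`.
#' @param n_components PLS components (plsda).
#' @param n_orth orthogonal components (oplsda).
#' @param k_folds number of folds (the chemometrics default of 7).
#' @return list with `q2`, `press`, `ss`, `predictions` (held-out),
#'   `folds`, `n`, `n_param` (total fitted components, used by
#'   [cv_anova()]).
#' @export
cross_validate <- function(table, y, method = c("plsda", "oplsda"),
                           n_components = 1, n_orth = 0, k_folds = 7) {
  method <- match.arg(method)
  X <- as_x_matrix(table)
  Y <- as.matrix(y)
  n <- nrow(X)
  if (k_folds < 2) stop("k_folds must be >= 2")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(n))
  folds <- assign_folds(Y, ids, k_folds)
  pred <- matrix(NA_real_, n, ncol(Y))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    Ytr <- Y[tr, , drop = FALSE]
    if (any(apply(Ytr, 2, function(col) length(unique(col)) < 2)))
      stop("stratification failure: a class is absent from a training fold")
    if (method == "plsda") {
      fit <- .pls_fit(X[tr, , drop = FALSE], Ytr, n_components)
      pred[!tr, ] <- .pls_predict(fit, X[!tr, , drop = FALSE])
    } else {
      fit <- .opls_fit(X[tr, , drop = FALSE], Ytr[, 1], n_orth)
      pred[!tr, 1] <- .opls_predict(fit, X[!tr, , drop = FALSE])$yhat
    }
  }
  press <- sum((Y - pred)^2)
  ss <- sum(sweep(Y, 2, colMeans(Y))^2)
  n_param <- if (method == "plsda") n_components else 1 + n_orth
  list(q2 = 1 - press / ss, press = press, ss = ss, predictions = pred,
       folds = folds, n = n, n_param = n_param, method = method)
}

#' Permutation test of a supervised model
#'
#' Refits the model `n_perm` times under random row permutations of the
#' response (the identity permutation is excluded) and records, per
#' permutation, the absolute correlation of the permuted with the original
#' response, R2Y and cross-validated Q2. The empirical p-value uses the
#' add-one estimator `p = (#(Q2_perm >= Q2_orig) + 1) / (n_perm + 1)`;
#' intercepts of the R2Y and Q2 regression lines against the correlation
#' (through the original model at correlation 1) are reported for
#' validation plots.
#'
#' @inheritParams cross_validate
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return list of class `"validation_record"`: `permutations` data frame
#'   (`cor`, `r2y`, `q2`), `r2y_orig`, `q2_orig`, `p_value`,
#'   `intercept_r2`, `intercept_q2`.
#' @export
permutation_test <- function(table, y, method = c("plsda", "oplsda"),
                             n_components = 1, n_orth = 0, k_folds = 7,
                             n_perm = 200, seed = 1L) {
  method <- match.arg(method)
  X <- as_x_matrix(table)
  Y <- as.matrix(y)
  n <- nrow(X)
  if (n_perm < 1) stop("n_perm must be >= 1")
  fit_stats <- function(Yk) {
    cv <- cross_validate(X, Yk, method = method, n_components = n_components,
                         n_orth = n_orth, k_folds = k_folds)
    r2y <- if (method == "plsda")
      sum(.pls_fit(X, Yk, n_components)$r2y)
    else .opls_fit(X, Yk[, 1], n_orth)$r2y
    c(r2y = r2y, q2 = cv$q2)
  }
  orig <- fit_stats(Y)
  set.seed(seed)
  res <- matrix(NA_real_, n_perm, 3,
                dimnames = list(NULL, c("cor", "r2y", "q2")))
  for (b in seq_len(n_perm)) {
    repeat {
      idx <- sample.int(n)
      if (!all(idx == seq_len(n))) break
    }
    Yp <- Y[idx, , drop = FALSE]
    cor_b <- mean(abs(diag(stats::cor(Yp, Y))))
    st <- fit_stats(Yp)
    res[b, ] <- c(cor_b, st["r2y"], st["q2"])
  }
  perms <- as.data.frame(res)
  p_value <- (sum(perms$q2 >= orig["q2"]) + 1) / (n_perm + 1)
  # regression lines through the permuted points and the original at cor = 1
  xs <- c(perms$cor, 1)
  int_r2 <- stats::coef(stats::lm(c(perms$r2y, orig["r2y"]) ~ xs))[1]
  int_q2 <- stats::coef(stats::lm(c(perms$q2, orig["q2"]) ~ xs))[1]
  structure(list(permutations = perms,
                 r2y_orig = unname(orig["r2y"]), q2_orig = unname(orig["q2"]),
                 p_value = p_value,
                 intercept_r2 = unname(int_r2), intercept_q2 = unname(int_q2),
                 n_perm = n_perm, seed = seed),
            class = "validation_record")
}

#' @export
print.validation_record <- function(x, ...) {
  cat(sprintf(
    "<validation_record> %d permutations: R2Y = %.3f, Q2 = %.3f, p = %.4g\n",
    x$n_perm, x$r2y_orig, x$q2_orig, x$p_value))
  invisible(x)
}

#' CV-ANOVA significance test of a cross-validated model
#'
#' F-test comparing the cross-validated residuals against the total
#' response variation:
#' `F = [(SS - PRESS) / df1] / [PRESS / df2]` with `df1 = 2A + 1` (A the
#' total number of fitted components, predictive plus orthogonal) and
#' `df2 = (N - 1) - df1`, P from `F(df1, df2)`. When the model does not
#' improve on the mean (`PRESS >= SS`) the p-value is 1.
#'
#' @param cv a [cross_validate()] result.
#' @param y the response used (only its length is needed; optional).
#' @return list `f`, `df1`, `df2`, `p_value`, `press`, `ss`.
#' @export
cv_anova <- function(cv, y = NULL) {
  N <- cv$n
  df1 <- 2 * cv$n_param + 1
  df2 <- (N - 1) - df1
  if (df2 <= 0) stop("too few samples for CV-ANOVA with ", cv$n_param,
                     " components")
  if (cv$press >= cv$ss) {
    return(list(f = 0, df1 = df1, df2 = df2, p_value = 1,
                press = cv$press, ss = cv$ss))
  }
  f <- ((cv$ss - cv$press) / df1) / (cv$press / df2)
  list(f = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       press = cv$press, ss = cv$ss)
}
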