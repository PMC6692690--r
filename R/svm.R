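# Two-class C-SVC with a polynomial kernel, solved by SMO (src/smo.cpp).
# Written from scratch because the evaluation protocol needs LIBSVM-style
# behaviour (degree-3 polynomial kernel) and no SVM library is available.

#' Polynomial kernel matrix
#'
#' `K(x, z) = (gamma * <x, z> + coef0) ^ degree`, the LIBSVM convention.
#'
#' @param x,z Numeric matrices with matching column counts (rows are
#'   samples).
#' @param degree,gamma,coef0 Kernel parameters.
#' @return The `nrow(x) x nrow(z)` kernel matrix.
#' @export
poly_kernel <- function(x, z, degree = 3, gamma = 1 / ncol(x), coef0 = 0) {
  (gamma * tcrossprod(x, z) + coef0)^degree
}

#' Fit a two-class polynomial-kernel SVM
#'
#' Soft-margin C-SVC solved by sequential minimal optimisation with
#' maximal-violating-pair working-set selection.  Defaults:
#' `gamma = 1/n_features` and `cost = 1` (LIBSVM conventions) with
#' `coef0 = 1`, the inhomogeneous polynomial kernel.  The offset matters:
#' with `coef0 = 0` and standardized features the Gram matrix degenerates
#' to near-diagonal, decision values for unseen points collapse to the
#' intercept, and evaluation on uninformative features locks onto one
#' class instead of behaving at chance (see the methods vignette).
#'
#' @param x Numeric matrix of training samples (rows).
#' @param y Labels: a two-level factor (second level is the positive
#'   class), or a vector coercible to \{-1, +1\}.
#' @param degree Polynomial degree (default 3).
#' @param cost Soft-margin penalty C (default 1).
#' @param gamma Kernel scale (default `1/ncol(x)`).
#' @param coef0 Kernel offset (default 1).
#' @param eps KKT violation tolerance for the solver (default 1e-3).
#' @param max_iter Iteration cap (default `200 * max(n, 50)`).
#' @return An object of class `poly_svm` holding the support vectors, dual
#'   coefficients and intercept.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
#' y <- factor(rep(c("a", "b"), each = 20))
#' fit <- svm_fit(x, y)
#' table(svm_predict(fit, x), y)
#' @export
svm_fit <- function(x, y, degree = 3, cost = 1, gamma = 1 / ncol(x),
                    coef0 = 1, eps = 1e-3, max_iter = NULL) {
  x <- as.matrix(x)
  if (is.factor(y)) {
    lev <- levels(y)
    if (length(lev) != 2L) stop("`y` must have exactly two levels")
    yi <- ifelse(as.integer(y) == 2L, 1L, -1L)
  } else {
    u <- sort(unique(y))
    if (length(u) != 2L) stop("`y` must contain exactly two classes")
    lev <- as.character(u)
    yi <- ifelse(y == u[2L], 1L, -1L)
  }
  n <- nrow(x)
  if (length(yi) != n) stop("length(y) must equal nrow(x)")
  if (is.null(max_iter)) max_iter <- 200L * max(n, 50L)
  K <- poly_kernel(x, x, degree, gamma, coef0)
  sol <- smo_solve(K, as.integer(yi), cost, eps, as.integer(max_iter))
  sv <- which(sol$alpha > 1e-12)
  structure(list(sv = x[sv, , drop = FALSE],
                 coefs = sol$alpha[sv] * yi[sv],
                 rho = sol$rho, levels = lev, degree = degree,
                 gamma = gamma, coef0 = coef0, cost = cost,
                 iterations = sol$iterations, gap = sol$gap),
            class = "poly_svm")
}

#' Predict with a fitted polynomial-kernel SVM
#'
#' @param model A `poly_svm` from [svm_fit()].
#' @param newx Numeric matrix of samples to classify.
#' @param decision Return raw decision values instead of labels.
#' @return Factor of predicted labels (levels as in training), or numeric
#'   decision values when `decision = TRUE` (positive favours the second
#'   training level).
#' @export
svm_predict <- function(model, newx, decision = FALSE) {
  newx <- as.matrix(newx)
  if (nrow(model$sv) == 0L) {
    f <- rep(-model$rho, nrow(newx))
  } else {
    K <- poly_kernel(newx, model$sv, model$degree, model$gamma, model$coef0)
    f <- as.vector(K %*% model$coefs) - model$rho
  }
  if (decision) return(f)
  factor(model$levels[(f > 0) + 1L], levels = model$levels)
}

#' @export
print.poly_svm <- function(x, ...) {
  cat(sprintf(
    "<poly_svm> degree %d, cost %g, gamma %g; %d support vectors (%d iterations)\n",
    x$degree, x$cost, x$gamma, nrow(x$sv), x$iterations))
  invisible(x)
}
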