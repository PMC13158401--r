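#' Smallest penalty that zeroes every coefficient
#'
#' For the mean negative log-likelihood + `lambda * sum(|beta|)` objective
#' with an unpenalized intercept, all marker coefficients are zero exactly
#' when `lambda >= max_j |(1/n) sum_i x_ij (y_i - ybar)|`.
#'
#' @param X numeric matrix of standardized markers.
#' @param y binary response vector.
#' @return The critical penalty `lambda_max`.
#' @export
lambda_max <- function(X, y) {
  max(abs(crossprod(X, y - mean(y)))) / length(y)
}

#' Fit an L1-penalized logistic regression
#'
#' Minimizes `(1/n) * sum(log(1 + exp(eta)) - y * eta) + lambda * sum(|beta|)`
#' with an unpenalized intercept, by iteratively reweighted least squares
#' with inner coordinate descent. Convergence is declared when the
#' Karush-Kuhn-Tucker residual of the objective falls below `tol`, so the
#' returned solution satisfies `|grad_j| <= lambda + tol` at every zero
#' coefficient and `|grad_j + lambda * sign(beta_j)| <= tol` elsewhere.
#'
#' @param X numeric matrix (patients x markers), complete and standardized.
#' @param y binary vector (0 = HCC, 1 = iCCA); both classes required.
#' @param lambda non-negative penalty.
#' @param tol KKT convergence tolerance (default 1e-8).
#' @param max_iter outer iteration cap (default 1e5).
#' @param init optional list with `beta0`, `beta` warm start.
#' @return An `l1_logistic` object: `intercept`, named `coefficients`,
#'   `lambda`, `iterations`, `converged`, `kkt`.
#' @export
fit_l1_logistic <- function(X, y, lambda, tol = 1e-8, max_iter = 1e5,
                            init = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("l1 fit error: X contains missing values")
  if (length(unique(y)) < 2) stop("l1 fit error: single-class response")
  if (lambda < 0) stop("l1 fit error: lambda must be non-negative")
  b0 <- if (is.null(init)) 0 else init$beta0
  b <- if (is.null(init)) numeric(ncol(X)) else init$beta
  fit <- l1_logistic_cd(X, as.double(y), lambda, tol, as.integer(max_iter),
                        b0, as.double(b))
  if (!fit$converged) {
    stop(sprintf(paste0("l1 fit error: no convergence within %d iterations ",
                        "(KKT residual %.3e, lambda %.3e)"),
                 as.integer(max_iter), fit$kkt, lambda))
  }
  structure(list(intercept = fit$beta0,
                 coefficients = stats::setNames(fit$beta, colnames(X)),
                 lambda = lambda, iterations = fit$iterations,
                 converged = fit$converged, kkt = fit$kkt),
            class = "l1_logistic")
}

#' @export
print.l1_logistic <- function(x, ...) {
  cat(sprintf("L1 logistic model (lambda = %.4g, %d active of %d markers)\n",
              x$lambda, sum(x$coefficients != 0), length(x$coefficients)))
  cat(sprintf("intercept %.4f\n", x$intercept))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted class-1 probabilities of a logistic model
#'
#' @param model an `l1_logistic` (or `ridge_logistic`) fit.
#' @param X matrix whose columns align with the model coefficients.
#' @return Probability vector in (0, 1).
#' @export
logistic_predict <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !is.null(names(model$coefficients))) {
    if (!all(names(model$coefficients) %in% colnames(X))) {
      stop("prediction error: X columns do not cover model coefficients")
    }
    X <- X[, names(model$coefficients), drop = FALSE]
  } else if (ncol(X) != length(model$coefficients)) {
    stop("prediction error: column count mismatch")
  }
  as.vector(stats::plogis(model$intercept + X %*% model$coefficients))
}

#' Regularization path of the penalized logistic model
#'
#' Fits one model per penalty on a decreasing grid, warm-starting each fit
#' from the previous solution, and records the first grid penalty at which
#' each marker's coefficient becomes non-zero (its entry point).
#'
#' @param X,y as in [fit_l1_logistic()].
#' @param lambda_grid decreasing positive penalties; default 30 log-spaced
#'   values from `lambda_max` down to `0.01 * lambda_max`.
#' @param tol,max_iter passed to [fit_l1_logistic()].
#' @return A `lasso_path` object: `lambda`, coefficient matrix
#'   (grid x markers), `intercepts`, `entry_lambda` per marker (NA if a
#'   marker never enters).
#' @export
lasso_path <- function(X, y, lambda_grid = NULL, tol = 1e-8, max_iter = 1e5) {
  X <- as.matrix(X)
  if (is.null(lambda_grid)) {
    lmax <- lambda_max(X, y)
    lambda_grid <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 30))
  }
  if (is.unsorted(rev(lambda_grid), strictly = TRUE)) {
    stop("path error: lambda_grid must be strictly decreasing")
  }
  p <- ncol(X)
  coefs <- matrix(0, length(lambda_grid), p,
                  dimnames = list(NULL, colnames(X)))
  intercepts <- numeric(length(lambda_grid))
  init <- NULL
  for (k in seq_along(lambda_grid)) {
    fit <- fit_l1_logistic(X, y, lambda_grid[k], tol = tol,
                           max_iter = max_iter, init = init)
    coefs[k, ] <- fit$coefficients
    intercepts[k] <- fit$intercept
    init <- list(beta0 = fit$intercept, beta = fit$coefficients)
  }
  entry <- apply(coefs, 2, function(b) {
    k <- which(b != 0)
    if (length(k)) lambda_grid[min(k)] else NA_real_
  })
  structure(list(lambda = lambda_grid, coefficients = coefs,
                 intercepts = intercepts, entry_lambda = entry),
            class = "lasso_path")
}

#' Penalty selection by stratified cross-validation
#'
#' Splits the training data into `nfolds` class-stratified folds, fits the
#' penalty path on each fold complement (warm-started), scores the held-out
#' fold by AUROC of the predicted probabilities, and returns the penalty
#' with the highest mean held-out AUROC. Ties are broken toward the larger
#' penalty (the sparser model).
#'
#' @param X,y as in [fit_l1_logistic()].
#' @param lambda_grid decreasing penalties; default as in [lasso_path()].
#' @param nfolds number of folds (default 5).
#' @param fold_seed seed fixing the fold assignment.
#' @return List: `lambda` (selected), `lambda_grid`, `cv_auroc` (mean per
#'   penalty).
#' @export
select_lambda_cv <- function(X, y, lambda_grid = NULL, nfolds = 5,
                             fold_seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(lambda_grid)) {
    lmax <- lambda_max(X, y)
    lambda_grid <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 25))
  }
  folds <- withr::with_seed(fold_seed, {
    f <- integer(n)
    for (cls in unique(y)) {
      rows <- which(y == cls)
      f[rows] <- sample(rep_len(seq_len(nfolds), length(rows)))
    }
    f
  })
  auc <- matrix(NA_real_, nfolds, length(lambda_grid))
  for (fd in seq_len(nfolds)) {
    tr <- folds != fd
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
    init <- NULL
    for (k in seq_along(lambda_grid)) {
      fit <- fit_l1_logistic(X[tr, , drop = FALSE], y[tr], lambda_grid[k])
      init <- list(beta0 = fit$intercept, beta = fit$coefficients)
      pr <- logistic_predict(fit, X[!tr, , drop = FALSE])
      auc[fd, k] <- auroc_value(pr, y[!tr])
    }
  }
  mean_auc <- colMeans(auc, na.rm = TRUE)
  best <- which(mean_auc >= max(mean_auc) - 1e-12)[1]  # grid is decreasing
  list(lambda = lambda_grid[best], lambda_grid = lambda_grid,
       cv_auroc = mean_auc)
}

#' Ridge-stabilized logistic refit
#'
#' Newton optimization of `(1/n) * NLL + lambda2/2 * sum(beta^2)` with an
#' unpenalized intercept. The small default ridge term guards against
#' complete separation when refitting on a handful of selected markers in a
#' 40-patient training split.
#'
#' @param X,y as in [fit_l1_logistic()].
#' @param lambda2 ridge penalty (default 1e-4).
#' @param tol gradient tolerance; `max_iter` iteration cap.
#' @param max_iter maximum Newton steps.
#' @return A `ridge_logistic` object with `intercept`, `coefficients`,
#'   `lambda2`, `iterations`, `converged`.
#' @export
fit_ridge_logistic <- function(X, y, lambda2 = 1e-4, tol = 1e-10,
                               max_iter = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  Xa <- cbind(`(Intercept)` = 1, X)
  pen <- c(0, rep(lambda2, p))
  theta <- numeric(p + 1)
  obj <- function(th) {
    eta <- as.vector(Xa %*% th)
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      sum(pen * th^2) / 2
  }
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Xa %*% theta)
    pr <- stats::plogis(eta)
    g <- crossprod(Xa, pr - y) / n + pen * theta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- pmax(pr * (1 - pr), 1e-8)
    H <- crossprod(Xa * w, Xa) / n + diag(pen, p + 1)
    step <- solve(H, g)
    f0 <- obj(theta)
    alpha <- 1
    repeat {
      cand <- theta - alpha * step
      if (obj(cand) <= f0 + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    theta <- theta - alpha * step
  }
  structure(list(intercept = theta[1],
                 coefficients = stats::setNames(theta[-1], colnames(X)),
                 lambda2 = lambda2, iterations = it, converged = converged),
            class = c("ridge_logistic", "l1_logistic"))
}
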