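test_that("penalties at or above lambda_max shrink every coefficient to zero", {
  withr::with_seed(101, {
    X <- matrix(rnorm(40 * 4), 40, 4,
                dimnames = list(NULL, paste0("m", 1:4)))
    y <- rep(c(0, 1), 20)
  })
  lmax <- lambda_max(X, y)
  fit <- fit_l1_logistic(X, y, lmax)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, log(mean(y) / (1 - mean(y))), tolerance = 1e-6)
  # single-class response is rejected
  expect_error(fit_l1_logistic(X, rep(1, 40), 0.1), "single-class")
})

test_that("solver matches a brute-force objective scan on a one-feature toy", {
  x <- matrix(c(-1, -1, 1, 1), ncol = 1)
  y <- c(0, 0, 1, 1)
  lam <- 0.1
  obj <- function(b0, b) {
    eta <- b0 + x[, 1] * b
    mean(log(1 + exp(eta)) - y * eta) + lam * abs(b)
  }
  grid <- seq(-5, 5, by = 1e-3)
  vals <- vapply(grid, function(b) {
    optimize(function(b0) obj(b0, b), c(-10, 10))$objective
  }, numeric(1))
  oracle_beta <- grid[which.min(vals)]
  fit <- fit_l1_logistic(x, y, lam)
  expect_lt(abs(unname(fit$coefficients) - oracle_beta), 1e-2)
  # objective at the solution is no worse than at the null model
  expect_lte(obj(fit$intercept, fit$coefficients),
             obj(log(mean(y) / (1 - mean(y))), 0) + 1e-12)
})

test_that("negating a feature column negates its coefficient", {
  withr::with_seed(7, {
    X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
    y <- as.numeric(runif(30) < plogis(X[, 1]))
  })
  f1 <- fit_l1_logistic(X, y, 0.05)
  X2 <- X
  X2[, 1] <- -X2[, 1]
  f2 <- fit_l1_logistic(X2, y, 0.05)
  expect_equal(unname(f2$coefficients[1]), -unname(f1$coefficients[1]),
               tolerance = 1e-6)
  expect_equal(unname(f2$coefficients[2]), unname(f1$coefficients[2]),
               tolerance = 1e-6)
})

test_that("solver agrees with glmnet on random instances", {
  for (s in 1:5) {
    withr::with_seed(200 + s, {
      n <- 60
      X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("m", 1:5)))
      y <- as.numeric(runif(n) < plogis(0.3 + X %*% c(1, -0.5, 0, 0, 0.2)))
    })
    if (length(unique(y)) < 2) next
    lam <- 0.5 * lambda_max(X, y)
    fit <- fit_l1_logistic(X, y, lam)
    g <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lam, standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(fit$coefficients),
                 as.vector(g$beta), tolerance = 1e-4)
    expect_equal(fit$intercept, unname(g$a0), tolerance = 1e-4)
  }
})

test_that("KKT conditions hold at the returned solution on random instances", {
  for (s in 1:100) {
    withr::with_seed(1000 + s, {
      n <- 10 + sample(30, 1)
      p <- sample(2:6, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rep_len(c(0, 1), n)[sample(n)]
      lam <- runif(1, 0.2, 1.2) * lambda_max(X, y)
    })
    fit <- fit_l1_logistic(X, y, lam)
    pr <- plogis(fit$intercept + X %*% fit$coefficients)
    g <- as.vector(crossprod(X, pr - y)) / n
    viol <- ifelse(fit$coefficients == 0,
                   pmax(abs(g) - lam, 0),
                   abs(g + lam * sign(fit$coefficients)))
    expect_lt(max(viol, abs(mean(pr - y))), 1e-6)
  }
})

test_that("sigmoid predictions follow the linear score", {
  null_model <- structure(list(intercept = 0,
                               coefficients = c(a = 0, b = 0)),
                          class = "l1_logistic")
  X <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(logistic_predict(null_model, X), rep(0.5, 10))
  one <- structure(list(intercept = 0, coefficients = c(a = 1)),
                   class = "l1_logistic")
  expect_equal(logistic_predict(one, matrix(0, 1, 1,
                                            dimnames = list(NULL, "a"))), 0.5)
  expect_equal(logistic_predict(one, matrix(log(3), 1, 1,
                                            dimnames = list(NULL, "a"))), 0.75)
  big <- logistic_predict(one, matrix(seq(0, 40, by = 5), ncol = 1,
                                      dimnames = list(NULL, "a")))
  expect_true(all(diff(big) >= 0) && big[length(big)] > 1 - 1e-10)
  expect_error(logistic_predict(one, matrix(0, 1, 2,
                                            dimnames = list(NULL, c("x", "z")))),
               "prediction error")
})

test_that("regularization path starts empty, orders entries, reaches the MLE", {
  # planted signal: only marker 1 separates
  withr::with_seed(44, {
    n <- 100
    x1 <- rnorm(n) + rep(c(0, 1.5), each = n / 2)
    x2 <- rnorm(n)
    X <- cbind(signal = scale(x1)[, 1], noise = scale(x2)[, 1])
    y <- rep(c(0, 1), each = n / 2)
  })
  lmax <- lambda_max(X, y)
  grid <- exp(seq(log(lmax * 1.05), log(lmax * 5e-4), length.out = 50))
  path <- lasso_path(X, y, grid)
  expect_true(all(path$coefficients[1, ] == 0))
  e_sig <- path$entry_lambda["signal"]
  e_noise <- path$entry_lambda["noise"]
  expect_false(is.na(e_sig))
  expect_true(is.na(e_noise) || e_sig > e_noise)
  # lambda -> 0 end approximates the unpenalized fit
  ml <- glm(y ~ X, family = binomial())
  expect_lt(max(abs(path$coefficients[50, ] - coef(ml)[-1])), 1e-2)
  expect_error(lasso_path(X, y, c(0.1, 0.2)), "decreasing")
})

test_that("PCA contributions match eigen anchors and ignore component signs", {
  # two perfectly correlated columns: one informative direction, loadings
  # (+-1/sqrt(2)), contributions 0.7071 each
  withr::with_seed(3, z <- rnorm(20))
  X2 <- cbind(a = scale(z)[, 1], b = scale(2 * z + 1)[, 1])
  contrib <- pca_contribution(X2, K = 2)
  expect_equal(unname(contrib), rep(1 / sqrt(2), 2), tolerance = 1e-10)

  # block-diagonal toy vs a dense eigendecomposition oracle
  withr::with_seed(9, {
    u <- rnorm(50); v <- rnorm(50)
    X4 <- cbind(p = u + rnorm(50, sd = 0.1), q = u + rnorm(50, sd = 0.1),
                r = v + rnorm(50, sd = 0.1), s = v + rnorm(50, sd = 0.1))
  })
  Xs <- scale(X4)
  eig <- eigen(cov(Xs))
  oracle <- rowSums(abs(eig$vectors[, 1:3, drop = FALSE]))
  names(oracle) <- colnames(X4)
  expect_equal(pca_contribution(X4, K = 3), oracle, tolerance = 1e-10)
  expect_error(pca_contribution(X4, K = 5), "K must lie")
})

test_that("ranking merge unions L1 support with top contributions", {
  mk_model <- function(beta) {
    structure(list(intercept = 0, coefficients = beta),
              class = "l1_logistic")
  }
  contrib <- c(A = 0.2, B = 0.9, C = 0.8, D = 0.1)

  # all coefficients non-zero, q = 0: selection is the support itself
  m1 <- mk_model(c(A = 1.5, B = -0.3, C = 0.7, D = 0.2))
  r1 <- merge_rankings(m1, contrib, q = 0)
  expect_true(all(r1$selected))
  expect_equal(r1$marker, c("A", "C", "B", "D"))  # by |coefficient|

  # all-zero coefficients, q = 3: top-3 contributions only
  m0 <- mk_model(c(A = 0, B = 0, C = 0, D = 0))
  r0 <- merge_rankings(m0, contrib, q = 3)
  expect_setequal(r0$marker[r0$selected], c("B", "C", "A"))

  # union case: support {A, B}, top-2 contributions {B, C} -> {A, B, C}
  m2 <- mk_model(c(A = 0.5, B = -0.8, C = 0, D = 0))
  r2 <- merge_rankings(m2, contrib, q = 2)
  expect_setequal(r2$marker[r2$selected], c("A", "B", "C"))
  # lexicographic rank: non-zero first by |coef|, then by contribution
  expect_equal(r2$marker, c("B", "A", "C", "D"))
  expect_error(merge_rankings(m2, contrib, q = 9), "q must lie")
})
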