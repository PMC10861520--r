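make_reg <- function(n = 80, p = 12, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("f", seq_len(p))
  beta <- c(2, -1.5, 1, rep(0, p - 3))
  y <- drop(X %*% beta) + rnorm(n, sd = 0.7)
  list(X = X, y = y, beta = beta)
}

test_that("sparse-group prox matches its closed forms", {
  # group norm 5 with threshold exactly 5: zeroed
  expect_equal(prox_sparse_group(c(3, 4), 0, 5 / sqrt(2), rep(1, 2)), c(0, 0))
  # threshold 2.5: scaling 1 - 2.5/5 = 0.5
  expect_equal(prox_sparse_group(c(3, 4), 0, 2.5 / sqrt(2), rep(1, 2)),
               c(1.5, 2.0))
  # soft-threshold only
  expect_equal(prox_sparse_group(c(3, -0.5), 1, 0), c(2, 0))
  expect_error(prox_sparse_group(c(1, 2), -1, 0), "nonnegative")
})

test_that("ridge solutions match the closed form", {
  d <- make_reg()
  n <- nrow(d$X); p <- ncol(d$X)
  lam <- 0.25
  Xc <- scale(d$X, scale = FALSE); yc <- d$y - mean(d$y)
  closed <- solve(crossprod(Xc) + n * lam * diag(p), crossprod(Xc, yc))
  fit <- penfit(d$X, d$y, "ridge", "regression", lambda = lam,
                standardize = FALSE, tol = 1e-12)
  expect_lt(max(abs(fit$coefficients - closed)), 1e-6)
  # two-point toy with explicit closed form
  X2 <- matrix(c(1, -1), 2, 1); y2 <- c(2, 0)
  f2 <- penfit(X2, y2, "ridge", "regression", lambda = 0.5,
               standardize = FALSE, tol = 1e-13)
  expect_equal(unname(f2$coefficients),
               drop(solve(crossprod(X2) + 2 * 0.5, crossprod(X2, y2 - 1))),
               tolerance = 1e-6)
})

test_that("lambda = 0 reproduces the unpenalised maximum likelihood fits", {
  d <- make_reg()
  f <- penfit(d$X, d$y, "ridge", "regression", lambda = 0,
              standardize = FALSE, tol = 1e-12)
  ols <- stats::lm(d$y ~ d$X)
  expect_lt(max(abs(coef(f) - coef(ols))), 1e-4)
  set.seed(2)
  yb <- rbinom(nrow(d$X), 1, stats::plogis(d$X[, 1]))
  fl <- penfit(d$X[, 1:3], yb, "ridge", "classification", lambda = 0,
               standardize = FALSE, tol = 1e-13, max_iter = 50000)
  ml <- stats::glm(yb ~ d$X[, 1:3], family = stats::binomial())
  expect_lt(max(abs(coef(fl) - coef(ml))), 1e-4)
})

test_that("lasso agrees with glmnet at matched objectives", {
  skip_if_not_installed("glmnet")
  d <- make_reg()
  f <- penfit(d$X, d$y, "lasso", "regression", lambda = 0.1,
              standardize = FALSE, tol = 1e-12)
  g <- glmnet::glmnet(d$X, d$y, lambda = 0.1, alpha = 1,
                      standardize = FALSE, thresh = 1e-15)
  expect_lt(max(abs(coef(f) - as.numeric(stats::coef(g)))), 1e-5)
  set.seed(3)
  yb <- rbinom(nrow(d$X), 1, stats::plogis(d$X[, 1] - d$X[, 2]))
  f2 <- penfit(d$X, yb, "lasso", "classification", lambda = 0.05,
               standardize = FALSE, tol = 1e-12)
  g2 <- glmnet::glmnet(d$X, yb, family = "binomial", lambda = 0.05,
                       alpha = 1, standardize = FALSE, thresh = 1e-15)
  expect_lt(max(abs(coef(f2) - as.numeric(stats::coef(g2)))), 1e-4)
})

test_that("sparse-group lasso with full l1 mixing reduces to the lasso", {
  d <- make_reg()
  groups <- rep(1:4, each = 3)
  sg <- penfit(d$X, d$y, "sparse_group_lasso", "regression", lambda = 0.15,
               alpha = 1, groups = groups, standardize = FALSE, tol = 1e-12)
  la <- penfit(d$X, d$y, "lasso", "regression", lambda = 0.15,
               standardize = FALSE, tol = 1e-12)
  expect_lt(max(abs(sg$coefficients - la$coefficients)), 1e-6)
})

test_that("KKT conditions hold at convergence for every family", {
  d <- make_reg()
  groups <- rep(1:4, each = 3)
  for (spec in list(list("lasso", NULL), list("ridge", NULL),
                    list("elastic_net", NULL),
                    list("sparse_group_lasso", groups))) {
    fit <- penfit(d$X, d$y, spec[[1]], "regression", lambda = 0.12,
                  alpha = 0.5, groups = spec[[2]], standardize = FALSE,
                  tol = 1e-12, max_iter = 50000)
    expect_lt(kkt_residual(fit, d$X, d$y), 1e-6)
  }
})

test_that("the number of active features shrinks along the lambda path", {
  d <- make_reg(n = 100, p = 20, seed = 4)
  lmax <- lambda_max(d$X, d$y, "regression", "lasso", 1, standardize = FALSE)
  grid <- exp(seq(log(lmax * 1.01), log(lmax * 1e-3), length.out = 15))
  nz <- vapply(grid, function(l) {
    sum(penfit(d$X, d$y, "lasso", "regression", lambda = l,
               standardize = FALSE, tol = 1e-10)$coefficients != 0)
  }, numeric(1))
  expect_equal(nz[1], 0)          # above lambda_max everything is zero
  inversions <- sum(diff(nz) < 0) # grid is decreasing: counts should grow
  expect_lte(inversions, 1)
})

test_that("sparse-group lasso recovers planted group supports", {
  res <- sg_recovery_experiment(n_rep = 12, seed = 99)
  expect_true(all(res$contains_true))
  expect_lt(mean(res$false_groups), 3)
})

test_that("model methods expose coefficients and predictions coherently", {
  d <- make_reg()
  fit <- penfit(d$X, d$y, "elastic_net", "regression", lambda = 0.05,
                standardize = TRUE)
  expect_named(coef(fit)[1], "(Intercept)")
  expect_equal(predict(fit, d$X),
               drop(d$X %*% fit$coefficients) + fit$intercept)
  set.seed(5)
  yb <- factor(ifelse(rbinom(nrow(d$X), 1, stats::plogis(d$X[, 1])) == 1,
                      "RA", "HC"), levels = c("HC", "RA"))
  cf <- penfit(d$X, yb, "lasso", "classification", lambda = 0.02)
  pr <- predict(cf, d$X, type = "response")
  expect_true(all(pr >= 0 & pr <= 1))
  cl <- predict(cf, d$X, type = "class")
  expect_setequal(levels(cl), c("HC", "RA"))
  expect_output(print(fit), "Penalised regression")
})
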