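test_that("Mann-Whitney U matches hand values and identities", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.99)
  # U_x + U_y = n_x * n_y
  set.seed(2)
  x <- rnorm(7); y <- rnorm(5)
  ux <- mann_whitney_u(x, y)$statistic
  uy <- mann_whitney_u(y, x)$statistic
  expect_equal(ux + uy, 35)
  expect_error(mann_whitney_u(numeric(0), y), "non-empty")
})

test_that("small-sample p-values agree with exhaustive permutation", {
  set.seed(11)
  for (r in 1:20) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- sample(100, nx); y <- sample(200, ny) + 0.5  # untied
    expect_equal(mann_whitney_u(x, y)$p_value, perm_mwut_p(x, y),
                 tolerance = 1e-10)
  }
  # KW against full enumeration at tiny n (exact path, untied)
  for (r in 1:8) {
    g <- list(sample(1000, 2) + 0.1, sample(1000, 3) + 0.2,
              sample(1000, 2) + 0.3)
    expect_equal(kruskal_wallis(g)$p_value, perm_kw_p(g), tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis reproduces the hand-ranked statistic", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(r$statistic), 32 / 7, tolerance = 1e-9)
  flat <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("two-group KW matches the squared standardised rank-sum test", {
  set.seed(9)
  x <- rnorm(50); y <- rnorm(50, 0.3)
  kw <- kruskal_wallis(list(x, y))
  mw <- mann_whitney_u(x, y)
  z2 <- stats::qnorm(mw$p_value / 2)^2
  expect_equal(unname(kw$statistic), z2, tolerance = 0.05)
})

test_that("Brown-Forsythe responds to spread, not location", {
  eq <- brown_forsythe(list(c(1, 2, 3, 4), c(11, 12, 13, 14)))
  expect_lt(eq$statistic, 1e-10)
  uneq <- brown_forsythe(list(rep(0, 4), c(-5, 5, -5, 5)))
  expect_lt(uneq$p_value, 0.05)
  a <- list(rnorm(10), rnorm(10, sd = 3))
  set.seed(1)
  r1 <- brown_forsythe(a)
  r2 <- brown_forsythe(list(a[[1]] + 100, a[[2]]))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  skip_if_not_installed("car")
  v <- unlist(a); g <- factor(rep(1:2, each = 10))
  lev <- car::leveneTest(v, g, center = stats::median)
  expect_equal(r1$statistic, lev[1, "F value"], tolerance = 1e-8)
})

test_that("Benjamini-Hochberg implements the linear step-up rule", {
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(bh$reject))
  expect_equal(sum(benjamini_hochberg(rep(1, 6))$reject), 0)
  expect_true(benjamini_hochberg(0.04, 0.05)$reject)
  expect_false(benjamini_hochberg(0.06, 0.05)$reject)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjusted p-values are monotone and rejections nest", {
  set.seed(3)
  for (r in 1:20) {
    p <- runif(sample(3:30, 1))
    bh <- benjamini_hochberg(p, 0.05)
    o <- order(p)
    expect_true(all(diff(bh$adjusted[o]) >= -1e-12))
    r1 <- benjamini_hochberg(p, 0.02)$reject
    r2 <- benjamini_hochberg(p, 0.10)$reject
    expect_true(all(!r1 | r2))   # rejections at 0.02 nest in those at 0.10
  }
})

test_that("correlations report strength categories on |r|", {
  x <- 1:10
  lin <- correlation(x, 2 * x + 1, "pearson")
  expect_equal(lin$r, 1)
  expect_equal(lin$category, "good_excellent")
  mono <- correlation(x, exp(x), "spearman")
  expect_equal(mono$r, 1)
  expect_lt(correlation(x, exp(x), "pearson")$r, 1)
  expect_equal(actiRA:::correlation_category(0.6), "moderate_good")
  expect_equal(actiRA:::correlation_category(-0.3), "fair")
  expect_equal(actiRA:::correlation_category(0.1), "none")
  expect_error(correlation(rep(1, 5), rnorm(5)), "zero-variance")
})
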