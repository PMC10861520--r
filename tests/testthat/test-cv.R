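long_row <- function(pid, day, feature, value, domain = "TVDA") {
  data.frame(participant_id = pid, day_index = day, feature = feature,
             domain = domain, value = value, stringsAsFactors = FALSE)
}

test_that("aggregation averages over non-missing days only", {
  d <- rbind(long_row("P1", 1, "a", 1), long_row("P1", 2, "a", 2),
             long_row("P1", 3, "a", 3))
  fm <- aggregate_features(d, "fortnightly")
  expect_equal(unname(fm$x[1, "a"]), 2)
  d2 <- rbind(long_row("P1", 1, "a", 1), long_row("P1", 2, "a", NA),
              long_row("P1", 3, "a", 3))
  fm2 <- aggregate_features(d2, "fortnightly")
  expect_equal(unname(fm2$x[1, "a"]), 2)
  # 14 daily rows aggregate to 2 weekly rows per participant
  d3 <- do.call(rbind, lapply(1:14, function(day)
    long_row("P1", day, "a", day)))
  fm3 <- aggregate_features(d3, "weekly")
  expect_equal(nrow(fm3$x), 2)
  expect_equal(unname(fm3$x[, "a"]), c(mean(1:7), mean(8:14)))
  fm4 <- aggregate_features(d3, "daily")
  expect_equal(nrow(fm4$x), 14)
})

test_that("subject folds are stratified to within one participant", {
  pid <- sprintf("P%02d", 1:60)
  lab <- rep(c("HC", "RA"), each = 30)
  f <- stratified_subject_kfold(pid, lab, 5, seed = 3)
  tab <- table(f[1:30])
  expect_true(all(tab == 6))
  expect_true(all(table(f[31:60]) == 6))
  # 13 + 15 participants: per-fold class counts within 1 of proportional
  pid2 <- sprintf("Q%02d", 1:28)
  lab2 <- rep(c("mod", "sev"), c(13, 15))
  f2 <- stratified_subject_kfold(pid2, lab2, 5, seed = 3)
  t_mod <- table(factor(f2[1:13], levels = 1:5))
  t_sev <- table(factor(f2[14:28], levels = 1:5))
  expect_true(all(abs(t_mod - 2.6) <= 1))
  expect_true(all(abs(t_sev - 3.0) <= 1))
  expect_identical(f, stratified_subject_kfold(pid, lab, 5, seed = 3))
  expect_error(stratified_subject_kfold(pid[1:3], lab[1:3], 5), "exceeds")
})

test_that("majority voting is modal with score-based tie-breaks", {
  expect_equal(majority_vote(c("1", "1", "0"), classes = c("0", "1")), "1")
  expect_equal(majority_vote(c("1", "0"), scores = c(0.9, 0.5),
                             classes = c("0", "1")), "1")
  expect_equal(majority_vote(c("1", "0"), scores = c(0.4, 0.2),
                             classes = c("0", "1")), "0")
  expect_equal(majority_vote("0", classes = c("0", "1")), "0")
})

test_that("classification metrics match hand-computed values", {
  m <- classification_metrics(factor(c(0, 1, 0, 1)), c(0, 1, 0, 1),
                              scores = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(m$auroc, 0.75)
  expect_equal(m$kappa, 1)
  expect_equal(m$macro_f1, 1)
  m2 <- classification_metrics(factor(c(1, 1, 0, 0)), c(1, 0, 1, 0))
  expect_equal(m2$kappa, 0)
  one <- classification_metrics(factor(c(1, 1)), c(1, 1), scores = c(1, 1))
  expect_true(is.na(one$auroc))
  expect_equal(one$accuracy, 1)
})

test_that("regression metrics follow their definitions", {
  y <- c(1, 2, 3, 4)
  perfect <- regression_metrics(y, y)
  expect_equal(perfect$r2, 1); expect_equal(perfect$mae, 0)
  off <- regression_metrics(y, y + 1)
  expect_equal(off$mae, 1); expect_equal(off$rmse, 1)
  base <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(base$r2, 0)
})

make_toy_fm <- function(n_per = 20, days = 4, shift = 2, seed = 6) {
  set.seed(seed)
  pid <- sprintf("P%02d", seq_len(2 * n_per))
  lab <- stats::setNames(rep(c("HC", "RA"), each = n_per), pid)
  rows <- do.call(rbind, lapply(pid, function(id) {
    mu <- if (lab[id] == "RA") shift else 0
    do.call(rbind, lapply(seq_len(days), function(d) rbind(
      long_row(id, d, "a", rnorm(1, mu)), long_row(id, d, "b", rnorm(1)))))
  }))
  list(fm = aggregate_features(rows, "daily"), labels = lab)
}

test_that("cross-validation partitions participants exactly once", {
  toy <- make_toy_fm()
  cv <- run_cv(toy$fm, toy$labels, list(family = "lasso", lambda = 0.05),
               "classification", k = 5, seed = 2)
  expect_setequal(names(cv$folds), unique(toy$fm$participant_id))
  expect_equal(sort(unique(cv$observations$fold)), 1:5)
  # every observation of a participant sits in that participant's fold
  by_p <- tapply(cv$observations$fold, cv$observations$participant_id,
                 function(v) length(unique(v)))
  expect_true(all(by_p == 1))
  expect_gt(cv$metrics_subject$macro_f1, 0.9)
})

test_that("preprocessing statistics never touch the held-out fold", {
  toy <- make_toy_fm()
  # poison one participant's rows with huge values; when that participant is
  # in the test fold the training statistics must be unchanged
  fm <- toy$fm
  poisoned <- "P01"
  fm$x[fm$participant_id == poisoned, ] <- 1e6
  tr_rows <- fm$participant_id != poisoned
  pp_clean <- actiRA:::fit_preprocess(toy$fm$x[tr_rows, , drop = FALSE])
  pp_pois <- actiRA:::fit_preprocess(fm$x[tr_rows, , drop = FALSE])
  expect_identical(pp_clean, pp_pois)
  xte <- actiRA:::apply_preprocess(fm$x[!tr_rows, , drop = FALSE], pp_pois)
  expect_true(all(is.finite(xte)))
})

test_that("median imputation fills missing cells from training data", {
  x <- rbind(c(1, 10), c(3, NA), c(5, 30))
  pp <- actiRA:::fit_preprocess(x)
  expect_equal(pp$median, c(3, 20))
  filled <- actiRA:::apply_preprocess(rbind(c(NA, NA)), pp)
  expect_equal(unname(filled[1, 1] * pp$scale[1] + pp$center[1]), 3)
})

test_that("permuted labels drive performance to chance", {
  toy <- make_toy_fm(n_per = 15, days = 3, shift = 3, seed = 8)
  set.seed(9)
  f1s <- vapply(1:10, function(r) {
    perm <- stats::setNames(sample(toy$labels), names(toy$labels))
    cv <- run_cv(toy$fm, perm, list(family = "lasso", lambda = 0.05),
                 "classification", k = 5, seed = r)
    cv$metrics_subject$macro_f1
  }, numeric(1))
  expect_gt(mean(f1s), 0.25)
  expect_lt(mean(f1s), 0.75)
})

test_that("cross-validation is reproducible from its seed", {
  toy <- make_toy_fm()
  cv1 <- run_cv(toy$fm, toy$labels, list(family = "elastic_net",
                                         alpha = 0.5), "classification",
                k = 4, seed = 11)
  cv2 <- run_cv(toy$fm, toy$labels, list(family = "elastic_net",
                                         alpha = 0.5), "classification",
                k = 4, seed = 11)
  expect_identical(cv1$observations, cv2$observations)
  expect_identical(cv1$metrics_subject, cv2$metrics_subject)
})
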