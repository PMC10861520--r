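#' Aggregate daily features into an observation matrix
#'
#' Pivots a long daily feature table to one row per participant-period,
#' averaging each feature over the non-missing days in the period (missing
#' days are excluded from the denominator, never imputed as zero). `daily`
#' aggregation passes days through as periods; `weekly` and `fortnightly`
#' average over 7- and 14-day blocks.
#'
#' @param daily long table (`participant_id`, `day_index`, `feature`,
#'   `domain`, `value`).
#' @param level `"daily"`, `"weekly"` or `"fortnightly"`.
#' @return object of class `feature_matrix`: list with `x` (matrix), ids
#'   `participant_id` / `period_id` per row, `domains` (named character
#'   vector mapping feature to domain) and `level`.
#' @export
aggregate_features <- function(daily, level = c("daily", "weekly",
                                                "fortnightly")) {
  level <- match.arg(level)
  if (!nrow(daily)) stopf("empty daily table")
  span <- switch(level, daily = 1L, weekly = 7L, fortnightly = 14L)
  period <- (as.integer(daily$day_index) - 1L) %/% span + 1L
  key <- interaction(daily$participant_id, period, drop = TRUE)
  feats <- sort(unique(daily$feature))
  agg <- tapply(daily$value, list(key, factor(daily$feature, feats)),
                function(v) mean(v, na.rm = TRUE))
  agg[is.nan(agg)] <- NA_real_
  ids <- do.call(rbind, strsplit(rownames(agg), ".", fixed = TRUE))
  dom <- daily$domain[match(feats, daily$feature)]
  keep <- colSums(!is.na(agg)) > 0
  structure(list(
    x = agg[, keep, drop = FALSE],
    participant_id = ids[, 1],
    period_id = as.integer(ids[, 2]),
    domains = stats::setNames(dom[keep], feats[keep]),
    level = level), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix (%s): %d observations x %d features, %d participants\n",
              x$level, nrow(x$x), ncol(x$x), length(unique(x$participant_id))))
  cat("domains:", paste(sprintf("%s(%d)", names(table(x$domains)),
                                table(x$domains)), collapse = " "), "\n")
  invisible(x)
}

#' Stratified subject-wise k-fold partition
#'
#' Participants (never observations) are partitioned into k folds; within
#' each class, shuffled participants are dealt round-robin, so per-fold
#' class counts differ by at most one from exact proportionality.
#'
#' @param participants participant identifiers.
#' @param labels class label per participant.
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return named integer vector: fold (1..k) per participant.
#' @export
stratified_subject_kfold <- function(participants, labels, k, seed = 1) {
  if (k > length(participants)) stopf("k exceeds the number of participants")
  if (length(labels) != length(participants)) stopf("length mismatch")
  set.seed(derive_seed(seed, "folds"))
  fold <- stats::setNames(integer(length(participants)), participants)
  for (cl in unique(labels)) {
    ids <- sample(participants[labels == cl])
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

#' Majority vote over a participant's observation-level predictions
#'
#' Returns the modal predicted class; ties break toward the class with the
#' higher mean predicted positive-class score (deterministic and
#' score-consistent).
#'
#' @param predictions character/factor vector of observation predictions.
#' @param scores positive-class scores aligned with `predictions`.
#' @param classes the two class labels, positive last.
#' @return single predicted class label.
#' @export
majority_vote <- function(predictions, scores = NULL, classes = NULL) {
  predictions <- as.character(predictions)
  if (is.null(classes)) classes <- sort(unique(predictions))
  tb <- table(factor(predictions, classes))
  mx <- which(tb == max(tb))
  if (length(mx) == 1) return(names(tb)[mx])
  if (is.null(scores)) return(names(tb)[mx[1]])
  pos <- classes[length(classes)]
  if (mean(scores) >= 0.5) pos else classes[1]
}

#' Binary classification metrics
#'
#' AUROC is the rank statistic (tied scores count one half), Cohen's kappa
#' is `(p_o - p_e) / (1 - p_e)`, and macro-F1 is the unweighted mean of
#' per-class F1 scores.
#'
#' @param y true labels.
#' @param yhat predicted labels.
#' @param scores positive-class scores (needed for AUROC; the positive class
#'   is the last factor level of `y`).
#' @return list: `auroc` (NA when `y` has one class), `kappa`, `macro_f1`,
#'   `accuracy`.
#' @export
classification_metrics <- function(y, yhat, scores = NULL) {
  y <- factor(y)
  classes <- levels(y)
  yhat <- factor(as.character(yhat), classes)
  auroc <- NA_real_
  if (!is.null(scores) && nlevels(droplevels(y)) == 2) {
    pos <- y == classes[length(classes)]
    r <- rank(scores)
    n1 <- sum(pos); n0 <- sum(!pos)
    auroc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  tab <- table(y, yhat)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  f1s <- vapply(classes, function(cl) {
    tp <- tab[cl, cl]
    prec <- if (sum(tab[, cl]) > 0) tp / sum(tab[, cl]) else 0
    rec <- if (sum(tab[cl, ]) > 0) tp / sum(tab[cl, ]) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  list(auroc = unname(auroc), kappa = kappa, macro_f1 = mean(f1s),
       accuracy = po)
}

#' Regression metrics
#'
#' @param y observed values.
#' @param yhat predictions.
#' @return list: `r2` (`1 - SS_res/SS_tot`; NA for zero-variance `y`),
#'   `mae`, `rmse`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stopf("length mismatch")
  ss_tot <- sum((y - mean(y))^2)
  list(r2 = if (ss_tot > 0) 1 - sum((y - yhat)^2) / ss_tot else NA_real_,
       mae = mean(abs(y - yhat)),
       rmse = sqrt(mean((y - yhat)^2)))
}

# train-fold preprocessing: median imputation + standardisation statistics
fit_preprocess <- function(x) {
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  ximp <- x
  for (j in seq_len(ncol(x))) ximp[is.na(ximp[, j]), j] <- med[j]
  ctr <- colMeans(ximp)
  scl <- apply(ximp, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(median = med, center = ctr, scale = scl)
}

apply_preprocess <- function(x, pp) {
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- pp$median[j]
  scale(x, pp$center, pp$scale)
}

# stratification labels: classes as-is; continuous responses binned into
# quartiles so folds stay balanced on the outcome
strat_labels <- function(y, task) {
  if (task != "regression") return(as.character(y))
  y <- as.numeric(y)
  br <- unique(stats::quantile(y, 0:4 / 4, na.rm = TRUE))
  if (length(br) < 2) return(rep("all", length(y)))
  as.character(cut(y, breaks = br, include.lowest = TRUE))
}

# inner subject-wise CV over a log-spaced lambda grid; returns best lambda.
# rule = "min" takes the error-minimising lambda; "1se" the sparsest lambda
# within one standard error of the minimum (preferred when support recovery
# matters more than raw prediction error)
select_lambda <- function(x, y, participants, task, family, alpha, groups,
                          inner_k = 3, n_lambda = 20, seed = 1,
                          rule = c("min", "1se")) {
  rule <- match.arg(rule)
  upid <- unique(participants)
  ulab <- y[match(upid, participants)]
  if (length(upid) < inner_k) return(0.01)
  lmax <- lambda_max(x, y, task, family, alpha, groups, standardize = FALSE)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = n_lambda))
  folds <- stratified_subject_kfold(upid, strat_labels(ulab, task), inner_k,
                                    seed)
  err <- matrix(NA_real_, inner_k, n_lambda)
  for (f in seq_len(inner_k)) {
    tr <- participants %in% upid[folds[upid] != f]
    if (task == "classification" &&
        length(unique(y[tr])) < 2) next
    fits <- penfit_path(x[tr, , drop = FALSE], y[tr], grid, family, task,
                        alpha, groups, standardize = FALSE)
    for (i in seq_along(grid)) {
      pred <- predict(fits[[i]], x[!tr, , drop = FALSE], type = "response")
      if (task == "regression") {
        err[f, i] <- mean((as.numeric(y[!tr]) - pred)^2)
      } else {
        yy <- as.numeric(factor(y[!tr], levels = levels(factor(y)))) - 1
        p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
        err[f, i] <- -mean(yy * log(p) + (1 - yy) * log(1 - p))
      }
    }
  }
  me <- colMeans(err, na.rm = TRUE)
  if (all(!is.finite(me))) return(grid[n_lambda %/% 2])
  if (rule == "min") return(grid[which.min(me)])
  se <- apply(err, 2, stats::sd) / sqrt(max(1, nrow(err)))
  i_min <- which.min(me)
  thresh <- me[i_min] + (if (is.finite(se[i_min])) se[i_min] else 0)
  # grid is decreasing: the first lambda within one SE is the sparsest
  grid[which(me <= thresh)[1]]
}

#' Subject-wise cross-validated model evaluation
#'
#' The full evaluation protocol: a stratified subject-wise k-fold partition;
#' per fold, median imputation and standardisation computed on the training
#' fold only and applied to the held-out observations; the penalty strength
#' chosen by an inner 3-fold subject-wise CV over a 20-point log-spaced grid
#' (unless `penalty$lambda` is supplied); observation-level predictions
#' aggregated per participant by majority vote (classification) or the mean
#' (regression). Observation-wise metrics are summarised as median and IQR
#' across folds; subject-wise metrics are computed once on the pooled
#' out-of-fold subject predictions.
#'
#' @param fm a [aggregate_features()] matrix.
#' @param labels named vector: response per participant (two-level for
#'   classification, numeric for regression).
#' @param penalty list with `family`, optional fixed `lambda`, `alpha`.
#' @param task `"classification"` or `"regression"`.
#' @param k number of outer folds.
#' @param seed integer seed (folds and inner CV).
#' @return object of class `cv_report`.
#' @export
run_cv <- function(fm, labels, penalty = list(family = "elastic_net",
                                              alpha = 0.5),
                   task = c("classification", "regression"), k = 5,
                   seed = 1) {
  task <- match.arg(task)
  upid <- unique(fm$participant_id)
  if (!all(upid %in% names(labels)))
    stopf("labels missing for some participants")
  ulab <- labels[upid]
  classes <- if (task == "classification") levels(factor(ulab)) else NULL
  groups_map <- fm$domains
  fam <- penalty$family %||% "elastic_net"
  alpha <- penalty$alpha %||% 0.5
  grp <- if (fam == "sparse_group_lasso") unname(groups_map[colnames(fm$x)])
         else NULL

  folds <- stratified_subject_kfold(upid, strat_labels(ulab, task), k, seed)
  obs <- NULL
  fold_metrics <- list()
  chosen_lambda <- numeric(0)
  for (f in seq_len(k)) {
    te_pid <- upid[folds == f]
    tr <- !(fm$participant_id %in% te_pid)
    te <- !tr
    ytr <- labels[fm$participant_id[tr]]
    if (task == "classification" && length(unique(ytr)) < 2) {
      warning("fold ", f, " has a single training class; skipped")
      next
    }
    pp <- fit_preprocess(fm$x[tr, , drop = FALSE])
    xtr <- apply_preprocess(fm$x[tr, , drop = FALSE], pp)
    xte <- apply_preprocess(fm$x[te, , drop = FALSE], pp)
    lam <- penalty$lambda
    if (is.null(lam)) {
      lam <- select_lambda(xtr, ytr, fm$participant_id[tr], task, fam,
                           alpha, grp, seed = derive_seed(seed, "inner", f))
    }
    chosen_lambda <- c(chosen_lambda, lam)
    fit <- suppressWarnings(
      penfit(xtr, ytr, family = fam, task = task, lambda = lam,
             alpha = alpha, groups = grp, standardize = FALSE,
             tol = 1e-7, max_iter = 5000))
    sc <- predict(fit, xte, type = "response")
    pred <- if (task == "classification")
      as.character(predict(fit, xte, type = "class")) else sc
    block <- data.frame(participant_id = fm$participant_id[te],
                        period_id = fm$period_id[te], fold = f,
                        y = unname(labels[fm$participant_id[te]]),
                        score = sc, pred = pred, stringsAsFactors = FALSE)
    obs <- rbind(obs, block)
    fold_metrics[[length(fold_metrics) + 1]] <-
      if (task == "classification")
        classification_metrics(factor(block$y, classes), block$pred, block$score)
      else regression_metrics(as.numeric(block$y), sc)
  }
  if (is.null(obs)) stopf("no usable folds")

  # subject-wise aggregation
  subj <- do.call(rbind, lapply(split(obs, obs$participant_id), function(s) {
    data.frame(participant_id = s$participant_id[1], y = s$y[1],
               pred = if (task == "classification")
                 majority_vote(s$pred, s$score, classes) else mean(s$score),
               mean_score = mean(s$score), stringsAsFactors = FALSE)
  }))
  metrics_subject <- if (task == "classification")
    classification_metrics(factor(subj$y, classes), subj$pred,
                           subj$mean_score)
  else regression_metrics(as.numeric(subj$y), subj$pred)
  # pooled observation-level metrics (alternative convention, also emitted)
  metrics_obs_pooled <- if (task == "classification")
    classification_metrics(factor(obs$y, classes), obs$pred, obs$score)
  else regression_metrics(as.numeric(obs$y), obs$score)

  summar <- function(name) {
    v <- vapply(fold_metrics, function(m) m[[name]] %||% NA_real_, numeric(1))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
    c(median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]))
  }
  metric_names <- names(fold_metrics[[1]])
  metrics_obs <- lapply(stats::setNames(metric_names, metric_names), summar)

  structure(list(folds = folds, task = task, classes = classes,
                 observations = obs, subjects = subj,
                 metrics_obs = metrics_obs,
                 metrics_obs_pooled = metrics_obs_pooled,
                 metrics_subject = metrics_subject,
                 lambda = chosen_lambda, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Subject-wise %d-fold CV (%s), %d participants, %d observations\n",
              max(x$folds), x$task, length(x$folds), nrow(x$observations)))
  if (x$task == "classification") {
    m <- x$metrics_subject
    cat(sprintf("  subject-wise: F1 = %.3f, kappa = %.3f, AUROC = %.3f\n",
                m$macro_f1, m$kappa, m$auroc %||% NA))
    cat(sprintf("  observation-wise F1 median [IQR]: %.3f [%.3f, %.3f]\n",
                x$metrics_obs$macro_f1["median"], x$metrics_obs$macro_f1["q1"],
                x$metrics_obs$macro_f1["q3"]))
  } else {
    m <- x$metrics_subject
    cat(sprintf("  subject-wise: r2 = %.3f, MAE = %.3f, RMSE = %.3f\n",
                m$r2, m$mae, m$rmse))
  }
  invisible(x)
}
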