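#' Test-retest reliability: ICC(3,k)
#'
#' Two-way average-measures intraclass correlation for consistency, with
#' study days as the k repeated measurements. From the two-way ANOVA
#' decomposition (subjects x days, no interaction term),
#' `ICC(3,k) = (MS_subjects - MS_error) / MS_subjects`. Negative estimates
#' are reported as computed (not clipped) and categorised as poor.
#' Reliability categories: poor (< 0.5), moderate (0.5-0.75), good
#' (0.75-0.9), excellent (> 0.9).
#'
#' @param data numeric matrix, subjects in rows, days (raters) in columns;
#'   must be complete.
#' @return list of class `icc_result`: `icc`, `n_subjects`, `k_raters`,
#'   `category`, and the mean squares `ms_subjects`, `ms_error`.
#' @export
icc_3k <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data))
    stopf("matrix has missing cells; reduce to complete cases first")
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stopf("need at least 2 subjects and 2 days")
  gm <- mean(data)
  ss_rows <- k * sum((rowMeans(data) - gm)^2)
  ss_cols <- n * sum((colMeans(data) - gm)^2)
  ss_tot <- sum((data - gm)^2)
  ms_rows <- ss_rows / (n - 1)
  ms_err <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  icc <- if (ms_rows > 0) (ms_rows - ms_err) / ms_rows else NA_real_
  structure(list(icc = icc, n_subjects = n, k_raters = k,
                 category = icc_category(icc),
                 ms_subjects = ms_rows, ms_error = ms_err),
            class = "icc_result")
}

icc_category <- function(icc) {
  if (is.na(icc) || icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
}

#' Single-measure ICC(3,1)
#'
#' Companion to [icc_3k()]; satisfies the Spearman-Brown identity
#' `ICC(3,k) = k * ICC(3,1) / (1 + (k-1) * ICC(3,1))`.
#'
#' @inheritParams icc_3k
#' @return scalar ICC(3,1).
#' @export
icc_31 <- function(data) {
  r <- icc_3k(data)
  (r$ms_subjects - r$ms_error) /
    (r$ms_subjects + (r$k_raters - 1) * r$ms_error)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,%d) = %.3f over %d subjects: %s reliability\n",
              x$k_raters, x$icc, x$n_subjects, x$category))
  invisible(x)
}

#' Reliability as a function of days of data
#'
#' For each `d` in the grid, computes ICC(3,d) per feature (and per group if
#' supplied) from the first `d` contiguous study days, reducing to subjects
#' with complete data on that day grid.
#'
#' @param daily long feature table (`participant_id`, `day_index`,
#'   `feature`, `value`).
#' @param d_grid day counts to evaluate (each >= 2).
#' @param groups optional named vector mapping participant_id to group; when
#'   given, curves are computed within each group.
#' @param features optional subset of features.
#' @return list with `curve` (feature, group, d, icc, category, n_subjects)
#'   and `summary` (group, d, median_icc, q1, q3 across features).
#' @export
icc_vs_days <- function(daily, d_grid = 2:14, groups = NULL, features = NULL) {
  if (is.null(features)) features <- unique(daily$feature)
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(unique(daily$participant_id))),
                              unique(daily$participant_id))
  }
  rows <- list()
  for (g in unique(groups)) {
    pid_g <- names(groups)[groups == g]
    sub_g <- daily[daily$participant_id %in% pid_g &
                   daily$feature %in% features, , drop = FALSE]
    for (f in features) {
      sub <- sub_g[sub_g$feature == f, , drop = FALSE]
      if (!nrow(sub)) next
      wide <- stats::reshape(sub[, c("participant_id", "day_index", "value")],
                             idvar = "participant_id", timevar = "day_index",
                             direction = "wide")
      day_cols <- order(as.integer(sub("value\\.", "", names(wide)[-1])))
      mat <- as.matrix(wide[, -1, drop = FALSE][, day_cols, drop = FALSE])
      for (d in d_grid) {
        if (d > ncol(mat)) next
        m <- mat[, seq_len(d), drop = FALSE]
        m <- m[stats::complete.cases(m), , drop = FALSE]
        if (nrow(m) < 2) next
        if (all(apply(m, 2, stats::sd) == 0)) next  # constant feature
        r <- icc_3k(m)
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, group = g, d = d, icc = r$icc,
          category = r$category, n_subjects = nrow(m),
          stringsAsFactors = FALSE)
      }
    }
  }
  curve <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(0), group = character(0), d = integer(0),
               icc = numeric(0), category = character(0),
               n_subjects = integer(0))
  summ <- NULL
  if (nrow(curve)) {
    summ <- do.call(rbind, lapply(split(curve, curve[c("group", "d")],
                                        drop = TRUE), function(s) {
      q <- stats::quantile(s$icc, c(0.25, 0.5, 0.75), na.rm = TRUE)
      data.frame(group = s$group[1], d = s$d[1], median_icc = q[2],
                 q1 = q[1], q3 = q[3], n_features = nrow(s),
                 stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
  }
  list(curve = curve, summary = summ)
}

#' Univariate feature report
#'
#' Runs a two-group rank test (HC vs RA by default) or the Kruskal-Wallis
#' test across all three groups for every feature of a long daily table
#' (features first averaged per participant), then applies
#' Benjamini-Hochberg FDR control.
#'
#' @param daily long feature table.
#' @param groups named vector mapping participant_id to group.
#' @param comparison `"hc_vs_ra"` (Mann-Whitney on HC vs pooled RA) or
#'   `"three_group"` (Kruskal-Wallis across HC / RA_mod / RA_sev).
#' @param alpha FDR level.
#' @return data.frame: feature, domain, test, statistic, p, p_adjusted,
#'   significant.
#' @export
univariate_report <- function(daily, groups, comparison = c("hc_vs_ra",
                                                            "three_group"),
                              alpha = 0.05) {
  comparison <- match.arg(comparison)
  agg <- stats::aggregate(value ~ participant_id + feature + domain,
                          data = daily, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  feats <- unique(agg[, c("feature", "domain")])
  res <- lapply(seq_len(nrow(feats)), function(i) {
    sub <- agg[agg$feature == feats$feature[i], ]
    v <- stats::setNames(sub$value, sub$participant_id)
    v <- v[is.finite(v)]
    g <- groups[names(v)]
    out <- data.frame(feature = feats$feature[i], domain = feats$domain[i],
                      test = NA_character_, statistic = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
    tryCatch({
      if (comparison == "hc_vs_ra") {
        t <- mann_whitney_u(v[g == "HC"], v[g != "HC"])
      } else {
        t <- kruskal_wallis(split(v, g))
      }
      out$test <- t$method; out$statistic <- t$statistic; out$p <- t$p_value
    }, error = function(e) NULL)
    out
  })
  rep <- do.call(rbind, res)
  bh <- benjamini_hochberg(rep$p, alpha)
  rep$p_adjusted <- bh$adjusted
  rep$significant <- bh$reject
  rep
}
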