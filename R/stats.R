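#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for a difference in population medians. Ties are
#' handled by midranks; the p-value is exact for combined samples of at most
#' 12 without ties and otherwise uses the normal approximation with tie
#' correction.
#'
#' @param x,y numeric samples.
#' @return list of class `uni_test`: `statistic` (U for `x`), `p_value`,
#'   `method`, `n_per_group`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = "MWUT", n_per_group = c(length(x), length(y))),
            class = "uni_test")
}

#' Kruskal-Wallis rank test
#'
#' The tie-corrected H statistic with, mirroring the exact/approximate split
#' of [mann_whitney_u()], an exact permutation p-value for small untied
#' samples (combined n of at most 8, where the group-assignment space is
#' enumerable) and the chi-squared approximation (df = groups - 1)
#' otherwise. Degenerate data (all values tied across all groups) returns
#' H = 0, p = 1.
#'
#' @param groups list of at least two non-empty numeric samples.
#' @return `uni_test` list with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (any(!lengths(groups))) stopf("groups must be non-empty")
  vals <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(vals)) == 1) {
    return(structure(list(statistic = 0, p_value = 1, method = "KW",
                          n_per_group = lengths(groups)), class = "uni_test"))
  }
  kt <- stats::kruskal.test(vals, g)
  h <- unname(kt$statistic)
  p <- kt$p.value
  if (length(vals) <= 8 && !anyDuplicated(vals)) {
    p <- kw_exact_p(rank(vals), lengths(groups), h)
  }
  structure(list(statistic = h, p_value = p,
                 method = "KW", n_per_group = lengths(groups)),
            class = "uni_test")
}

# exact permutation p-value of the (untied) H statistic: enumerate all
# assignments of the pooled ranks to the group sizes
kw_exact_p <- function(ranks, sizes, h_obs) {
  n <- length(ranks)
  h_of <- function(split_ranks) {
    12 / (n * (n + 1)) *
      sum(vapply(split_ranks, function(r) length(r) * mean(r)^2,
                 numeric(1))) - 3 * (n + 1)
  }
  assigns <- enumerate_assignments(seq_len(n), sizes)
  hs <- vapply(assigns, function(a) {
    h_of(lapply(a, function(idx) ranks[idx]))
  }, numeric(1))
  mean(hs >= h_obs - 1e-12)
}

enumerate_assignments <- function(idx, sizes) {
  if (length(sizes) == 1) return(list(list(idx)))
  first <- utils::combn(idx, sizes[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- enumerate_assignments(setdiff(idx, f), sizes[-1])
    out <- c(out, lapply(rest, function(r) c(list(f), r)))
  }
  out
}

#' Brown-Forsythe test for equality of variances
#'
#' One-way ANOVA F test on absolute deviations from the group medians.
#'
#' @param groups list of at least two samples, each with at least two values.
#' @return `uni_test` list with the F statistic and its p-value.
#' @export
brown_forsythe <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (any(lengths(groups) < 2)) stopf("every group needs n >= 2")
  z <- unlist(lapply(groups, function(v) abs(v - stats::median(v))))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ssw <- sum(unlist(lapply(split(z, g), function(v) (v - mean(v))^2)))
  ssb <- sum(lengths(groups) * (vapply(split(z, g), mean, 1) - mean(z))^2)
  if (ssw < 1e-300) {
    # degenerate within-group spread: F is 0/0 (identical deviations) or
    # infinite (separated deviation levels)
    stat <- if (ssb < 1e-300) 0 else Inf
    p <- if (ssb < 1e-300) 1 else 0
  } else {
    ft <- stats::oneway.test(z ~ g, var.equal = TRUE)
    stat <- unname(ft$statistic); p <- ft$p.value
  }
  structure(list(statistic = stat, p_value = p, method = "BF",
                 n_per_group = lengths(groups)), class = "uni_test")
}

#' @export
print.uni_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Benjamini-Hochberg FDR control
#'
#' Linear step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' reject all hypotheses up to the largest `i` with
#' `p_(i) <= i * alpha / m`. Adjusted p-values come from the backward
#' cumulative-minimum pass and are returned in the original order;
#' rejection at level `alpha` is equivalent to `adjusted <= alpha`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `adjusted` and logical `reject`, both in input order.
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Correlation with clinical strength categories
#'
#' Pearson or Spearman correlation with a two-sided p-value; the association
#' strength is categorised on `|r|` as good-to-excellent (> 0.75),
#' moderate-to-good (0.50-0.75), fair (0.25-0.49) or none (< 0.25).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `cor_result`: `r`, `p_value`, `method`, `category`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined for zero-variance input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  structure(list(r = r, p_value = ct$p.value, method = method,
                 category = correlation_category(r)),
            class = "cor_result")
}

correlation_category <- function(r) {
  a <- abs(r)
  if (a > 0.75) "good_excellent"
  else if (a >= 0.50) "moderate_good"
  else if (a >= 0.25) "fair"
  else "none"
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("%s r = %.3f (p = %.3g), strength: %s\n",
              x$method, x$r, x$p_value, x$category))
  invisible(x)
}
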