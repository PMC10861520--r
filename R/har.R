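#' Split a raw stream into fixed-length epochs
#'
#' Half-open windows `[t, t + epoch_len_s)`; a trailing partial window is
#' dropped.
#'
#' @param stream a `tri_stream` from [synthesize_raw_stream()].
#' @param epoch_len_s window length in seconds (default 30).
#' @return list of `n x 3` sample matrices, one per complete window.
#' @export
window_stream <- function(stream, epoch_len_s = 30) {
  if (epoch_len_s <= 0) stopf("epoch_len_s must be positive")
  spe <- as.integer(stream$sample_rate_hz * epoch_len_s)
  n <- nrow(stream$xyz)
  k <- n %/% spe
  if (k == 0) return(list())
  lapply(seq_len(k), function(i) {
    stream$xyz[((i - 1) * spe + 1):(i * spe), , drop = FALSE]
  })
}

#' Per-epoch summary features of a raw window
#'
#' Deterministic hand-crafted summary of one epoch of tri-axial samples:
#' moments and percentiles of the Euclidean magnitude, per-axis means, the
#' zero-crossing rate of the mean-removed magnitude, and band power of the
#' magnitude in the 0.5-3 Hz and 3-8 Hz bands. These features feed the
#' window classifier that stands in for a learned deep representation.
#'
#' @param w an `n x 3` sample matrix.
#' @param sample_rate_hz sampling rate of the window.
#' @return named numeric feature vector.
#' @export
extract_window_features <- function(w, sample_rate_hz = 30) {
  if (!nrow(w)) stopf("window is empty")
  if (!all(is.finite(w))) stopf("window contains non-finite samples")
  m <- sqrt(rowSums(w^2))
  md <- m - mean(m)
  zcr <- if (length(md) > 1) mean(diff(sign(md)) != 0) else 0
  qs <- stats::quantile(m, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)

  # band power via the periodogram of the magnitude
  n <- length(m)
  sp <- Mod(stats::fft(md))^2 / n
  freq <- (seq_len(n) - 1) * sample_rate_hz / n
  half <- freq <= sample_rate_hz / 2
  bp <- function(lo, hi) sum(sp[half & freq >= lo & freq < hi])

  c(mag_mean = mean(m), mag_sd = stats::sd(m),
    mag_p10 = qs[1], mag_p25 = qs[2], mag_p50 = qs[3],
    mag_p75 = qs[4], mag_p90 = qs[5],
    x_mean = mean(w[, 1]), y_mean = mean(w[, 2]), z_mean = mean(w[, 3]),
    zcr = zcr, bp_low = bp(0.5, 3), bp_high = bp(3, 8))
}

#' Fit the per-epoch activity window classifier
#'
#' Multinomial logistic regression on standardised window features; a
#' transparent stand-in for a deep activity-recognition network. The class
#' posteriors it emits are the input to the HMM smoothing step, which is
#' agnostic to how the posteriors were produced.
#'
#' @param X numeric feature matrix (epochs x features).
#' @param y class labels (factor or character).
#' @return object of class `window_clf` with a `predict` method that returns
#'   posterior probabilities.
#' @export
fit_window_classifier <- function(X, y) {
  y <- factor(y)
  if (nlevels(y) < 2) stopf("need at least 2 classes to train")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  df <- data.frame(.y = y, Xs, check.names = FALSE)
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 500,
                        MaxNWts = 5000, reltol = 1e-12)
  structure(list(fit = fit, center = ctr, scale = scl, classes = levels(y)),
            class = "window_clf")
}

#' @param object a `window_clf`.
#' @param newdata feature matrix to score.
#' @param ... unused.
#' @return matrix of class posteriors (rows sum to 1).
#' @rdname fit_window_classifier
#' @export
predict.window_clf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- names(object$center)
  Xs <- scale(newdata, object$center, object$scale)
  pr <- stats::predict(object$fit, newdata = as.data.frame(Xs), type = "probs")
  if (is.null(dim(pr))) {  # binary: multinom returns P(class 2)
    pr <- cbind(1 - pr, pr)
  }
  colnames(pr) <- object$classes
  pr
}

#' Posterior matrix for a raw stream
#'
#' Convenience wrapper: window the stream, extract features, score with the
#' window classifier.
#'
#' @param stream a `tri_stream`.
#' @param clf a fitted `window_clf`.
#' @param epoch_len_s epoch length in seconds.
#' @return matrix (epochs x classes) of posteriors.
#' @export
epoch_posteriors <- function(stream, clf, epoch_len_s = 30) {
  wins <- window_stream(stream, epoch_len_s)
  if (!length(wins)) return(matrix(numeric(0), 0, length(clf$classes),
                                   dimnames = list(NULL, clf$classes)))
  feats <- t(vapply(wins, extract_window_features,
                    numeric(13), sample_rate_hz = stream$sample_rate_hz))
  predict(clf, feats)
}
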