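#' Estimate HMM smoothing parameters from label sequences
#'
#' Transition probabilities are smoothed empirical bigram frequencies,
#' `A[i,j] = (n_ij + c) / (n_i. + K c)` with pseudocount `c`; the prior over
#' classes is taken from marginal class frequencies by default (with few
#' long sequences the marginal is far better determined than the initial
#' state) or from sequence-initial states.
#'
#' @param sequences list of label vectors (factor/character) over `classes`.
#' @param pseudocount nonnegative smoothing constant added to every cell.
#' @param classes class labels; defaults to the union of observed labels.
#' @param pi_method `"marginal"` or `"initial"`.
#' @return object of class `hmm_params`: list with `classes`, `pi`,
#'   `transition`, `pseudocount`.
#' @export
estimate_hmm <- function(sequences, pseudocount = 1,
                         classes = NULL, pi_method = c("marginal", "initial")) {
  pi_method <- match.arg(pi_method)
  if (!length(sequences)) stopf("need at least one sequence")
  if (is.null(classes))
    classes <- sort(unique(unlist(lapply(sequences, as.character))))
  K <- length(classes)
  counts <- matrix(0, K, K, dimnames = list(classes, classes))
  marg <- stats::setNames(numeric(K), classes)
  init <- stats::setNames(numeric(K), classes)
  for (s in sequences) {
    s <- as.character(s)
    if (!all(s %in% classes)) stopf("sequence contains labels outside classes")
    tb <- table(factor(s, classes))
    marg <- marg + as.numeric(tb)
    init[s[1]] <- init[s[1]] + 1
    if (length(s) > 1) {
      from <- factor(s[-length(s)], classes)
      to <- factor(s[-1], classes)
      counts <- counts + table(from, to)
    }
  }
  rs <- rowSums(counts)
  if (pseudocount == 0 && any(rs == 0))
    stopf("class '%s' never occurs as a source state and pseudocount is 0",
          classes[which(rs == 0)[1]])
  A <- (counts + pseudocount) / (rs + K * pseudocount)
  p <- if (pi_method == "marginal") marg else init
  if (sum(p) == 0) p <- rep(1, K)
  structure(list(classes = classes, pi = p / sum(p),
                 transition = A, pseudocount = pseudocount),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("HMM smoothing parameters over", length(x$classes), "classes\n")
  cat("pi:", paste(sprintf("%s=%.3f", x$classes, x$pi), collapse = " "), "\n")
  cat("transition matrix:\n")
  print(round(x$transition, 3))
  invisible(x)
}

#' Viterbi decoding of epoch posteriors
#'
#' Maximum a posteriori state path through per-epoch class posteriors under
#' the HMM. By default the emission score for class `c` at epoch `t` is the
#' scaled likelihood `posterior_t(c) / pi(c)` — the correct generative
#' emission term when the classifier was trained under non-uniform class
#' priors; `emission = "raw"` uses the posteriors unmodified. All arithmetic
#' is in log space with probabilities floored at 1e-12; ties in the
#' back-pointers break toward the lower class index.
#'
#' @param posteriors matrix (epochs x classes), rows summing to 1.
#' @param hmm an [estimate_hmm()] result.
#' @param emission `"scaled"` (default) or `"raw"`.
#' @return factor vector of decoded labels, one per epoch.
#' @export
viterbi_decode <- function(posteriors, hmm, emission = c("scaled", "raw")) {
  emission <- match.arg(emission)
  posteriors <- as.matrix(posteriors)
  K <- length(hmm$classes)
  if (ncol(posteriors) != K)
    stopf("posterior columns (%d) do not match hmm classes (%d)",
          ncol(posteriors), K)
  Tn <- nrow(posteriors)
  if (Tn == 0) return(factor(character(0), levels = hmm$classes))
  floorp <- 1e-12
  if (any(rowSums(posteriors) < floorp))
    warning("epoch with all-zero posteriors; numeric floor applied")
  em <- pmax(posteriors, floorp)
  if (emission == "scaled") em <- sweep(em, 2, pmax(hmm$pi, floorp), "/")
  logE <- log(em)
  logA <- log(pmax(hmm$transition, floorp))
  logPi <- log(pmax(hmm$pi, floorp))

  delta <- logPi + logE[1, ]
  back <- matrix(0L, Tn, K)
  if (Tn > 1) {
    for (t in 2:Tn) {
      cand <- delta + logA           # cand[i, j] = delta_i + log A[i -> j]
      bp <- max.col(t(cand), ties.method = "first")
      back[t, ] <- bp
      delta <- cand[cbind(bp, seq_len(K))] + logE[t, ]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)       # which.max: first max = lower index
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- back[t + 1, path[t + 1]]
  factor(hmm$classes[path], levels = hmm$classes)
}

#' Log-score of a state path
#'
#' The quantity Viterbi maximises: log prior + log transitions + log
#' emissions, with the same emission convention and numeric floor as
#' [viterbi_decode()]. Useful for verifying decoder optimality.
#'
#' @param path integer or factor state path.
#' @inheritParams viterbi_decode
#' @return scalar log score.
#' @export
path_logscore <- function(path, posteriors, hmm, emission = c("scaled", "raw")) {
  emission <- match.arg(emission)
  floorp <- 1e-12
  idx <- if (is.numeric(path)) as.integer(path) else
    match(as.character(path), hmm$classes)
  em <- pmax(as.matrix(posteriors), floorp)
  if (emission == "scaled") em <- sweep(em, 2, pmax(hmm$pi, floorp), "/")
  s <- log(pmax(hmm$pi[idx[1]], floorp)) + log(em[1, idx[1]])
  if (length(idx) > 1) {
    A <- pmax(hmm$transition, floorp)
    tr <- A[cbind(idx[-length(idx)], idx[-1])]
    s <- s + sum(log(tr)) + sum(log(em[cbind(2:length(idx), idx[-1])]))
  }
  unname(s)
}

#' Quantify the benefit of HMM smoothing over independent argmax
#'
#' Simulates first-order Markov label sequences (uniform classes,
#' configurable self-transition probability) and noisy per-epoch posteriors
#' that put `post_correct` mass on an observed class which equals the truth
#' with probability `post_correct`. Each replicate is decoded both by
#' independent per-epoch argmax and by Viterbi under the true transition
#' model, and per-epoch accuracies are compared.
#'
#' @param n_seq number of replicate sequences.
#' @param len sequence length in epochs (2880 = one day of 30-s epochs).
#' @param self_prob self-transition probability of the true chain.
#' @param post_correct posterior mass on the observed class, and the
#'   probability that the observed class is the true one.
#' @param n_classes number of activity classes.
#' @param seed integer seed.
#' @return data.frame with per-replicate `acc_argmax`, `acc_viterbi`.
#' @export
hmm_smoothing_benefit <- function(n_seq = 200, len = 2880, self_prob = 0.95,
                                  post_correct = 0.6, n_classes = 4,
                                  seed = 1) {
  K <- n_classes
  A <- matrix((1 - self_prob) / (K - 1), K, K)
  diag(A) <- self_prob
  classes <- paste0("c", seq_len(K))
  dimnames(A) <- list(classes, classes)
  hmm <- structure(list(classes = classes, pi = rep(1 / K, K),
                        transition = A, pseudocount = 0),
                   class = "hmm_params")
  set.seed(derive_seed(seed, "hmmbenefit"))
  out <- vapply(seq_len(n_seq), function(r) {
    truth <- integer(len)
    truth[1] <- sample.int(K, 1)
    flips <- stats::runif(len - 1) > self_prob
    for (t in 2:len) {
      truth[t] <- if (flips[t - 1])
        sample(setdiff(seq_len(K), truth[t - 1]), 1) else truth[t - 1]
    }
    correct <- stats::runif(len) < post_correct
    obs <- ifelse(correct, truth,
                  (truth - 1 + sample.int(K - 1, len, replace = TRUE)) %% K + 1)
    post <- matrix((1 - post_correct) / (K - 1), len, K)
    post[cbind(seq_len(len), obs)] <- post_correct
    vit <- as.integer(viterbi_decode(post, hmm))
    c(mean(obs == truth), mean(vit == truth))
  }, numeric(2))
  data.frame(acc_argmax = out[1, ], acc_viterbi = out[2, ])
}
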