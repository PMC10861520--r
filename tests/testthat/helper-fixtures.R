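# shared fixtures, built once per test run and cached in this environment
.fixture_env <- new.env(parent = emptyenv())

# the default-condition synthetic study (reference-population group sizes,
# 14 days); used by the pipeline-level and acceptance tests
fixture_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- effect_config(seed = 20260901L)
    .fixture_env$study <- simulate_study(cfg, n_hc = 30, n_ra_mod = 13,
                                         n_ra_sev = 15, n_days = 14)
  }
  .fixture_env$study
}

fixture_groups <- function() {
  st <- fixture_study()
  stats::setNames(as.character(st$cohort$group), st$cohort$participant_id)
}

# vectorised exhaustive path search: scores every state path and returns the
# best score; independent of the dynamic-programming decoder
brute_force_best <- function(post, hmm, emission = "scaled") {
  K <- length(hmm$classes)
  Tn <- nrow(post)
  floorp <- 1e-12
  em <- pmax(post, floorp)
  if (emission == "scaled") em <- sweep(em, 2, pmax(hmm$pi, floorp), "/")
  logE <- log(em)
  logA <- log(pmax(hmm$transition, floorp))
  logPi <- log(pmax(hmm$pi, floorp))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  sc <- logPi[paths[, 1]] + logE[cbind(1, paths[, 1])]
  if (Tn > 1) for (t in 2:Tn) {
    sc <- sc + logA[cbind(paths[, t - 1], paths[, t])] +
      logE[cbind(t, paths[, t])]
  }
  list(score = max(sc), path = paths[which.max(sc), ])
}

random_hmm <- function(K) {
  A <- matrix(stats::rgamma(K * K, 1), K)
  A <- A / rowSums(A)
  pi <- stats::rgamma(K, 1); pi <- pi / sum(pi)
  cl <- paste0("s", seq_len(K))
  dimnames(A) <- list(cl, cl)
  structure(list(classes = cl, pi = pi, transition = A, pseudocount = 0),
            class = "hmm_params")
}

random_posteriors <- function(Tn, K) {
  post <- matrix(stats::rgamma(Tn * K, 1), Tn)
  post / rowSums(post)
}

# an activity sequence built directly from labels (bypasses the simulator)
make_seq <- function(labels, epoch_len_s = 30, n_days = NULL,
                     classes = activity_classes("broad")) {
  n <- length(labels)
  structure(list(participant_id = "T001", epoch_len_s = epoch_len_s,
                 epoch_start_s = (seq_len(n) - 1) * epoch_len_s,
                 labels = factor(labels, levels = classes),
                 n_days = n_days %||% ceiling(n * epoch_len_s / 86400)),
            class = "activity_seq")
}
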