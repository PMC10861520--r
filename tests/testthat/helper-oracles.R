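# independent small-sample enumeration oracles for the rank tests

# exhaustive two-sample permutation p-value for the rank-sum statistic
perm_mwut_p <- function(x, y) {
  pool <- c(x, y)
  n <- length(pool); nx <- length(x)
  idx <- utils::combn(n, nx)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  us <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# exhaustive permutation p-value for the Kruskal-Wallis statistic, written
# from the textbook rank-sum formula H = 12/(n(n+1)) sum n_i rbar_i^2 - 3(n+1)
perm_kw_p <- function(groups) {
  sizes <- lengths(groups)
  r <- rank(unlist(groups))
  n <- length(r)
  h_stat <- function(assign) {
    rs <- tapply(r, assign, mean)
    12 / (n * (n + 1)) * sum(sizes * rs^2) - 3 * (n + 1)
  }
  obs <- h_stat(rep(seq_along(sizes), sizes))
  hs <- c()
  walk <- function(idx, left_sizes, assign) {
    if (length(left_sizes) == 1) {
      assign[idx] <- length(sizes)
      hs <<- c(hs, h_stat(assign))
      return(invisible())
    }
    g <- length(sizes) - length(left_sizes) + 1
    for (pick in utils::combn(idx, left_sizes[1], simplify = FALSE)) {
      a2 <- assign; a2[pick] <- g
      walk(setdiff(idx, pick), left_sizes[-1], a2)
    }
  }
  walk(seq_len(n), sizes, integer(n))
  mean(hs >= obs - 1e-12)
}
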