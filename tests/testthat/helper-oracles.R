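# Independent brute-force oracles used to pin the optimized implementations.
# These are written in plain R with explicit loops / dense matrices and share
# no code with the package internals.

# AR(1) draw with unit innovations, fixed seed
oracle_ar1 <- function(phi, n, seed, n_start = 200) {
  withr::with_seed(seed, {
    e <- rnorm(n + n_start)
    x <- numeric(n + n_start)
    for (t in 2:(n + n_start)) x[t] <- phi * x[t - 1] + e[t]
    x[(n_start + 1):(n_start + n)]
  })
}

# Entropy trio by direct counting.  Template starts j = 1..N-m; counts cm /
# cm1 include the self-match; SampEn pair counts exclude it.
oracle_entropy <- function(x, m = 2L, r = 0.2) {
  N <- length(x)
  M <- N - m
  tol <- r * sqrt(mean((x - mean(x))^2))
  tpl <- sapply(0:m, function(k) x[(1:M) + k])  # M x (m+1)
  cm <- cm1 <- integer(M)
  for (q in 1:M) {
    dmax <- rep(0, M)
    for (k in 1:m) dmax <- pmax(dmax, abs(tpl[, k] - tpl[q, k]))
    hit <- dmax <= tol
    cm[q] <- sum(hit)
    cm1[q] <- sum(hit & abs(tpl[, m + 1] - tpl[q, m + 1]) <= tol)
  }
  B <- (sum(cm) - M) / 2
  A <- (sum(cm1) - M) / 2
  list(exps = -log(cm1 / cm),
       apen = mean(-log(cm1 / cm)),
       sampen = if (B == 0) NA_real_ else if (A == 0) Inf else -log(A / B))
}

# FNN fractions by explicit all-pairs search for one dimension.
oracle_fnn_dim <- function(x, d, tau, A = 10, B = 2, theiler = tau) {
  N <- length(x)
  M <- N - d * tau
  sigma <- sqrt(mean((x - mean(x))^2))
  emb <- sapply(0:(d - 1), function(k) x[(1:M) + k * tau])
  emb <- matrix(emb, nrow = M)
  n1 <- n2 <- ncomb <- used <- 0
  for (i in 1:M) {
    best <- Inf; nn <- -1
    for (j in 1:M) {
      if (abs(i - j) <= theiler) next
      dist2 <- sum((emb[i, ] - emb[j, ])^2)
      if (dist2 < best) { best <- dist2; nn <- j }
    }
    if (nn < 0) next
    used <- used + 1
    D <- sqrt(best)
    extra <- abs(x[i + d * tau] - x[nn + d * tau])
    t1 <- D > 0 && extra / D > A
    t2 <- sqrt(D^2 + extra^2) / sigma > B
    if (t1) n1 <- n1 + 1
    if (t2) n2 <- n2 + 1
    if (t1 || t2) ncomb <- ncomb + 1
  }
  c(test1 = n1 / used, test2 = n2 / used, combined = ncomb / used)
}

# DFA fluctuation for one window size by explicit per-window loops.
oracle_dfa_f <- function(x, n) {
  N <- length(x)
  y <- cumsum(x - mean(x))
  nw <- N %/% n
  starts <- c((seq_len(nw) - 1) * n + 1, N - seq_len(nw) * n + 1)
  ss <- 0; cnt <- 0
  for (s in starts) {
    seg <- y[s:(s + n - 1)]
    k <- 1:n
    fit <- lm(seg ~ k)
    ss <- ss + sum(residuals(fit)^2)
    cnt <- cnt + n
  }
  sqrt(ss / cnt)
}

# smoothed expSampEn representatives for one recording (used in the group
# statistics checks)
rep_from_values <- function(values, scale, smooth = 3600L, m = 2L, r = 0.2) {
  bin <- as.numeric(binarize_median(values)$values)
  av <- moving_average(bin, scale)
  sm <- moving_average(exp_sampen(av, m = m, r = r)$values, smooth)
  representative_values(sm)
}
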