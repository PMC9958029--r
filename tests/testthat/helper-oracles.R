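# Independent oracles used by both the module tests and the acceptance
# suite. They share only the statistic definitions, not the search or
# permutation code paths of the package.

# exhaustive single-breakpoint search over the same arc statistic: the
# independent oracle for segment_track on short tracks
oracle_two_segment <- function(x, alpha = 0.01, n_perm = 2000) {
  n <- length(x)
  z_at <- function(v, b) {
    m1 <- mean(v[1:b])
    m2 <- mean(v[(b + 1):n])
    abs(m1 - m2) / sqrt(1 / b + 1 / (n - b))
  }
  zs <- vapply(1:(n - 1), function(b) z_at(x, b), 0)
  b <- which.max(zs)
  count <- 0
  for (i in seq_len(n_perm)) {
    xp <- sample(x)
    if (max(vapply(1:(n - 1), function(bb) z_at(xp, bb), 0)) >=
          zs[b] - 1e-12) {
      count <- count + 1
    }
  }
  p <- (1 + count) / (1 + n_perm)
  if (p < alpha) {
    data.frame(start = c(1, b + 1), end = c(b, n),
               mean = c(mean(x[1:b]), mean(x[(b + 1):n])))
  } else {
    data.frame(start = 1, end = n, mean = mean(x))
  }
}

# exact rank-sum p by enumerating every group assignment (tie-free input)
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combos <- combn(length(pooled), n1)
  ws <- apply(combos, 2, function(i) sum(r[i]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
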