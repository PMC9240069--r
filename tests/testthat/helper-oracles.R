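# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately avoid the code paths (and the library
# calls) they verify.

# Step-up Benjamini-Hochberg from the definition: adj_(i) = min_{j >= i}
# min(1, m * p_(j) / j), mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- pmin(1, m * ranked / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) draws from a universe whose first K elements are "significant".
hyper_enum_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Weighted running-sum enrichment score computed position by position over
# the full ranked list.
es_oracle <- function(metric, is_hit, weight = 1) {
  N <- length(metric)
  n <- sum(is_hit)
  w <- abs(metric)^weight
  tot <- sum(w[is_hit])
  inc <- if (tot > 0) w / tot else rep(1 / n, N)
  step <- ifelse(is_hit, inc, -1 / (N - n))
  running <- cumsum(step)
  hi <- max(running)
  lo <- min(running)
  # maximum deviation from zero; near-exact ties resolve to the positive side
  if (hi >= -lo - 1e-12) hi else lo
}

# Two-group log-rank chi-square from the observed-minus-expected table,
# with the standard hypergeometric variance (handles tied event times).
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(list(chisq = 0, p = 1))
  chisq <- (o1 - e1)^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Welch t from the closed-form textbook formulas.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# One-way ANOVA F from between/within sums of squares.
anova_oracle <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}
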