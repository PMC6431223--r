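# Independent brute-force oracles used across the suite. These deliberately
# take the slow, direct route (textbook formulas, full enumeration) so they
# share no code path with the package implementation.

# textbook Pearson r: covariance over the product of standard deviations
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_pearson_p <- function(x, y) {
  n <- length(x)
  r <- oracle_pearson(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), n - 2)
}

# Spearman rho = Pearson on mid-ranks
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# exact two-sided permutation p for Spearman rho, by explicit loop
oracle_spearman_exact_p <- function(x, y) {
  n <- length(y)
  perms <- oracle_perms(n)
  r_obs <- abs(oracle_spearman(x, y))
  hits <- 0L
  for (i in seq_len(nrow(perms))) {
    if (abs(oracle_spearman(x, y[perms[i, ]])) >= r_obs - 1e-12)
      hits <- hits + 1L
  }
  hits / nrow(perms)
}

oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Benjamini-Hochberg by the definitional step-up construction
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided Fisher exact p by hypergeometric point-mass enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tie-corrected Kruskal-Wallis H from the rank-sum formula
oracle_kruskal_H <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# average silhouette width from the definition, via the full distance matrix
oracle_avg_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k)
      mean(d[i, labels == k]), numeric(1L)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# minimal-swap fraction between labelings by exhaustive permutation
oracle_swap_rate <- function(la, lb) {
  k <- max(la, lb)
  perms <- oracle_perms(k)
  best <- 0L
  for (i in seq_len(nrow(perms))) {
    best <- max(best, sum(perms[i, ][lb] == la))
  }
  1 - best / length(la)
}

# a tiny hand-buildable alignment
toy_alignment <- function(rows, reference_id = names(rows)[1L],
                          annotations = NULL) {
  plastome_alignment(rows, reference_id, annotations)
}
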