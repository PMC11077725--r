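# Independent brute-force oracles used to check the package's statistics.
# These deliberately use naive formulations (pair enumeration, direct
# combinatorial sums, permutation averaging) distinct from the
# implementations they verify.

# Silhouette by the textbook definition, point by point.
brute_silhouette <- function(points, labels) {
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(vapply(which(labels == l), function(j) d(i, j), numeric(1)))
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Hypergeometric pmf and upper tail by direct choose() sums.
brute_hyper_pmf <- function(x, N, K, n) choose(K, x) * choose(N - K, n - x) / choose(N, n)
brute_hyper_sf <- function(k, N, K, n) {
  support <- max(0, n + K - N):min(K, n)
  sum(brute_hyper_pmf(support[support >= k], N, K, n))
}

# Fowlkes-Mallows by explicit enumeration of all unordered pairs.
brute_fms <- function(p, q) {
  n <- length(p)
  tp <- fp <- fn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- p[i] == p[j]; sq <- q[i] == q[j]
    if (sp && sq) tp <- tp + 1
    else if (sp) fp <- fp + 1
    else if (sq) fn <- fn + 1
  }
  if (tp + fp == 0 || tp + fn == 0) return(0)
  tp / sqrt((tp + fp) * (tp + fn))
}

# Mutual information (nats) of two label vectors.
brute_mi <- function(p, q) {
  n <- length(p)
  mi <- 0
  for (a in unique(p)) for (b in unique(q)) {
    nij <- sum(p == a & q == b)
    if (nij == 0) next
    mi <- mi + (nij / n) * log(n * nij / (sum(p == a) * sum(q == b)))
  }
  mi
}

brute_entropy <- function(p) {
  f <- table(p) / length(p)
  -sum(f * log(f))
}

# Expected MI by direct summation of the hypergeometric model with plain
# factorials (exact for the small n used in tests).
brute_emi <- function(p, q) {
  N <- length(p)
  a <- as.vector(table(p)); b <- as.vector(table(q))
  emi <- 0
  for (ai in a) for (bj in b) {
    for (nij in max(1, ai + bj - N):min(ai, bj)) {
      if (nij < max(1, ai + bj - N)) next
      prob <- (factorial(ai) * factorial(bj) * factorial(N - ai) *
                 factorial(N - bj)) /
        (factorial(N) * factorial(nij) * factorial(ai - nij) *
           factorial(bj - nij) * factorial(N - ai - bj + nij))
      emi <- emi + (nij / N) * log(N * nij / (ai * bj)) * prob
    }
  }
  emi
}

brute_amis <- function(p, q) {
  hu <- brute_entropy(p); hv <- brute_entropy(q)
  if (hu == 0 && hv == 0) return(1)
  mi <- brute_mi(p, q)
  emi <- brute_emi(p, q)
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(1)
  (mi - emi) / denom
}

# Expected MI by exhaustive permutation averaging — the definition of the
# permutation model. Only usable for very small n.
perm_emi <- function(p, q) {
  n <- length(q)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  mean(vapply(perms(seq_len(n)), function(ix) brute_mi(p, q[ix]), numeric(1)))
}

# All set partitions of n items into at most max_blocks blocks, as integer
# label vectors (restricted growth strings).
all_partitions <- function(n, max_blocks = n) {
  out <- list()
  grow <- function(labels, k) {
    if (length(labels) == n) { out[[length(out) + 1]] <<- labels; return() }
    for (b in seq_len(min(k + 1, max_blocks)))
      grow(c(labels, b), max(k, b))
  }
  grow(integer(0), 0)
  out
}
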