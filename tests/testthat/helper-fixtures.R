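# Shared fixtures and independent brute-force oracles.

# random count matrix with minimal three-group metadata
make_cm <- function(n_mirna = 20, n_sample = 10, seed = 1, lambda = 50) {
  withr::with_seed(seed, {
    counts <- matrix(stats::rpois(n_mirna * n_sample, lambda),
                     nrow = n_mirna,
                     dimnames = list(sprintf("mir-%03d", seq_len(n_mirna)),
                                     sprintf("S%02d", seq_len(n_sample))))
    grp <- rep(c("PC", "BTC", "HC"), length.out = n_sample)
    meta <- data.frame(sample_id = colnames(counts), group = grp,
                       age = round(stats::runif(n_sample, 30, 75)),
                       gender = sample(c("M", "F"), n_sample, replace = TRUE),
                       bmi = round(stats::runif(n_sample, 18, 30), 1),
                       stringsAsFactors = FALSE)
    count_matrix(counts, meta)
  })
}

# direct step-up BH formula: min over j >= i of p_(j) * m / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive KNN with the same tie-break contract, written as plain loops
bf_knn <- function(train, labels, query, k) {
  d <- apply(train, 1, function(r) sqrt(sum((r - query)^2)))
  nn <- order(d)[1:k]
  lab <- as.character(labels)[nn]
  tab <- table(lab)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    s <- sapply(top, function(l) sum(d[nn][lab == l]))
    top <- top[s == min(s)]
    top <- sort(top)[1]
  }
  top
}

# double-loop silhouette with singleton convention s = 0
bf_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in 1:n) {
    same <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(d[i, same])
    b <- Inf
    for (l in unique(labels)) {
      if (l == labels[i]) next
      b <- min(b, mean(d[i, labels == l]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# straight-line TMM factor for a single pair, unweighted (closed-form limit)
bf_tmm_unweighted_pair <- function(obs, ref, nobs, nref) {
  both <- obs > 0 & ref > 0
  m <- log2((obs[both] / nobs) / (ref[both] / nref))
  2^mean(m)
}
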