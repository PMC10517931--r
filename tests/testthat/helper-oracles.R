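# Independent brute-force oracles used to validate the package's
# implementations. Deliberately written in the most literal style possible
# and kept free of any package internals.

# window-recount smoothing: explicit double loop, synchronous update
oracle_refine <- function(map, domain = NULL) {
  sentinels <- c("BACKGROUND", "OUT_OF_STAGE")
  if (is.null(domain)) domain <- setdiff(unique(as.vector(map)), sentinels)
  out <- map
  for (r in seq_len(nrow(map))) {
    for (c in seq_len(ncol(map))) {
      if (!map[r, c] %in% domain) next
      votes <- character()
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nrow(map) || cc < 1 || cc > ncol(map)) next
        if (map[rr, cc] %in% domain) votes <- c(votes, map[rr, cc])
      }
      counts <- table(votes)
      winners <- names(counts)[counts == max(counts)]
      if (length(winners) == 1) out[r, c] <- winners
    }
  }
  out
}

# balanced accuracy recomputed class by class
oracle_balanced_accuracy <- function(cm) {
  recalls <- numeric(nrow(cm))
  for (k in seq_len(nrow(cm))) recalls[k] <- cm[k, k] / sum(cm[k, ])
  mean(recalls)
}

# multiclass MCC in the triple-sum form (Gorodkin), independent of the
# covariance-of-marginals form used by the package
oracle_mcc <- function(cm) {
  K <- nrow(cm)
  num <- 0
  for (k in 1:K) for (l in 1:K) for (m in 1:K)
    num <- num + cm[k, k] * cm[l, m] - cm[k, l] * cm[m, k]
  d1 <- 0
  for (k in 1:K) {
    row_k <- sum(cm[k, ])
    other <- 0
    for (kp in 1:K) if (kp != k) other <- other + sum(cm[kp, ])
    d1 <- d1 + row_k * other
  }
  d2 <- 0
  for (k in 1:K) {
    col_k <- sum(cm[, k])
    other <- 0
    for (kp in 1:K) if (kp != k) other <- other + sum(cm[, kp])
    d2 <- d2 + col_k * other
  }
  if (d1 == 0 || d2 == 0) return(NA_real_)
  num / sqrt(d1 * d2)
}

# random masked label map for refine testing
random_label_map <- function(nr, nc, n_labels, sentinel_frac = 0.2) {
  labs <- LETTERS[seq_len(n_labels)]
  m <- matrix(sample(labs, nr * nc, replace = TRUE), nr, nc)
  n_sent <- rbinom(1, nr * nc, sentinel_frac)
  if (n_sent > 0) {
    pos <- sample(nr * nc, n_sent)
    m[pos] <- sample(c("BACKGROUND", "OUT_OF_STAGE"), n_sent, replace = TRUE)
  }
  m
}
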