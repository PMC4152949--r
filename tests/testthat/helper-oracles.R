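# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops over the defining formulas, and a hand-rolled
# dynamic program for alignment identity.

DINUCS <- as.vector(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0)))

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Longest common subsequence length by textbook dynamic programming:
# the number of matches in a maximal-match global alignment with free
# gaps and zero mismatch score.
oracle_lcs <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

oracle_identity <- function(a, b) oracle_lcs(a, b) / min(nchar(a), nchar(b))

# Greedy length-descending clustering, re-derived from the contract with
# the DP identity above (independent of the package's alignment path).
oracle_cluster_ids <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), seq_along(seqs))
  reps <- integer(0)
  for (i in ord) {
    hit <- FALSE
    for (r in reps) {
      if (oracle_identity(seqs[i], seqs[r]) >= threshold) { hit <- TRUE; break }
    }
    if (!hit) reps <- c(reps, i)
  }
  sort(reps)
}

# Direct per-property loops over the correlation-distance definition.
oracle_theta_pair <- function(x, y, tab) {
  v <- tab$values
  s <- 0
  for (p in seq_len(nrow(v))) s <- s + (v[p, x] - v[p, y])^2
  s / nrow(v)
}

oracle_tier_correlations <- function(seq, lambda, tab) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  din <- vapply(seq_len(L - 1L), function(i) paste0(ch[i], ch[i + 1L]), "")
  vapply(seq_len(lambda), function(j) {
    s <- 0
    for (i in seq_len(L - 1L - j))
      s <- s + oracle_theta_pair(din[i], din[i + j], tab)
    s / (L - 1L - j)
  }, numeric(1))
}

oracle_psednc <- function(seq, w, lambda, tab) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  f <- setNames(numeric(16), DINUCS)
  for (i in seq_len(L - 1L)) {
    d <- paste0(ch[i], ch[i + 1L])
    f[d] <- f[d] + 1
  }
  f <- f / (L - 1L)
  theta <- oracle_tier_correlations(seq, lambda, tab)
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

oracle_metrics <- function(tp, tn, fp, fn) {
  den <- sqrt((tp + fn) * (tn + fn) * (tp + fp) * (tn + fp))
  list(sn = tp / (tp + fn), sp = tn / (tn + fp),
       acc = (tp + tn) / (tp + tn + fp + fn),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# Small standardized two-property table with hand-picked values, for
# tests that need full control over theta.
toy_property_table <- function() {
  raw <- rbind(p1 = 1:16, p2 = c(16:2, 1))
  colnames(raw) <- DINUCS
  standardize_properties(property_table(raw))
}
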