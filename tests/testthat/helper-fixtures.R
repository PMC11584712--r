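# shared fixtures and independent brute-force oracles

# count set whose columns are exact per-condition means (noiseless)
toyCountSet <- function(cond_means, n_reps = 3) {
  conds <- rep(conditionLevels(), each = n_reps)
  m <- do.call(cbind, lapply(conditionLevels(), function(cn) {
    matrix(rep(cond_means[, cn], n_reps), nrow = nrow(cond_means))
  }))
  rownames(m) <- rownames(cond_means)
  colnames(m) <- paste0(conds, "_", seq_along(conds))
  ParalogCountSet(m, setNames(conds, colnames(m)))
}

# brute-force Benjamini-Hochberg step-up with monotonicity enforcement
bruteBH <- function(p) {
  ok <- which(!is.na(p))
  m <- length(ok)
  out <- rep(NA_real_, length(p))
  if (m == 0) return(out)
  o <- order(p[ok])
  ranked <- p[ok][o]
  adj <- ranked * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out[ok][o] <- adj
  out
}

# brute-force two-sided Fisher exact p via hypergeometric enumeration
bruteFisherP <- function(nA, nB, k, N) {
  ks <- max(0, nA + nB - N):min(nA, nB)
  probs <- dhyper(ks, nA, N - nA, nB)
  sum(probs[probs <= dhyper(k, nA, N - nA, nB) * (1 + 1e-7)])
}

# brute-force basic bootstrap interval from the definition
bruteBasicCI <- function(values, alpha = 0.05, center = mean(values)) {
  q <- quantile(values, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(2 * center - q[2], 2 * center - q[1])
}

# brute-force median-of-ratios size factors
bruteSizeFactors <- function(m) {
  gm <- apply(m, 1, function(r) exp(mean(log(r))))
  use <- which(gm > 0 & apply(m, 1, function(r) all(r > 0)))
  vapply(seq_len(ncol(m)), function(j) median(m[use, j] / gm[use]),
         numeric(1))
}

# brute-force peak-gene link table by double loop (positions, not GRanges)
bruteLinks <- function(pk_chr, pk_point, tss_chr, tss_pos, tss_strand,
                       gene_id, max_dist) {
  rows <- list()
  for (i in seq_along(pk_point)) {
    for (j in seq_along(tss_pos)) {
      if (pk_chr[i] != tss_chr[j]) next
      d <- (pk_point[i] - tss_pos[j]) * (if (tss_strand[j] == "-") -1 else 1)
      if (abs(d) <= max_dist)
        rows[[length(rows) + 1L]] <- data.frame(gene = gene_id[j], peak = i,
                                                distance = d)
    }
  }
  if (!length(rows)) return(data.frame(gene = character(), peak = integer(),
                                       distance = integer()))
  do.call(rbind, rows)
}

# random small gene-id sets for property tests
randomSets <- function(n, universe = 200, max_size = 60) {
  lapply(seq_len(n), function(i)
    sample(sprintf("g%03d", seq_len(universe)), sample.int(max_size, 1)))
}
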