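# Independent reference implementations used as oracles. Deliberately
# naive (quadratic loops, no sorting tricks) so they share no code path
# with the package internals they check.

# O(n^2) double-loop cFDR: p_i * N_j / N_ij with inclusive counts
cfdr_oracle <- function(p_i, p_j) {
  n <- length(p_i)
  out <- numeric(n)
  for (s in seq_len(n)) {
    n_j <- 0L
    n_ij <- 0L
    for (t in seq_len(n)) {
      if (p_j[t] <= p_j[s]) {
        n_j <- n_j + 1L
        if (p_i[t] <= p_i[s]) n_ij <- n_ij + 1L
      }
    }
    out[s] <- min(1, p_i[s] * n_j / n_ij)
  }
  out
}

# full-pair-scan pruning oracle: no windows; each round finds the largest
# offending r2 pair (ties: first in row-major order) and discards its
# smaller-MAF member (MAF tie: later position)
prune_oracle <- function(r2, maf, pos, r2_max) {
  alive <- rep(TRUE, length(maf))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    sub <- r2[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- -Inf
    if (max(sub) <= r2_max) break
    hit <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- idx[hit[1]]; b <- idx[hit[2]]
    drop <- if (maf[a] < maf[b]) a
            else if (maf[b] < maf[a]) b
            else if (pos[a] > pos[b]) a else b
    alive[drop] <- FALSE
  }
  which(alive)
}

# direct double-loop LD scores with the r2 bias adjustment
ld_scores_oracle <- function(panel, window_kb) {
  m <- length(panel$snp_id)
  n <- panel$n_ind
  ell <- numeric(m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (abs(panel$pos[k] - panel$pos[j]) <= window_kb * 1000 &&
          panel$chrom[k] == panel$chrom[j]) {
        r2 <- stats::cor(panel$dosage[, j], panel$dosage[, k])^2
        ell[j] <- ell[j] + r2 - (1 - r2) / (n - 2)
      }
    }
  }
  ell
}
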