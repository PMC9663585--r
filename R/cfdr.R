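# Empirical conditional false discovery rate.
#
# cFDR(p_i | p_j) = Pr(H0(i) | P_i <= p_i, P_j <= p_j) is estimated by the
# empirical plug-in  p_i * N_j / N_ij  where N_j counts SNPs whose
# conditional-trait p-value is <= p_j and N_ij counts SNPs dominated in
# both coordinates. Counts are inclusive of the SNP itself (ties count,
# matching the "as small as or smaller" definition), so N_ij >= 1 always.

# dominance counts: for each row s, #{t : x[t] <= x[s] & y[t] <= y[s]},
# inclusive. O(n log n) with a Fenwick (binary indexed) tree; the O(n^2)
# oracle used in tests lives in the test helpers.
dominance_counts <- function(x, y) {
  n <- length(x)
  yr <- match(y, sort(unique(y)))            # dense ranks, ties share a rank
  k <- max(yr)
  tree <- integer(k)
  out <- integer(n)
  ord <- order(x)
  s <- 1L
  while (s <= n) {
    e <- s
    while (e < n && x[ord[e + 1L]] == x[ord[s]]) e <- e + 1L
    for (t in s:e) {                         # insert the whole x-tie group first
      i <- yr[ord[t]]
      while (i <= k) { tree[i] <- tree[i] + 1L; i <- i + bitwAnd(i, -i) }
    }
    for (t in s:e) {                         # then query (<= on both axes)
      i <- yr[ord[t]]
      cnt <- 0L
      while (i > 0L) { cnt <- cnt + tree[i]; i <- i - bitwAnd(i, -i) }
      out[ord[t]] <- cnt
    }
    s <- e + 1L
  }
  out
}

#' Per-SNP conditional false discovery rate
#'
#' Estimates, for every SNP, the posterior probability of being null for
#' the principal trait given that both traits' p-values are at least as
#' small as observed, via the empirical estimator
#' `p_i * N_j / N_ij` (capped at 1), where `N_j = #\{P_j <= p_j\}` and
#' `N_ij = #\{P_i <= p_i and P_j <= p_j\}`, counts inclusive of the SNP
#' itself.
#'
#' @param paired A nonempty paired tibble with columns `p_A`, `p_B`
#'   (conventionally LD-pruned, so that SNPs are near-independent).
#' @param principal `"A"` or `"B"`: the trait whose null hypothesis is
#'   being assessed; the other trait conditions.
#' @return Numeric vector of cFDR values in (0, 1], aligned with the rows
#'   of `paired`.
#' @export
compute_cfdr <- function(paired, principal = c("A", "B")) {
  principal <- match.arg(principal)
  assert_that(nrow(paired) > 0, "empty paired table")
  p_i <- if (principal == "A") paired$p_A else paired$p_B
  p_j <- if (principal == "A") paired$p_B else paired$p_A
  n_j <- rank(p_j, ties.method = "max")
  n_ij <- dominance_counts(p_i, p_j)
  pmin(1, p_i * n_j / n_ij)
}

#' Conjunction conditional FDR
#'
#' The per-SNP conjunction statistic is the maximum of the two reciprocal
#' conditional FDRs; a small value requires the SNP to look non-null for
#' both traits.
#'
#' @param cfdr_A_given_B,cfdr_B_given_A Aligned numeric vectors.
#' @return Element-wise maximum.
#' @export
compute_ccfdr <- function(cfdr_A_given_B, cfdr_B_given_A) {
  assert_that(length(cfdr_A_given_B) == length(cfdr_B_given_A),
              "cFDR vectors differ in length")
  pmax(cfdr_A_given_B, cfdr_B_given_A)
}

#' Full per-SNP cFDR/ccFDR result table
#'
#' Computes both conditioning directions and the conjunction statistic and
#' attaches the significance flags at the given thresholds (strict `<`).
#'
#' @param paired A paired tibble (pruned).
#' @param cfdr_max Threshold for trait association (default 0.05).
#' @param ccfdr_max Threshold for the pleiotropy call (default 0.05).
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `p_A`, `p_B`,
#'   `cfdr_A_given_B`, `cfdr_B_given_A`, `ccfdr`, `sig_A`, `sig_B`,
#'   `sig_pleio`.
#' @export
cfdr_table <- function(paired, cfdr_max = 0.05, ccfdr_max = 0.05) {
  ca <- compute_cfdr(paired, "A")
  cb <- compute_cfdr(paired, "B")
  cc <- compute_ccfdr(ca, cb)
  keep <- intersect(c("snp_id", "chrom", "pos", "p_A", "p_B"), names(paired))
  out <- dplyr::bind_cols(
    paired[, keep],
    tibble::tibble(cfdr_A_given_B = ca, cfdr_B_given_A = cb, ccfdr = cc,
                   sig_A = ca < cfdr_max, sig_B = cb < cfdr_max,
                   sig_pleio = cc < ccfdr_max)
  )
  attr(out, "thresholds") <- c(cfdr = cfdr_max, ccfdr = ccfdr_max)
  out
}

#' Call trait-associated and pleiotropic SNPs
#'
#' @param result A tibble from [cfdr_table()].
#' @param cfdr_max Conditional FDR threshold, strict (default 0.05).
#' @param ccfdr_max Conjunction threshold, strict (default 0.05).
#' @param principal Which trait's association calls to report (default "A").
#' @return List with `trait` (SNP ids with cFDR below `cfdr_max` for the
#'   principal trait) and `pleiotropic` (SNP ids with ccFDR below
#'   `ccfdr_max`).
#' @export
call_significant <- function(result, cfdr_max = 0.05, ccfdr_max = 0.05,
                             principal = c("A", "B")) {
  principal <- match.arg(principal)
  col <- if (principal == "A") "cfdr_A_given_B" else "cfdr_B_given_A"
  ids <- if ("snp_id" %in% names(result)) result$snp_id else seq_len(nrow(result))
  list(trait = ids[result[[col]] < cfdr_max],
       pleiotropic = ids[result$ccfdr < ccfdr_max])
}
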