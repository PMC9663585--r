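#' Construct a reference genotype panel
#'
#' A genotype panel holds a dosage matrix (individuals x SNPs, values in
#' [0, 2]), SNP identifiers, positions, and per-SNP allele frequency.
#' Missing dosages are mean-imputed per SNP at construction so that all
#' correlation machinery downstream sees a complete matrix.
#'
#' @param dosage Numeric matrix, individuals in rows, SNPs in columns.
#' @param snp_id Character vector of SNP ids, one per column.
#' @param pos Integer base-pair positions (1-based), one per column.
#' @param chrom Chromosome labels, one per column (default all "1").
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, snp_id, pos, chrom = rep("1", length(snp_id))) {
  dosage <- as.matrix(dosage)
  assert_that(ncol(dosage) == length(snp_id), "snp_id length must match columns")
  assert_that(ncol(dosage) == length(pos), "pos length must match columns")
  assert_that(!anyDuplicated(snp_id), "duplicated snp ids in panel")
  if (anyNA(dosage)) {
    mu <- colMeans(dosage, na.rm = TRUE)
    idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[idx] <- mu[idx[, 2]]
  }
  freq <- colMeans(dosage) / 2
  structure(
    list(dosage = dosage, snp_id = as.character(snp_id),
         pos = as.integer(pos), chrom = as.character(chrom),
         maf = pmin(freq, 1 - freq), n_ind = nrow(dosage)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", x$n_ind, " individuals x ", length(x$snp_id),
      " SNPs; MAF range [", round(min(x$maf), 3), ", ", round(max(x$maf), 3),
      "]\n", sep = "")
  invisible(x)
}

panel_index <- function(panel, snp) {
  if (is.character(snp)) {
    i <- match(snp, panel$snp_id)
    assert_that(!anyNA(i), paste0("SNP(s) absent from panel: ",
                                  paste(snp[is.na(i)], collapse = ", ")))
    i
  } else {
    as.integer(snp)
  }
}

#' Squared genotype correlation between two panel SNPs
#'
#' The LD measure r-squared: the square of the Pearson correlation of the
#' two dosage columns.
#'
#' @param panel A [genotype_panel()].
#' @param i,j SNP index or SNP id.
#' @return Squared correlation in [0, 1].
#' @export
pairwise_r2 <- function(panel, i, j) {
  i <- panel_index(panel, i); j <- panel_index(panel, j)
  x <- panel$dosage[, i]; y <- panel$dosage[, j]
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "constant dosage column: r2 undefined")
  stats::cor(x, y)^2
}

# r2 matrix for a set of panel columns (constant columns yield NA -> treated 0)
r2_matrix <- function(panel, idx) {
  x <- panel$dosage[, idx, drop = FALSE]
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  r^2
}

#' Greedy LD-based pruning of a paired summary table
#'
#' Removes one SNP of every high-LD pair so that the surviving set has no
#' retained within-window pair with r-squared exceeding `r2_max` (strict:
#' a pair at exactly `r2_max` is kept). When a pair exceeds the threshold
#' the member with the smaller minor allele frequency is discarded; on an
#' exact MAF tie the later-positioned SNP is discarded. Windows slide over
#' position-sorted SNPs (`window` SNPs wide, advancing by `step`), the
#' standard toolkit mechanic for this filter; within a window the worst
#' (largest r-squared) offending pair is resolved first, deterministically.
#'
#' @param paired A paired tibble from [harmonize_and_merge()].
#' @param panel A [genotype_panel()] covering the paired SNPs.
#' @param r2_max Pruning threshold, default 0.2; pairs with r2 strictly
#'   greater are broken up.
#' @param window Window width in SNPs (default 50).
#' @param step Window advance in SNPs (default 5).
#' @param on_missing What to do with paired SNPs absent from the panel:
#'   `"drop"` (default) or `"error"`.
#' @return The pruned paired tibble (a subset of the input rows).
#' @export
ld_prune <- function(paired, panel, r2_max = 0.2, window = 50, step = 5,
                     on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  assert_that(r2_max >= 0 && r2_max <= 1, "r2_max must be in [0,1]")
  assert_that(window >= 2 && step >= 1, "window must be >= 2 and step >= 1")
  idx_panel <- match(paired$snp_id, panel$snp_id)
  if (anyNA(idx_panel)) {
    if (on_missing == "error") {
      stop("paired SNP(s) missing from panel: ",
           paste(utils::head(paired$snp_id[is.na(idx_panel)], 5), collapse = ", "),
           call. = FALSE)
    }
    ps_log("prune: dropped ", sum(is.na(idx_panel)), " SNP(s) without panel coverage")
  }
  keep_rows <- which(!is.na(idx_panel))
  if (length(keep_rows) == 0) return(paired[0, ])
  ord <- keep_rows[order(as.integer(paired$chrom[keep_rows]), paired$pos[keep_rows])]
  pidx <- idx_panel[ord]                      # panel column per ordered SNP
  maf <- panel$maf[pidx]
  pos <- paired$pos[ord]
  m <- length(ord)
  alive <- rep(TRUE, m)

  starts <- seq(1L, max(1L, m - 1L), by = step)
  for (s in starts) {
    win <- s:min(s + window - 1L, m)
    repeat {
      cur <- win[alive[win]]
      if (length(cur) < 2) break
      r2 <- r2_matrix(panel, pidx[cur])
      r2[lower.tri(r2, diag = TRUE)] <- -Inf
      worst <- max(r2)
      if (worst <= r2_max) break
      hit <- which(r2 == worst, arr.ind = TRUE)[1, ]   # first pair, row-major det.
      a <- cur[hit[1]]; b <- cur[hit[2]]
      drop <- if (maf[a] < maf[b]) a
              else if (maf[b] < maf[a]) b
              else if (pos[a] > pos[b]) a else b       # tie: later position goes
      alive[drop] <- FALSE
    }
    if (max(win) >= m) break
  }
  out <- paired[sort(ord[alive]), , drop = FALSE]
  attr(out, "trait_A") <- attr(paired, "trait_A")
  attr(out, "trait_B") <- attr(paired, "trait_B")
  out
}

#' Per-SNP LD scores from a reference panel
#'
#' The LD score of SNP j is the sum, over panel SNPs within `window_kb`
#' kilobases of j on the same chromosome (self included), of the
#' bias-adjusted squared correlation `r2 - (1 - r2) / (n - 2)`, which
#' removes the upward finite-sample bias of the naive r-squared.
#'
#' @param panel A [genotype_panel()] with at least 3 individuals.
#' @param window_kb Window half-width in kb (default 1000, i.e. 1 Mb,
#'   a conventional stand-in for 1 centimorgan).
#' @return A tibble with columns `snp_id`, `ld_score`.
#' @export
ld_scores <- function(panel, window_kb = 1000) {
  assert_that(window_kb > 0, "window_kb must be positive")
  n <- panel$n_ind
  assert_that(n >= 3, "need at least 3 individuals for bias-adjusted r2")
  m <- length(panel$snp_id)
  x <- scale(panel$dosage)
  bad <- !is.finite(colSums(x))
  x[, bad] <- 0                               # constant SNPs contribute nothing
  pos <- panel$pos
  chrom <- panel$chrom
  win <- window_kb * 1000
  ell <- numeric(m)
  chunk <- 256L
  for (s in seq(1L, m, by = chunk)) {
    cols <- s:min(s + chunk - 1L, m)
    lo <- findInterval(pos[cols] - win, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos[cols] + win, pos)
    rng <- min(lo):max(hi)
    r <- crossprod(x[, cols, drop = FALSE], x[, rng, drop = FALSE]) / (n - 1)
    r2 <- r^2
    adj <- r2 - (1 - r2) / (n - 2)
    for (k in seq_along(cols)) {
      sel <- which(rng >= lo[k] & rng <= hi[k] & chrom[rng] == chrom[cols[k]])
      ell[k + s - 1L] <- sum(adj[k, sel])
    }
  }
  tibble::tibble(snp_id = panel$snp_id, ld_score = ell)
}

#' Is a candidate SNP a replication of a known association?
#'
#' A candidate is considered previously reported (a replication) when its
#' LD with a confirmed SNP is r-squared >= 0.6, boundary inclusive.
#'
#' @param r2 Squared correlation in [0, 1].
#' @return Logical.
#' @export
is_replication <- function(r2) {
  assert_that(all(r2 >= 0 & r2 <= 1), "r2 must lie in [0,1]")
  r2 >= 0.6
}

#' Read / write a genotype panel as plain text
#'
#' The text format is a tab-delimited matrix, individuals in rows and SNPs
#' in columns, with a header row of SNP ids and two leading metadata rows
#' (`#chrom` and `#pos`) giving each SNP's chromosome and position.
#'
#' @param path File path.
#' @return For `read_panel`, a [genotype_panel()].
#' @export
read_panel <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  assert_that(length(lines) >= 4, "panel file too short")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  chrom <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  pos <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  assert_that(identical(chrom[1], "#chrom") && identical(pos[1], "#pos"),
              "panel file must carry #chrom and #pos metadata rows")
  body <- utils::read.table(text = lines[-(1:3)], sep = "\t")
  genotype_panel(as.matrix(body), snp_id = header,
                 pos = as.integer(pos[-1]), chrom = chrom[-1])
}

#' @rdname read_panel
#' @param panel A [genotype_panel()].
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(panel$snp_id, collapse = "\t"), con)
  writeLines(paste(c("#chrom", panel$chrom), collapse = "\t"), con)
  writeLines(paste(c("#pos", panel$pos), collapse = "\t"), con)
  utils::write.table(panel$dosage, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read precomputed LD scores from two-column delimited text
#'
#' @param path File with columns `snp_id` and `ld_score` (header required).
#' @return A tibble with columns `snp_id`, `ld_score`.
#' @export
read_ld_scores <- function(path) {
  tab <- readr::read_table(path, col_types = "cd", progress = FALSE)
  assert_that(all(c("snp_id", "ld_score") %in% names(tab)),
              "LD score file needs columns snp_id, ld_score")
  tibble::as_tibble(tab[, c("snp_id", "ld_score")])
}
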