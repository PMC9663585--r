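# Stratified Q-Q, fold-enrichment and Manhattan machinery. Everything is
# computed as a plot-ready tibble first; the ggplot2 layers are thin views
# over those tables and carry no logic of their own.

#' Stratified Q-Q table for the principal trait
#'
#' For each conditioning threshold t, restricts to SNPs whose
#' conditional-trait p-value is <= t and pairs the sorted observed
#' -log10 p of the principal trait with the expected null quantiles
#' -log10((rank - 0.5) / n_t). Pleiotropic enrichment shows as curves
#' leaving the null line earlier in stricter strata.
#'
#' @param paired A paired tibble with `p_A`, `p_B`.
#' @param principal `"A"` or `"B"`.
#' @param strata Conditioning thresholds, decreasing; 1 is the full set.
#' @return A tibble of class `pleio_qq` with columns `stratum`, `n_stratum`,
#'   `expected`, `observed` (both on the -log10 scale).
#' @export
stratified_qq <- function(paired, principal = c("A", "B"),
                          strata = c(1, 0.1, 0.01, 0.001)) {
  principal <- match.arg(principal)
  assert_that(nrow(paired) > 0, "empty paired table")
  p_i <- if (principal == "A") paired$p_A else paired$p_B
  p_j <- if (principal == "A") paired$p_B else paired$p_A
  strata <- sort(strata, decreasing = TRUE)
  out <- purrr::map_dfr(strata, function(t) {
    obs <- sort(p_i[p_j <= t])
    n_t <- length(obs)
    if (n_t == 0) return(NULL)
    tibble::tibble(
      stratum = t, n_stratum = n_t,
      expected = -log10((seq_len(n_t) - 0.5) / n_t),
      observed = -log10(clip_p(obs))
    )
  })
  dropped <- setdiff(strata, unique(out$stratum))
  if (length(dropped) > 0) {
    warning("empty strata dropped: ", paste(dropped, collapse = ", "))
  }
  class(out) <- c("pleio_qq", class(out))
  out
}

#' Fold-enrichment curves across conditioning strata
#'
#' On a grid of nominal -log10 p values, computes the ratio of the
#' stratum-restricted empirical tail CDF of the principal trait to the
#' full-set tail CDF. The full-set stratum is identically 1; upward shift
#' that grows in stricter strata indicates pleiotropic enrichment.
#'
#' @param paired A paired tibble with `p_A`, `p_B`.
#' @param principal `"A"` or `"B"`.
#' @param strata Conditioning thresholds (1 = full set).
#' @param grid Nominal -log10 p grid; defaults to an even grid over the
#'   range where the full-set tail CDF is positive.
#' @return A tibble of class `pleio_enrich` with columns `stratum`,
#'   `neg_log10_p`, `enrichment`.
#' @export
fold_enrichment <- function(paired, principal = c("A", "B"),
                            strata = c(1, 0.1, 0.01, 0.001), grid = NULL) {
  principal <- match.arg(principal)
  assert_that(nrow(paired) > 0, "empty paired table")
  p_i <- if (principal == "A") paired$p_A else paired$p_B
  p_j <- if (principal == "A") paired$p_B else paired$p_A
  if (is.null(grid)) {
    hi <- stats::quantile(-log10(clip_p(p_i)), 0.999)
    grid <- seq(0, hi, length.out = 50)
  }
  thr <- 10^(-grid)
  f_all <- vapply(thr, function(q) mean(p_i <= q), numeric(1))
  grid <- grid[f_all > 0]
  thr <- thr[f_all > 0]
  f_all <- f_all[f_all > 0]
  out <- purrr::map_dfr(sort(strata, decreasing = TRUE), function(t) {
    sub <- p_i[p_j <= t]
    if (length(sub) == 0) return(NULL)
    f_t <- vapply(thr, function(q) mean(sub <= q), numeric(1))
    tibble::tibble(stratum = t, neg_log10_p = grid, enrichment = f_t / f_all)
  })
  class(out) <- c("pleio_enrich", class(out))
  out
}

#' Plot-ready Manhattan table of conditional or conjunction FDR
#'
#' Converts a cFDR result into per-SNP (chromosome, position,
#' -log10 statistic) rows with a cumulative genome coordinate for plotting
#' and the -log10(0.05) = 1.3010 significance line attached as an
#' attribute.
#'
#' @param cfdr_result A tibble from [cfdr_table()] with `chrom` and `pos`.
#' @param mode `"conditional"` (plots `cfdr_A_given_B`) or `"conjunction"`
#'   (plots `ccfdr`).
#' @return A tibble of class `pleio_manhattan` with columns `snp_id`,
#'   `chrom`, `pos`, `genome_pos`, `neg_log10`, plus attribute `threshold`.
#' @export
manhattan_tables <- function(cfdr_result, mode = c("conditional", "conjunction")) {
  mode <- match.arg(mode)
  if (nrow(cfdr_result) == 0) {
    out <- tibble::tibble(snp_id = character(), chrom = character(),
                          pos = integer(), genome_pos = numeric(),
                          neg_log10 = numeric())
    class(out) <- c("pleio_manhattan", class(out))
    attr(out, "threshold") <- -log10(0.05)
    return(out)
  }
  assert_that(all(c("chrom", "pos") %in% names(cfdr_result)) &&
                !anyNA(cfdr_result$pos), "positions required for a Manhattan table")
  stat <- if (mode == "conditional") cfdr_result$cfdr_A_given_B else cfdr_result$ccfdr
  ord <- order(as.integer(cfdr_result$chrom), cfdr_result$pos)
  x <- cfdr_result[ord, ]
  stat <- stat[ord]
  offs <- tapply(x$pos, factor(as.integer(x$chrom)), max)
  offsets <- stats::setNames(c(0, cumsum(as.numeric(offs)))[seq_along(offs)],
                             names(offs))
  out <- tibble::tibble(
    snp_id = x$snp_id, chrom = x$chrom, pos = x$pos,
    genome_pos = x$pos + offsets[as.character(as.integer(x$chrom))],
    neg_log10 = -log10(clip_p(stat))
  )
  class(out) <- c("pleio_manhattan", class(out))
  attr(out, "threshold") <- -log10(0.05)
  attr(out, "mode") <- mode
  out
}

ROLE_LEVELS <- c("intronic", "ncRNA_intronic", "intergenic", "UTR3", "UTR5", "other")

#' Summarize an annotated pleiotropic-loci table
#'
#' Counts SNPs, distinct annotated genes (comma-separated gene lists are
#' split first) and distinct chromosomes, and tabulates functional-role
#' percentages (integer-rounded) with intronic and ncRNA-intronic pooled
#' as intronic and the two UTR classes pooled as UTR.
#'
#' @param rows A tibble with columns `chrom`, `gene`, `role` (one row per
#'   SNP). Unknown role labels are counted as "other" with a warning.
#' @return List with `n_snps`, `n_distinct_genes`, `n_distinct_chroms`,
#'   and `role_percent` (named integer vector over intronic / intergenic /
#'   UTR / other, zero-count classes omitted).
#' @export
summarize_pleiotropic_table <- function(rows) {
  assert_that(all(c("chrom", "gene", "role") %in% names(rows)),
              "need columns chrom, gene, role")
  role <- as.character(rows$role)
  unknown <- !(role %in% ROLE_LEVELS)
  if (any(unknown)) {
    warning("unknown role label(s) counted as 'other': ",
            paste(unique(role[unknown]), collapse = ", "))
    role[unknown] <- "other"
  }
  pooled <- dplyr::case_match(role,
    c("intronic", "ncRNA_intronic") ~ "intronic",
    c("UTR3", "UTR5") ~ "UTR",
    "intergenic" ~ "intergenic",
    .default = "other"
  )
  genes <- unlist(strsplit(as.character(rows$gene), ",[ ]*"))
  genes <- unique(trimws(genes[nzchar(genes)]))
  tab <- table(pooled)
  pct <- round(100 * as.numeric(tab) / nrow(rows))
  names(pct) <- names(tab)
  list(
    n_snps = nrow(rows),
    n_distinct_genes = length(genes),
    n_distinct_chroms = dplyr::n_distinct(normalize_chrom(rows$chrom)),
    role_percent = pct
  )
}

#' Load the packaged pleiotropic-loci worked example
#'
#' A machine-readable copy of the 13 pleiotropic SNPs reported by a
#' published cross-trait cFDR/GPA analysis of childhood body-mass index
#' and coronary artery disease, shipped as a plain-text fixture for the
#' worked examples and tests.
#'
#' @return A tibble with one row per SNP: `chrom`, `snp_id`, `allele`,
#'   `role`, `gene`, `p_A`, `p_B`, `cfdr_A_given_B`, `cfdr_B_given_A`,
#'   `ccfdr`, `fdr11`.
#' @export
pleiotropic_loci_example <- function() {
  path <- system.file("extdata", "pleiotropic_loci_cbmi_cad.tsv",
                      package = "pleioscan", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", col_types = "cccccdddddd",
                  progress = FALSE)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method
autoplot.pleio_qq <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$expected, y = .data$observed,
                                       colour = factor(.data$stratum))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  colour = "p(cond) <=") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.pleio_enrich <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$neg_log10_p, y = .data$enrichment,
                                       colour = factor(.data$stratum))) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Nominal ~ -log[10](p)), y = "Fold enrichment",
                  colour = "p(cond) <=") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.pleio_manhattan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$genome_pos, y = .data$neg_log10,
                                       colour = factor(as.integer(.data$chrom) %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"), colour = "red") +
    ggplot2::labs(x = "Genomic position", y = expression(-log[10](FDR))) +
    ggplot2::theme_minimal()
}
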