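# Programmatic fixtures; nothing is stored on disk beyond the packaged
# worked-example table.

options(pleioscan.verbose = FALSE)

# canonical well-formed 6-SNP table
sumstats_fixture <- function() {
  tibble::tibble(
    snp_id = paste0("rs", 1:6),
    chrom = c("1", "1", "2", "2", "3", "3"),
    pos = c(100L, 200L, 100L, 300L, 150L, 250L),
    a1 = c("A", "G", "C", "T", "A", "G"),
    a2 = c("G", "A", "T", "C", "C", "T"),
    beta = c(0.1, -0.2, 0.05, 0.3, -0.1, 0.02),
    se = c(0.05, 0.04, 0.02, 0.1, 0.03, 0.01),
    pvalue = c(0.045, 1e-6, 0.0124, 0.0027, 8e-4, 0.0455),
    n = 10000,
    info = c(0.99, 0.95, 0.97, 0.93, 0.91, 0.98),
    freq = c(0.3, 0.45, 0.12, 0.25, 0.08, 0.41)
  )
}

write_fixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "sumstats.tsv")
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# tiny panel with hand-controllable dosages
panel_fixture <- function(dosage, pos = 1000L * seq_len(ncol(dosage))) {
  genotype_panel(dosage, snp_id = paste0("snp", seq_len(ncol(dosage))), pos = pos)
}

# paired table aligned with a panel's SNPs (for pruning tests)
paired_for_panel <- function(panel, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    snp_id = panel$snp_id,
    chrom = panel$chrom,
    pos = panel$pos,
    p_A = stats::runif(length(panel$snp_id)),
    p_B = stats::runif(length(panel$snp_id)),
    maf = panel$maf
  ))
}

# correlated-dosage panel builder: draws latent MVN columns with a given
# correlation matrix, thresholds into dosages at frequency 0.5-ish
panel_from_corr <- function(n_ind, corr, seed) {
  withr::with_seed(seed, {
    ch <- chol(corr)
    z1 <- matrix(stats::rnorm(n_ind * ncol(corr)), n_ind) %*% ch
    z2 <- matrix(stats::rnorm(n_ind * ncol(corr)), n_ind) %*% ch
    panel_fixture((z1 < 0) + (z2 < 0))
  })
}
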