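test_that("a well-formed file reads back identically", {
  df <- sumstats_fixture()
  tab <- read_sumstats(write_fixture(df), trait_label = "toy")
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$snp_id, df$snp_id)
  # sorted by (chrom, pos)
  expect_equal(tab$snp_id, df$snp_id[order(as.integer(df$chrom), df$pos)])
  expect_equal(attr(tab, "trait_label"), "toy")
  expect_equal(attr(tab, "n_dropped"), 0)
  # values survive the round trip
  expect_equal(tab$pvalue[tab$snp_id == "rs2"], 1e-6)
})

test_that("rows failing range validation are dropped and counted", {
  df <- sumstats_fixture()
  df$pvalue[3] <- 0                       # p = 0 is invalid on input
  tab <- read_sumstats(write_fixture(df))
  expect_equal(nrow(tab), 5)
  expect_false("rs3" %in% tab$snp_id)
  expect_equal(attr(tab, "n_dropped"), 1)

  df2 <- sumstats_fixture()
  df2$se[1] <- -0.1
  df2$a2[2] <- df2$a1[2]                  # identical alleles
  tab2 <- read_sumstats(write_fixture(df2))
  expect_equal(attr(tab2, "n_dropped"), 2)
})

test_that("duplicated rsid is a hard error naming the rsid", {
  df <- sumstats_fixture()
  df$snp_id[4] <- "rs1"
  expect_error(read_sumstats(write_fixture(df)), "rs1")
})

test_that("missing required columns and unreadable files are hard errors", {
  df <- sumstats_fixture()
  df$pvalue <- NULL
  expect_error(read_sumstats(write_fixture(df)), "pvalue")
  expect_error(read_sumstats(file.path(tempdir(), "no-such-file.tsv")), "not found")
})

test_that("column_map renames arbitrary headers onto the schema", {
  df <- sumstats_fixture()
  names(df) <- c("RSID", "CHR", "BP", "EA", "OA", "B", "SE", "P", "N", "INFO", "EAF")
  tab <- read_sumstats(
    write_fixture(df),
    column_map = c(snp_id = "RSID", chrom = "CHR", pos = "BP", a1 = "EA",
                   a2 = "OA", beta = "B", se = "SE", pvalue = "P", n = "N",
                   info = "INFO", freq = "EAF")
  )
  expect_equal(nrow(tab), 6)
  expect_error(read_sumstats(write_fixture(df), column_map = c(snp_id = "nope")),
               "nope")
})

test_that("qc_filter applies strict INFO and MAF thresholds", {
  base <- sumstats_fixture()[1, ]
  mk <- function(info, freq) {
    x <- base; x$info <- info; x$freq <- freq; x
  }
  expect_equal(nrow(qc_filter(mk(0.95, 0.30))), 1)   # both pass
  expect_equal(nrow(qc_filter(mk(0.90, 0.30))), 0)   # INFO boundary is strict
  expect_equal(nrow(qc_filter(mk(0.95, 0.01))), 0)   # MAF boundary is strict
  expect_equal(nrow(qc_filter(mk(0.95, 0.995))), 0)  # MAF folds: 1-0.995 = 0.005
  expect_equal(nrow(qc_filter(mk(NA, 0.30))), 0)     # missing INFO fails QC
  expect_equal(nrow(qc_filter(mk(0.95, NA))), 0)     # missing freq fails QC
})

test_that("qc_filter matches a brute-force row filter and is idempotent", {
  withr::with_seed(42, {
    n <- 40
    tab <- tibble::tibble(
      snp_id = paste0("rs", 1:n), chrom = "1", pos = 1:n * 10L,
      a1 = "A", a2 = "G", beta = 0, se = 1,
      pvalue = runif(n), n = 1000,
      info = round(runif(n, 0.85, 1), 3),
      freq = round(runif(n, 0.001, 0.999), 3)
    )
  })
  out <- qc_filter(tab)
  keep <- vapply(seq_len(nrow(tab)), function(i) {
    maf <- min(tab$freq[i], 1 - tab$freq[i])
    tab$info[i] > 0.9 && maf > 0.01
  }, logical(1))
  expect_equal(out$snp_id, tab$snp_id[keep])
  expect_equal(qc_filter(out)$snp_id, out$snp_id)
})

test_that("allele swaps flip the second trait's z-score sign", {
  a <- sumstats_fixture()[1, ]                        # rs1 A/G, beta .1, se .05
  b <- a
  b$a1 <- "G"; b$a2 <- "A"; b$beta <- 0.08            # swapped coding, z = +1.6
  merged <- harmonize_and_merge(a, b)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$z_B, -0.08 / 0.05)
  # strand flip without swap leaves the sign alone
  b2 <- a; b2$a1 <- "T"; b2$a2 <- "C"                 # complement of A/G
  expect_equal(harmonize_and_merge(a, b2)$z_B, a$beta / a$se)
  # strand flip plus swap flips
  b3 <- a; b3$a1 <- "C"; b3$a2 <- "T"
  expect_equal(harmonize_and_merge(a, b3)$z_B, -a$beta / a$se)
})

test_that("palindromic and irreconcilable SNPs are dropped at merge", {
  a <- sumstats_fixture()
  a$a1[1] <- "A"; a$a2[1] <- "T"                      # palindromic
  b <- a
  b$a1[2] <- "A"; b$a2[2] <- "C"                      # irreconcilable with G/A
  merged <- harmonize_and_merge(a, b)
  expect_false(any(c("rs1", "rs2") %in% merged$snp_id))
  expect_equal(nrow(merged), 4)
  cnt <- attr(merged, "harmonize_counts")
  expect_equal(unname(cnt["dropped_ambiguous"]), 1)
  expect_equal(unname(cnt["dropped_irreconcilable"]), 1)
})

test_that("merge equals a hand-built join on the shared ids", {
  a <- sumstats_fixture()
  extra <- sumstats_fixture()[1:4, ]
  extra$snp_id <- paste0("rsB", 1:4)
  b <- dplyr::bind_rows(sumstats_fixture()[1:3, ], extra)   # 3 shared of 7
  merged <- harmonize_and_merge(a, b)
  expect_setequal(merged$snp_id, c("rs1", "rs2", "rs3"))
  hand <- merge(as.data.frame(a), as.data.frame(b), by = "snp_id")
  expect_equal(merged$p_A[order(merged$snp_id)],
               hand$pvalue.x[order(hand$snp_id)])
  expect_error(harmonize_and_merge(a, extra), "overlap")
})

test_that("merge is symmetric and self-merge pairs each p with itself", {
  a <- sumstats_fixture()
  b <- sumstats_fixture()[3:6, ]
  ab <- harmonize_and_merge(a, b)
  ba <- harmonize_and_merge(b, a)
  expect_setequal(ab$snp_id, ba$snp_id)
  expect_equal(ab$p_A, ba$p_B[match(ab$snp_id, ba$snp_id)])
  expect_equal(ab$p_B, ba$p_A[match(ab$snp_id, ba$snp_id)])
  self <- harmonize_and_merge(a, a)
  expect_equal(self$p_A, self$p_B)
  expect_equal(nrow(self), 6)            # fixture has no palindromic SNPs
})

test_that("paired tables round-trip through the writer", {
  merged <- harmonize_and_merge(sumstats_fixture(), sumstats_fixture())
  path <- file.path(withr::local_tempdir(), "paired.tsv")
  write_paired(merged, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("snp_id", "chrom", "pos", "p_A", "p_B",
                              "z_A", "z_B", "maf"))
  expect_equal(back$p_A, merged$p_A)
})
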