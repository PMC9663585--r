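#' Read GWAS summary statistics from a delimited file
#'
#' Reads a whitespace- or tab-delimited per-SNP association table (gzip
#' transparent), renames columns to the canonical schema via `column_map`,
#' validates every row, and returns a tibble sorted by chromosome and
#' position. Rows failing type or range validation (p-value outside (0, 1],
#' non-positive standard error, identical or non-ACGT alleles, unparseable
#' chromosome) are dropped and counted; a duplicated rsid is a hard error
#' because rsid is the merge key for all downstream analysis.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field names
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `pvalue`, and optionally `beta`,
#'   `se`, `n`, `info`, `freq`) to the column names in the file. Fields
#'   already named canonically need not be listed.
#' @param trait_label Short label for the trait (stored as an attribute and
#'   carried into merged output).
#'
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `beta`, `se`, `pvalue`, `n`, `info`, `freq` (missing optional columns
#'   are `NA`), one row per retained SNP, with attributes `trait_label`,
#'   `provenance` and `n_dropped`.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = "trait") {
  assert_that(file.exists(path), paste0("summary-statistics file not found: ", path))
  raw <- tryCatch(
    readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE),
    error = function(e) stop("unparseable summary-statistics file: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    assert_that(length(missing_src) == 0,
                paste0("column_map names columns absent from file: ",
                       paste(missing_src, collapse = ", ")))
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  required <- c("snp_id", "chrom", "pos", "a1", "a2", "pvalue")
  missing_req <- setdiff(required, names(raw))
  assert_that(length(missing_req) == 0,
              paste0("missing required column(s): ", paste(missing_req, collapse = ", ")))
  optional <- c("beta", "se", "n", "info", "freq")
  for (col in setdiff(optional, names(raw))) raw[[col]] <- NA_character_

  tab <- tibble::tibble(
    snp_id = raw$snp_id,
    chrom  = normalize_chrom(raw$chrom),
    pos    = suppressWarnings(as.integer(raw$pos)),
    a1     = toupper(trimws(raw$a1)),
    a2     = toupper(trimws(raw$a2)),
    beta   = suppressWarnings(as.numeric(raw$beta)),
    se     = suppressWarnings(as.numeric(raw$se)),
    pvalue = suppressWarnings(as.numeric(raw$pvalue)),
    n      = suppressWarnings(as.numeric(raw$n)),
    info   = suppressWarnings(as.numeric(raw$info)),
    freq   = suppressWarnings(as.numeric(raw$freq))
  )

  ok <- !is.na(tab$snp_id) & nzchar(tab$snp_id) &
    !is.na(tab$chrom) &
    !is.na(tab$pos) & tab$pos >= 1L &
    tab$a1 %in% c("A", "C", "G", "T") &
    tab$a2 %in% c("A", "C", "G", "T") &
    tab$a1 != tab$a2 &
    !is.na(tab$pvalue) & tab$pvalue > 0 & tab$pvalue <= 1 &
    (is.na(tab$se) | tab$se > 0) &
    (is.na(tab$info) | (tab$info >= 0 & tab$info <= 1)) &
    (is.na(tab$freq) | (tab$freq > 0 & tab$freq < 1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    ps_log(trait_label, ": dropped ", n_dropped, " row(s) failing validation")
  }
  tab <- tab[ok, , drop = FALSE]

  dup <- tab$snp_id[duplicated(tab$snp_id)]
  assert_that(length(dup) == 0,
              paste0("duplicated rsid(s) in ", trait_label, ": ",
                     paste(unique(dup), collapse = ", ")))

  tab <- dplyr::arrange(tab, as.integer(.data$chrom), .data$pos)
  attr(tab, "trait_label") <- trait_label
  attr(tab, "provenance") <- paste0("read_sumstats(", path, ")")
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Apply imputation-quality and allele-frequency QC filters
#'
#' Retains exactly the SNPs with imputation INFO strictly greater than
#' `info_min` and minor allele frequency strictly greater than `maf_min`
#' (MAF is `min(freq, 1 - freq)`). Records with missing INFO or frequency
#' fail QC: the filters cannot be evaluated for them, and keeping them would
#' silently admit unfilterable SNPs.
#'
#' @param table A summary-statistics tibble from [read_sumstats()].
#' @param info_min Minimum imputation quality, exclusive. Default 0.9.
#' @param maf_min Minimum minor allele frequency, exclusive. Default 0.01.
#' @return The filtered tibble (attributes preserved; attribute `qc_counts`
#'   records kept/dropped counts per rule).
#' @export
qc_filter <- function(table, info_min = 0.9, maf_min = 0.01) {
  assert_that(info_min > 0 && info_min < 1, "info_min must be in (0,1)")
  assert_that(maf_min > 0 && maf_min < 1, "maf_min must be in (0,1)")
  maf <- pmin(table$freq, 1 - table$freq)
  pass_info <- !is.na(table$info) & table$info > info_min
  pass_maf <- !is.na(maf) & maf > maf_min
  keep <- pass_info & pass_maf
  counts <- c(kept = sum(keep), dropped_info = sum(!pass_info),
              dropped_maf = sum(!pass_maf))
  ps_log("QC: kept ", counts[["kept"]], "/", nrow(table),
         " (", counts[["dropped_info"]], " fail INFO, ",
         counts[["dropped_maf"]], " fail MAF)")
  out <- table[keep, , drop = FALSE]
  for (a in c("trait_label", "provenance")) attr(out, a) <- attr(table, a)
  attr(out, "qc_counts") <- counts
  out
}

# strand complement for single-nucleotide alleles
allele_complement <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_palindromic <- function(a1, a2) {
  a2 == allele_complement(a1)
}

#' Harmonize alleles and merge two traits into a paired p-value table
#'
#' Inner-joins two QC'd summary-statistics tables on rsid and reconciles
#' allele coding so both traits' effects refer to the same allele: a plain
#' allele swap flips the sign of the second trait's z-score; a strand flip
#' (complementary alleles) is resolved by complementing before comparison.
#' Strand-ambiguous palindromic SNPs (A/T, C/G) and SNPs whose alleles
#' cannot be reconciled are dropped and counted.
#'
#' @param a,b Summary-statistics tibbles (trait A and trait B).
#' @return A paired tibble sorted by (chrom, pos) with columns `snp_id`,
#'   `chrom`, `pos`, `p_A`, `p_B`, `z_A`, `z_B`, `maf` (reference MAF taken
#'   from trait A's frequency where present, else trait B's). Attribute
#'   `harmonize_counts` records merged/dropped tallies; attributes
#'   `trait_A`/`trait_B` carry the input labels.
#' @export
harmonize_and_merge <- function(a, b) {
  shared <- intersect(a$snp_id, b$snp_id)
  assert_that(length(shared) > 0, "no overlapping SNPs between the two tables")
  ai <- a[match(shared, a$snp_id), ]
  bi <- b[match(shared, b$snp_id), ]

  pal <- is_palindromic(ai$a1, ai$a2) | is_palindromic(bi$a1, bi$a2)

  same <- bi$a1 == ai$a1 & bi$a2 == ai$a2
  swap <- bi$a1 == ai$a2 & bi$a2 == ai$a1
  b1c <- allele_complement(bi$a1)
  b2c <- allele_complement(bi$a2)
  flip_same <- b1c == ai$a1 & b2c == ai$a2
  flip_swap <- b1c == ai$a2 & b2c == ai$a1

  reconcilable <- !pal & (same | swap | flip_same | flip_swap)
  sign_flip <- ifelse(swap | flip_swap, -1, 1)

  n_pal <- sum(pal)
  n_bad <- sum(!pal & !reconcilable)
  if (n_pal + n_bad > 0) {
    ps_log("merge: dropped ", n_pal, " strand-ambiguous and ", n_bad,
           " irreconcilable SNP(s)")
  }

  keep <- which(reconcilable)
  z_a <- ai$beta / ai$se
  z_b <- (bi$beta / bi$se) * sign_flip
  maf_a <- pmin(ai$freq, 1 - ai$freq)
  maf_b <- pmin(bi$freq, 1 - bi$freq)

  out <- tibble::tibble(
    snp_id = ai$snp_id[keep],
    chrom  = ai$chrom[keep],
    pos    = ai$pos[keep],
    p_A    = ai$pvalue[keep],
    p_B    = bi$pvalue[keep],
    z_A    = z_a[keep],
    z_B    = z_b[keep],
    maf    = dplyr::coalesce(maf_a, maf_b)[keep]
  )
  out <- dplyr::arrange(out, as.integer(.data$chrom), .data$pos)
  attr(out, "trait_A") <- attr(a, "trait_label") %||% "A"
  attr(out, "trait_B") <- attr(b, "trait_label") %||% "B"
  attr(out, "harmonize_counts") <- c(
    shared = length(shared), merged = length(keep),
    dropped_ambiguous = n_pal, dropped_irreconcilable = n_bad
  )
  out
}

#' Write a paired two-trait table to tab-delimited text
#'
#' Fixed column order: snp_id, chrom, pos, p_A, p_B, z_A, z_B, maf.
#'
#' @param paired A paired tibble from [harmonize_and_merge()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paired <- function(paired, path) {
  cols <- c("snp_id", "chrom", "pos", "p_A", "p_B", "z_A", "z_B", "maf")
  readr::write_tsv(paired[, intersect(cols, names(paired))], path, progress = FALSE)
  invisible(path)
}

#' Write a summary-statistics table in the format [read_sumstats()] reads
#'
#' @param table A summary-statistics tibble.
#' @param path Output file path (tab-delimited, header row).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  cols <- c("snp_id", "chrom", "pos", "a1", "a2", "beta", "se", "pvalue",
            "n", "info", "freq")
  readr::write_tsv(table[, intersect(cols, names(table))], path, progress = FALSE)
  invisible(path)
}
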