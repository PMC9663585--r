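# internal helpers shared across modules

# Floor for p-values ahead of any log transform; far below any GWAS-meaningful p.
P_FLOOR <- 1e-300

# Clip p-values away from 0 (and above 1 from rounding) before log transforms.
clip_p <- function(p, floor = P_FLOOR) {
  pmin(pmax(p, floor), 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Normalize chromosome labels to "1".."22"; anything else (X, Y, MT, malformed)
# comes back NA so callers can drop it. Accepts "chr1", "01", 1L, etc.
normalize_chrom <- function(chrom) {
  x <- tolower(trimws(as.character(chrom)))
  x <- sub("^chr", "", x)
  n <- suppressWarnings(as.integer(x))
  n[!is.na(n) & (n < 1L | n > 22L)] <- NA_integer_
  as.character(n)
}

# message-level logging with a common prefix, quiet by default in tests
ps_log <- function(..., verbose = getOption("pleioscan.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[pleioscan] ", ...)
  invisible(NULL)
}
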