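# End-to-end orchestration: QC -> harmonize/merge -> LD prune -> LDSC ->
# enrichment diagnostics -> cFDR -> GPA -> combined call sets.

#' Build a validated pipeline configuration
#'
#' All thresholds default to the conventional values used throughout the
#' package: strict INFO > 0.9 and MAF > 0.01 QC, pruning at r2 > 0.2,
#' cFDR/ccFDR calls at 0.05, GPA local-fdr calls at 0.2. The configuration
#' round-trips through YAML unchanged via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param sumstats_a,sumstats_b Paths to the two traits' summary-statistics
#'   files (ignored when `simulate` is set).
#' @param column_map_a,column_map_b Optional column maps for [read_sumstats()].
#' @param info_min,maf_min QC thresholds (defaults 0.9, 0.01).
#' @param r2_max,prune_window,prune_step LD pruning parameters.
#' @param cfdr_max,ccfdr_max cFDR / conjunction thresholds (default 0.05).
#' @param gpa_fdr_max GPA local-fdr threshold (default 0.2).
#' @param strata Conditioning strata for the Q-Q / enrichment diagnostics.
#' @param combine How cFDR and GPA call sets are combined: `"intersection"`
#'   (default) or `"union"`.
#' @param seed Integer seed for any simulated stage.
#' @param simulate Optional list of arguments for [simulate_fourgroup()]
#'   (fields `n`, `pi`, `alpha`); when present the pipeline starts from
#'   generated paired p-values instead of files.
#' @param output_dir Optional directory; when set, result tables are
#'   written there as tab-delimited text with a provenance header.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sumstats_a = NULL, sumstats_b = NULL,
                            column_map_a = NULL, column_map_b = NULL,
                            info_min = 0.9, maf_min = 0.01,
                            r2_max = 0.2, prune_window = 50, prune_step = 5,
                            cfdr_max = 0.05, ccfdr_max = 0.05,
                            gpa_fdr_max = 0.2,
                            strata = c(1, 0.1, 0.01, 0.001),
                            combine = c("intersection", "union"),
                            seed = 1L, simulate = NULL, output_dir = NULL) {
  combine <- match.arg(combine)
  for (v in c(info_min, maf_min, cfdr_max, ccfdr_max, gpa_fdr_max)) {
    assert_that(v > 0 && v < 1, "thresholds must lie in (0,1)")
  }
  assert_that(r2_max >= 0 && r2_max <= 1, "r2_max must lie in [0,1]")
  structure(
    list(sumstats_a = sumstats_a, sumstats_b = sumstats_b,
         column_map_a = column_map_a, column_map_b = column_map_b,
         info_min = info_min, maf_min = maf_min,
         r2_max = r2_max, prune_window = prune_window, prune_step = prune_step,
         cfdr_max = cfdr_max, ccfdr_max = ccfdr_max, gpa_fdr_max = gpa_fdr_max,
         strata = strata, combine = combine, seed = as.integer(seed),
         simulate = simulate, output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_stage <- function(tab, dir, name, seed) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(name, ".tsv"))
  header <- paste0("# pleioscan ", utils::packageVersion("pleioscan"),
                   " | stage: ", name, " | seed: ", seed)
  writeLines(header, path)
  suppressWarnings(readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                                    progress = FALSE))
  invisible(path)
}

#' Run the full cross-trait pleiotropy pipeline
#'
#' Sequences QC, allele harmonization and merging, LD pruning (when a
#' reference panel is supplied), LD score regression (when LD scores are
#' available), stratified Q-Q / fold-enrichment diagnostics, cFDR/ccFDR,
#' the four-group GPA fit with its pleiotropy LRT, and the combined call
#' sets (cFDR AND GPA by default). Deterministic given the config and its
#' seed. Any stage failure aborts with an error naming the stage; results
#' computed so far are retained in `output_dir` when one was given.
#'
#' @param config A [pipeline_config()].
#' @param panel Optional [genotype_panel()] for pruning and LD scores.
#' @param ld Optional precomputed LD-score tibble (overrides `panel` for
#'   the regression stage).
#' @return List with `paired`, `pruned`, `ldsc` (possibly NULL), `cfdr`,
#'   `gpa`, `lrt`, `gpa_fdr`, `qq`, `enrichment`, `calls` (list with
#'   `trait_A`, `trait_B`, `pleiotropic`), and `log` (character vector of
#'   stage messages).
#' @export
run_pipeline <- function(config, panel = NULL, ld = NULL) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  log <- character(0)
  note <- function(...) {
    log <<- c(log, paste0(...))
    ps_log(...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  paired <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- simulate_fourgroup(
        n = config$simulate$n %||% 10000L,
        pi = config$simulate$pi %||% fourgroup_defaults()$pi,
        alpha = config$simulate$alpha %||% fourgroup_defaults()$alpha,
        seed = config$seed
      )
      note("input: simulated ", nrow(sim$paired), " paired p-values")
      sim$paired
    } else {
      a <- read_sumstats(config$sumstats_a, config$column_map_a, "trait_A")
      b <- read_sumstats(config$sumstats_b, config$column_map_b, "trait_B")
      a <- qc_filter(a, config$info_min, config$maf_min)
      b <- qc_filter(b, config$info_min, config$maf_min)
      merged <- harmonize_and_merge(a, b)
      note("input: ", nrow(merged), " harmonized SNPs after QC and merge")
      merged
    }
  })
  write_stage(paired, config$output_dir, "paired", config$seed)

  pruned <- stage("prune", {
    if (is.null(panel)) {
      note("prune: no panel supplied, skipping")
      paired
    } else {
      pr <- ld_prune(paired, panel, r2_max = config$r2_max,
                     window = config$prune_window, step = config$prune_step)
      note("prune: ", nrow(pr), "/", nrow(paired), " SNPs retained at r2 <= ",
           config$r2_max)
      pr
    }
  })
  write_stage(pruned, config$output_dir, "pruned", config$seed)

  ldsc_fit <- stage("ldsc", {
    have_z <- all(c("z_A", "z_B") %in% names(pruned)) &&
      !all(is.na(pruned$z_A)) && !all(is.na(pruned$z_B))
    scores <- if (!is.null(ld)) ld else if (!is.null(panel)) ld_scores(panel) else NULL
    if (!have_z || is.null(scores)) {
      note("ldsc: z-scores or LD scores unavailable, skipping")
      NULL
    } else {
      ell <- scores$ld_score[match(pruned$snp_id, scores$snp_id)]
      ok <- !is.na(ell)
      n_a <- attr(pruned, "n_A") %||% 10000
      n_b <- attr(pruned, "n_B") %||% 10000
      h2a <- fit_h2(pruned$z_A[ok], ell[ok], n = n_a)
      h2b <- fit_h2(pruned$z_B[ok], ell[ok], n = n_b)
      rg <- fit_rg(pruned$z_A[ok], pruned$z_B[ok], ell[ok], n1 = n_a, n2 = n_b,
                   h2_1 = h2a$h2, h2_2 = h2b$h2)
      note("ldsc: h2_A = ", signif(h2a$h2, 3), ", h2_B = ", signif(h2b$h2, 3),
           ", rg = ", signif(rg$rg, 3))
      list(h2_A = h2a, h2_B = h2b, rg = rg)
    }
  })

  qq <- stage("enrich", stratified_qq(pruned, "A", config$strata))
  enrich <- stage("enrich", fold_enrichment(pruned, "A", config$strata))

  cfdr_res <- stage("cfdr", cfdr_table(pruned, config$cfdr_max, config$ccfdr_max))
  write_stage(cfdr_res, config$output_dir, "cfdr", config$seed)

  gpa_fit <- stage("gpa", fit_gpa(pruned))
  gpa_fit <- stage("gpa", pi_standard_errors(gpa_fit))
  lrt <- stage("gpa", lrt_pleiotropy(pruned, gpa_fit))
  fdr <- stage("gpa", local_fdr(gpa_fit))
  note("gpa: LRT = ", signif(lrt$lrt_stat, 5), ", p = ",
       format(lrt$pvalue, digits = 3))
  write_stage(fdr, config$output_dir, "gpa_fdr", config$seed)

  calls <- stage("calls", {
    ids <- cfdr_res$snp_id
    set_a_cfdr <- ids[cfdr_res$cfdr_A_given_B < config$cfdr_max]
    set_b_cfdr <- ids[cfdr_res$cfdr_B_given_A < config$cfdr_max]
    set_p_cfdr <- ids[cfdr_res$ccfdr < config$ccfdr_max]
    set_a_gpa <- ids[fdr$fdr_A < config$gpa_fdr_max]
    set_b_gpa <- ids[fdr$fdr_B < config$gpa_fdr_max]
    set_p_gpa <- ids[fdr$fdr11 < config$gpa_fdr_max]
    comb <- if (config$combine == "intersection") intersect else union
    list(trait_A = comb(set_a_cfdr, set_a_gpa),
         trait_B = comb(set_b_cfdr, set_b_gpa),
         pleiotropic = comb(set_p_cfdr, set_p_gpa),
         cfdr_only = list(A = set_a_cfdr, B = set_b_cfdr, pleio = set_p_cfdr),
         gpa_only = list(A = set_a_gpa, B = set_b_gpa, pleio = set_p_gpa))
  })
  note("calls: ", length(calls$trait_A), " trait-A, ", length(calls$trait_B),
       " trait-B, ", length(calls$pleiotropic), " pleiotropic (",
       config$combine, ")")

  list(paired = paired, pruned = pruned, ldsc = ldsc_fit, cfdr = cfdr_res,
       gpa = gpa_fit, lrt = lrt, gpa_fdr = fdr, qq = qq, enrichment = enrich,
       calls = calls, log = log)
}
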