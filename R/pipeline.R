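# Three-stage orchestration: (1) exposure screen with five MR estimators,
# sensitivity cascade and SMR/HEIDI validation; (2) upstream mediation
# (methylation -> gene -> outcome); (3) downstream mediation (gene ->
# immune trait -> outcome). Plus JSON configuration, CLI, and a
# reproducibility manifest.

default_config <- function() {
  list(p_threshold = 5e-8, maf_min = 0.01, clump_r2 = 0.001, clump_kb = 10000,
       f_min = 20, palindrome_window = 0.08, alpha = 0.05, n_boot = 1000,
       n_sim = 1000, n_mc = 1e5, seed = 1, strict_sensitivity = FALSE,
       bh_correction = FALSE)
}

merge_config <- function(config) {
  cfg <- default_config()
  if (!is.null(config)) cfg[names(config)] <- config
  cfg
}

#' Stage 1: screen exposures against the outcome
#'
#' For each exposure dataset: instrument selection, harmonization, the five
#' MR estimators, and the sensitivity cascade. The verdict is `significant`
#' only when the headline IVW p-value is below `alpha` AND the IVW and
#' MR-Egger estimates agree in sign (vacuously true when fewer than 3
#' instruments make Egger unavailable). Heterogeneity (Q) and Egger
#' intercept findings warn rather than reject by default; set
#' `strict_sensitivity = TRUE` in the config to gate on them
#' (`rejected_sensitivity`).
#'
#' @param exposures list of exposure [summary_dataset()] objects.
#' @param outcome outcome [summary_dataset()].
#' @param ld optional [ld_matrix()].
#' @param config named list of overrides, see `default_config` internals
#'   (`p_threshold`, `maf_min`, `clump_r2`, `clump_kb`, `f_min`, `alpha`,
#'   `n_boot`, `n_sim`, `seed`, `strict_sensitivity`).
#' @return list of per-exposure `stage_decision` lists: `unit_id`,
#'   `mr_results`, `sensitivity`, `flags`, `verdict` in `significant`,
#'   `rejected_pvalue`, `rejected_direction`, `rejected_sensitivity`, or
#'   `no_instruments`.
#' @export
stage1_screen <- function(exposures, outcome, ld = NULL, config = NULL) {
  stopifnot(length(exposures) >= 1, inherits(outcome, "summary_dataset"))
  cfg <- merge_config(config)
  lapply(exposures, function(exp_ds) {
    dat <- tryCatch(
      build_instruments(exp_ds, outcome, ld, p_threshold = cfg$p_threshold,
                        maf_min = cfg$maf_min, r2_threshold = cfg$clump_r2,
                        window_kb = cfg$clump_kb, f_min = cfg$f_min,
                        palindrome_window = cfg$palindrome_window),
      error = function(e) data.frame())
    if (!nrow(dat))
      return(list(unit_id = exp_ds$trait_id, mr_results = NULL,
                  sensitivity = NULL, flags = character(0),
                  verdict = "no_instruments"))
    res <- mr_all(dat, n_boot = cfg$n_boot, seed = cfg$seed)
    sens <- if (nrow(dat) >= 2)
      sensitivity_report(dat, n_sim = cfg$n_sim, seed = cfg$seed) else NULL
    ivw <- res[res$method %in% c("ivw_mre", "wald_ratio"), ][1, ]
    egger <- if ("egger" %in% res$method) res[res$method == "egger", ][1, ] else NULL

    flags <- character(0)
    if (!is.null(sens)) {
      if (sens$q$q_pval < cfg$alpha) flags <- c(flags, "heterogeneity")
      if (!is.null(sens$egger_intercept) &&
          sens$egger_intercept$pval < cfg$alpha) flags <- c(flags, "pleiotropy")
    }
    verdict <- if (!(ivw$pval < cfg$alpha)) "rejected_pvalue"
    else if (!is.null(egger) && sign(ivw$beta) != sign(egger$beta)) "rejected_direction"
    else if (cfg$strict_sensitivity && length(flags)) "rejected_sensitivity"
    else "significant"
    list(unit_id = exp_ds$trait_id, mr_results = res, sensitivity = sens,
         instruments = dat, flags = flags, verdict = verdict)
  })
}

#' Stage 1b: SMR + HEIDI validation of screen candidates
#'
#' For each candidate surviving [stage1_screen()], runs [smr_heidi()] on its
#' QTL region against the outcome GWAS region. The verdict stays
#' `significant` only when `p_smr < alpha` and `p_heidi > alpha`; otherwise
#' it becomes `rejected_smr`, `rejected_heidi`, or records
#' `heidi_unavailable`.
#'
#' @param decisions output of [stage1_screen()].
#' @param qtl_regions named list (by `unit_id`) of QTL-region
#'   [summary_dataset()]s.
#' @param gwas_region outcome GWAS [summary_dataset()] over the same regions.
#' @param ld [ld_matrix()] for the regions.
#' @param config overrides (`alpha`, `n_mc`, `seed`, HEIDI thresholds
#'   `heidi_r2_min`, `heidi_r2_max`, `heidi_max_snps`, `heidi_min_snps`).
#' @return `decisions` with `smr` results attached and verdicts updated.
#' @export
stage1_validate_smr <- function(decisions, qtl_regions, gwas_region, ld,
                                config = NULL) {
  cfg <- merge_config(config)
  lapply(decisions, function(dec) {
    if (!identical(dec$verdict, "significant")) return(dec)
    reg <- qtl_regions[[dec$unit_id]]
    if (is.null(reg)) stop("stage1_validate_smr: missing region for ", dec$unit_id)
    smr <- smr_heidi(reg, gwas_region, ld, alpha = cfg$alpha,
                     r2_min = cfg$heidi_r2_min %||% 0.05,
                     r2_max = cfg$heidi_r2_max %||% 0.9,
                     max_snps = cfg$heidi_max_snps %||% 20,
                     min_snps = cfg$heidi_min_snps %||% 3,
                     n_mc = cfg$n_mc, seed = cfg$seed)
    dec$smr <- smr
    dec$verdict <- switch(smr$verdict,
                          pass = "significant",
                          fail_smr = "rejected_smr",
                          fail_heidi = "rejected_heidi",
                          heidi_unavailable = "heidi_unavailable")
    dec
  })
}

#' Stage 2: upstream mediation screen (methylation -> gene -> outcome)
#'
#' Runs [two_step_mediation()] with each methylation dataset as the exposure
#' and the stage-1 gene as the mediator. Only directionally consistent
#' results whose three legs are individually significant are reported.
#'
#' @param methylation_ds_list list of CpG exposure [summary_dataset()]s.
#' @param gene_ds the selected gene's [summary_dataset()].
#' @param outcome_ds outcome [summary_dataset()].
#' @param ld optional [ld_matrix()].
#' @param config overrides as in [two_step_mediation()].
#' @return list with `results` (all `mediation_result`s) and `table`
#'   (reported rows only, see [mediation_table()]).
#' @export
stage2_upstream <- function(methylation_ds_list, gene_ds, outcome_ds, ld = NULL,
                            config = NULL) {
  results <- lapply(methylation_ds_list, function(cpg)
    tryCatch(two_step_mediation(cpg, gene_ds, outcome_ds, ld, config),
             error = function(e) NULL))
  results <- Filter(Negate(is.null), results)
  list(results = results, table = mediation_table(results))
}

#' Stage 3: downstream mediation screen (gene -> immune trait -> outcome)
#'
#' Mirror of [stage2_upstream()] with the gene as the exposure and each
#' immune trait as the mediator.
#'
#' @param gene_ds the selected gene's [summary_dataset()].
#' @param immune_ds_list list of immune-trait [summary_dataset()]s.
#' @param outcome_ds,ld,config as in [stage2_upstream()].
#' @return list with `results` and `table`.
#' @export
stage3_downstream <- function(gene_ds, immune_ds_list, outcome_ds, ld = NULL,
                              config = NULL) {
  results <- lapply(immune_ds_list, function(imm)
    tryCatch(two_step_mediation(gene_ds, imm, outcome_ds, ld, config),
             error = function(e) NULL))
  results <- Filter(Negate(is.null), results)
  list(results = results, table = mediation_table(results))
}

stage1_table <- function(decisions) {
  rows <- lapply(decisions, function(dec) {
    if (is.null(dec$mr_results))
      return(data.frame(unit_id = dec$unit_id, method = NA, nsnp = 0,
                        beta = NA, se = NA, ci_low = NA, ci_high = NA,
                        pval = NA, odds_ratio = NA, or_ci_low = NA,
                        or_ci_high = NA, verdict = dec$verdict,
                        stringsAsFactors = FALSE))
    cbind(unit_id = dec$unit_id, dec$mr_results, verdict = dec$verdict,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

sensitivity_table <- function(decisions) {
  rows <- lapply(decisions, function(dec) {
    s <- dec$sensitivity
    if (is.null(s)) return(NULL)
    data.frame(
      unit_id = dec$unit_id, q_stat = s$q$q_stat, q_df = s$q$q_df,
      q_pval = s$q$q_pval,
      egger_intercept = if (!is.null(s$egger_intercept)) s$egger_intercept$estimate else NA,
      egger_intercept_pval = if (!is.null(s$egger_intercept)) s$egger_intercept$pval else NA,
      presso_global_pval = if (!is.null(s$presso)) s$presso$global_pval else NA,
      presso_outliers = if (!is.null(s$presso))
        paste(s$presso$outliers, collapse = ",") else "",
      flags = paste(dec$flags, collapse = ","), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

smr_table <- function(decisions) {
  rows <- lapply(decisions, function(dec) {
    s <- dec$smr
    if (is.null(s)) return(NULL)
    data.frame(unit_id = dec$unit_id, top_rsid = s$top_rsid, b_xy = s$b_xy,
               se_xy = s$se_xy, p_smr = s$p_smr, p_heidi = s$p_heidi,
               n_heidi_snps = s$n_heidi_snps, verdict = s$verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_tsv <- function(tab, path) {
  if (is.null(tab)) tab <- data.frame()
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Run the full three-stage pipeline from a configuration file
#'
#' The configuration is JSON. A `simulate` block makes the run fully
#' self-contained: `study` fields are [sim_config()] arguments (two studies
#' are derived, one for the upstream chain and one for the downstream
#' chain), `smr_region` fields are [simulate_smr_region()] arguments.
#' Without `simulate`, an `inputs` block names summary-statistics files
#' (`exposures`, `outcome`, optional `ld`, `qtl_regions`) read with
#' [read_sumstats()]. `stages` selects a subset of
#' `c("mr", "smr", "mediate_upstream", "mediate_downstream")`.
#'
#' Outputs in `out_dir`: `stage1_mr.tsv`, `stage1_sensitivity.tsv`,
#' `stage1_smr.tsv`, `stage2_mediation.tsv`, `stage3_mediation.tsv`,
#' `summary.txt`, and `manifest.json` (config hash, seed, package version).
#' Reruns with identical config and seed are byte-identical.
#'
#' @param config_path path to the JSON configuration.
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @return invisibly, the output directory path.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  if (!file.exists(config_path)) stop("run_pipeline: config not found: ", config_path)
  raw <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  cfg <- merge_config(raw$thresholds)
  if (!is.null(raw$seed)) cfg$seed <- raw$seed
  out_dir <- out_dir %||% raw$out_dir %||% "mrmediate_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- raw$stages %||% c("mr", "smr", "mediate_upstream", "mediate_downstream")

  if (!is.null(raw$simulate)) {
    sim_args <- as.list(raw$simulate$study %||% list())
    mk <- function(k) {
      a <- sim_args; a$seed <- child_seed(cfg$seed, k)
      do.call(sim_config, a)
    }
    upstream <- simulate_study(mk(1))   # cpg -> gene -> outcome
    downstream <- simulate_study(mk(2)) # gene -> immune -> outcome
    exposures <- list(downstream$exposure)
    outcome <- downstream$outcome
    ld <- downstream$ld
    reg_args <- as.list(raw$simulate$smr_region %||% list())
    reg_args$seed <- child_seed(cfg$seed, 3)
    if (is.null(reg_args$shared_causal)) reg_args$shared_causal <- TRUE
    region <- do.call(simulate_smr_region, reg_args)
    qtl_regions <- stats::setNames(list(region$qtl_region),
                                   downstream$exposure$trait_id)
    gwas_region <- region$gwas_region
    region_ld <- region$ld
  } else {
    inp <- raw$inputs
    if (is.null(inp)) stop("run_pipeline: config needs a 'simulate' or 'inputs' block")
    read_one <- function(spec) {
      spec <- as.list(spec)
      do.call(read_sumstats, c(list(path = spec$path),
                               spec[setdiff(names(spec), "path")]))
    }
    exp_specs <- inp$exposures
    if (is.data.frame(exp_specs))   # jsonlite simplifies arrays of objects
      exp_specs <- lapply(seq_len(nrow(exp_specs)), function(i) exp_specs[i, ])
    exposures <- lapply(exp_specs, read_one)
    outcome <- read_one(inp$outcome)
    ld <- if (!is.null(inp$ld))
      read_ld_matrix(inp$ld$path, inp$ld$positions_path) else NULL
    qtl_regions <- NULL; gwas_region <- NULL; region_ld <- ld
    upstream <- NULL; downstream <- NULL
  }

  decisions <- NULL
  if ("mr" %in% stages) {
    decisions <- stage1_screen(exposures, outcome, ld, cfg)
    write_tsv(stage1_table(decisions), file.path(out_dir, "stage1_mr.tsv"))
    write_tsv(sensitivity_table(decisions),
              file.path(out_dir, "stage1_sensitivity.tsv"))
  }
  if ("smr" %in% stages && !is.null(decisions) && !is.null(qtl_regions)) {
    decisions <- stage1_validate_smr(decisions, qtl_regions, gwas_region,
                                     region_ld, cfg)
    write_tsv(smr_table(decisions), file.path(out_dir, "stage1_smr.tsv"))
  }
  med_cfg <- cfg; med_cfg$n_boot <- min(cfg$n_boot, 200)
  if ("mediate_upstream" %in% stages && !is.null(raw$simulate)) {
    st2 <- stage2_upstream(list(upstream$exposure), upstream$mediator,
                           upstream$outcome, upstream$ld, med_cfg)
    write_tsv(mediation_table(st2$results, reported_only = FALSE),
              file.path(out_dir, "stage2_mediation.tsv"))
  }
  if ("mediate_downstream" %in% stages && !is.null(raw$simulate)) {
    st3 <- stage3_downstream(downstream$exposure, list(downstream$mediator),
                             downstream$outcome, downstream$ld, med_cfg)
    write_tsv(mediation_table(st3$results, reported_only = FALSE),
              file.path(out_dir, "stage3_mediation.tsv"))
  }

  summary_lines <- c("mrmediate pipeline summary",
                     sprintf("stages: %s", paste(stages, collapse = ", ")))
  if (!is.null(decisions))
    summary_lines <- c(summary_lines, vapply(decisions, function(d)
      sprintf("%s: %s", d$unit_id, d$verdict), character(1)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  manifest <- list(config_md5 = unname(tools::md5sum(config_path)),
                   seed = cfg$seed,
                   package = "mrmediate",
                   version = as.character(utils::packageVersion("mrmediate")),
                   stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `pipeline` (full run), `simulate` (write a simulated study
#' to disk), `mr`, `smr`, `mediate` (stage subsets of `pipeline`). Flags:
#' `--config PATH` (required for all but `simulate`), `--seed INT`,
#' `--out-dir PATH`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status 0 on success (invisibly).
#' @export
mr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: mrmediate <pipeline|simulate|mr|smr|mediate> [--config PATH] [--seed INT] [--out-dir PATH]")
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out_dir <- opt("--out-dir", "mrmediate_out")
  config <- opt("--config")
  stage_map <- list(mr = "mr", smr = c("mr", "smr"),
                    mediate = c("mediate_upstream", "mediate_downstream"),
                    pipeline = c("mr", "smr", "mediate_upstream", "mediate_downstream"))
  if (cmd == "simulate") {
    study <- simulate_study(sim_config(seed = seed))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sumstats(study$exposure, file.path(out_dir, "exposure.tsv"))
    write_sumstats(study$mediator, file.path(out_dir, "mediator.tsv"))
    write_sumstats(study$outcome, file.path(out_dir, "outcome.tsv"))
    write_ld_matrix(study$ld, file.path(out_dir, "ld.txt"))
  } else if (cmd %in% names(stage_map)) {
    if (is.null(config)) stop("mr_cli: --config is required for '", cmd, "'")
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    raw$stages <- stage_map[[cmd]]
    raw$seed <- raw$seed %||% seed
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(raw, tmp, auto_unbox = TRUE)
    run_pipeline(tmp, out_dir = out_dir)
  } else stop("mr_cli: unknown subcommand '", cmd, "'")
  invisible(0L)
}
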