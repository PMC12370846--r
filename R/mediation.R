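# Two-step mediation MR: product-of-coefficients decomposition of a total
# causal effect into indirect (via a mediator) and direct components, with a
# directional-consistency filter on the three regression coefficients.

#' Directional-consistency filter
#'
#' A mediation chain is directionally consistent when the indirect path
#' agrees in sign with the total effect: a positive total effect requires
#' the exposure-to-mediator (`beta1`) and mediator-to-outcome (`beta2`)
#' effects to be both positive or both negative; a negative total effect
#' requires them to have opposite signs. Equivalently
#' `sign(beta1 * beta2) == sign(beta_total)`.
#'
#' @param beta_total,beta1,beta2 the three effects; any exact zero fails the
#'   filter (degenerate, logged).
#' @return logical scalar.
#' @export
directional_filter <- function(beta_total, beta1, beta2) {
  if (beta_total == 0 || beta1 == 0 || beta2 == 0) {
    log_info("directional_filter: zero coefficient, filter fails")
    return(FALSE)
  }
  sign(beta1 * beta2) == sign(beta_total)
}

#' Mediation effect decomposition
#'
#' Product-of-coefficients mediation: indirect effect `beta1 * beta2` with
#' first-order delta-method SE `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`,
#' proportion mediated `indirect / beta_total`, direct effect
#' `beta_total - indirect`. Proportions outside [0, 1] (opposing direct and
#' indirect paths) are reported as computed, with a warning.
#'
#' @param beta_total,se_total total effect of exposure on outcome and SE.
#' @param beta1,se1 exposure-to-mediator effect and SE.
#' @param beta2,se2 mediator-to-outcome effect and SE.
#' @param exposure_id,mediator_id,outcome_id optional labels.
#' @return list of class `mediation_result`: the inputs plus `indirect`,
#'   `se_indirect`, `p_indirect` (normal), `proportion`, `direct`,
#'   `consistent` (the [directional_filter()]).
#' @export
mediation_effect <- function(beta_total, se_total, beta1, se1, beta2, se2,
                             exposure_id = "exposure", mediator_id = "mediator",
                             outcome_id = "outcome") {
  if (beta_total == 0) stop("mediation_effect: zero total effect, proportion undefined")
  indirect <- beta1 * beta2
  se_indirect <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  proportion <- indirect / beta_total
  if (proportion < 0 || proportion > 1)
    log_warn("mediation_effect: proportion mediated %.3f outside [0, 1]", proportion)
  structure(list(
    exposure_id = exposure_id, mediator_id = mediator_id, outcome_id = outcome_id,
    beta_total = beta_total, se_total = se_total,
    beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
    indirect = indirect, se_indirect = se_indirect,
    p_indirect = if (se_indirect > 0) p_normal(indirect, se_indirect) else NA_real_,
    proportion = proportion, direct = beta_total - indirect,
    consistent = directional_filter(beta_total, beta1, beta2)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> %s -> %s -> %s\n  total %.4f, indirect %.4f (%.2f%%), direct %.4f, consistent: %s\n",
    x$exposure_id, x$mediator_id, x$outcome_id, x$beta_total, x$indirect,
    100 * x$proportion, x$direct, x$consistent))
  invisible(x)
}

# One MR leg: instrument selection on the leg's exposure, harmonization
# against the leg's outcome, full estimator battery. Returns NULL when no
# instruments survive.
mr_leg <- function(exposure_ds, outcome_ds, ld, config) {
  cfg <- mediation_config(config)
  dat <- tryCatch(
    build_instruments(exposure_ds, outcome_ds, ld,
                      p_threshold = cfg$p_threshold, maf_min = cfg$maf_min,
                      r2_threshold = cfg$clump_r2, window_kb = cfg$clump_kb,
                      f_min = cfg$f_min,
                      palindrome_window = cfg$palindrome_window),
    error = function(e) data.frame())
  if (!nrow(dat)) return(NULL)
  res <- mr_all(dat, n_boot = cfg$n_boot, seed = cfg$seed)
  list(dat = dat, results = res, ivw = res[res$method == "ivw_mre", ][1, ],
       egger = if ("egger" %in% res$method) res[res$method == "egger", ][1, ] else NULL,
       egger_intercept = attr(res, "egger_intercept"))
}

mediation_config <- function(config = NULL) {
  defaults <- list(p_threshold = 5e-8, maf_min = 0.01, clump_r2 = 0.001,
                   clump_kb = 10000, f_min = 20, palindrome_window = 0.08,
                   alpha = 0.05, n_boot = 1000, seed = 1)
  if (is.null(config)) return(defaults)
  defaults[names(config)] <- config
  defaults
}

leg_ok <- function(leg, alpha) {
  if (is.null(leg)) return(FALSE)
  if (!(leg$ivw$pval < alpha)) return(FALSE)
  # direction must agree with MR-Egger when Egger is estimable
  if (!is.null(leg$egger) && sign(leg$ivw$beta) != sign(leg$egger$beta))
    return(FALSE)
  TRUE
}

#' Two-step mediation MR
#'
#' Runs three univariable MR legs, each with its own instruments: (i)
#' exposure to outcome (total effect `beta`), (ii) exposure to mediator
#' (`beta1`), (iii) mediator to outcome (`beta2`); IVW multiplicative
#' random effects is the headline estimator of every leg (the full battery
#' is recorded). The decomposition is reported (`reported = TRUE`) only
#' when each leg's IVW p-value is below `alpha`, each leg's IVW and Egger
#' estimates agree in sign, and the [directional_filter()] passes.
#' `beta2` comes from univariable MR of the mediator on the outcome (not
#' multivariable MR adjusting for the exposure).
#'
#' @param exposure_ds,mediator_ds,outcome_ds [summary_dataset()] objects.
#' @param ld optional [ld_matrix()] shared by the three legs.
#' @param config named list overriding `p_threshold`, `maf_min`, `clump_r2`,
#'   `clump_kb`, `f_min`, `palindrome_window`, `alpha`, `n_boot`, `seed`.
#' @return `mediation_result` with extra fields `reported`, `legs_ok`, and
#'   `component_results` (the three estimator tables); errors if any leg has
#'   zero surviving instruments.
#' @export
two_step_mediation <- function(exposure_ds, mediator_ds, outcome_ds, ld = NULL,
                               config = NULL) {
  cfg <- mediation_config(config)
  leg_total <- mr_leg(exposure_ds, outcome_ds, ld, cfg)
  leg1 <- mr_leg(exposure_ds, mediator_ds, ld, cfg)
  leg2 <- mr_leg(mediator_ds, outcome_ds, ld, cfg)
  for (nm in c("leg_total", "leg1", "leg2")) {
    if (is.null(get(nm)))
      stop("two_step_mediation: no surviving instruments for ", nm)
  }
  res <- mediation_effect(
    leg_total$ivw$beta, leg_total$ivw$se,
    leg1$ivw$beta, leg1$ivw$se, leg2$ivw$beta, leg2$ivw$se,
    exposure_id = exposure_ds$trait_id, mediator_id = mediator_ds$trait_id,
    outcome_id = outcome_ds$trait_id)
  res$legs_ok <- c(total = leg_ok(leg_total, cfg$alpha),
                   exposure_mediator = leg_ok(leg1, cfg$alpha),
                   mediator_outcome = leg_ok(leg2, cfg$alpha))
  res$reported <- all(res$legs_ok) && res$consistent
  res$component_results <- list(total = leg_total$results, beta1 = leg1$results,
                                beta2 = leg2$results)
  res
}

#' Tabulate mediation results for reporting
#'
#' @param results list of `mediation_result` objects.
#' @param reported_only keep only results passing the reporting rule
#'   (default TRUE).
#' @return data frame: exposure, mediator, outcome, beta_total, beta1,
#'   beta2, indirect, se_indirect, proportion_pct, direct, consistent,
#'   reported.
#' @export
mediation_table <- function(results, reported_only = TRUE) {
  rows <- lapply(results, function(r) {
    data.frame(exposure = r$exposure_id, mediator = r$mediator_id,
               outcome = r$outcome_id, beta_total = r$beta_total,
               beta1 = r$beta1, beta2 = r$beta2, indirect = r$indirect,
               se_indirect = r$se_indirect,
               proportion_pct = 100 * r$proportion, direct = r$direct,
               consistent = r$consistent,
               reported = isTRUE(r$reported), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (reported_only && !is.null(tab)) tab <- tab[tab$reported, , drop = FALSE]
  tab
}
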