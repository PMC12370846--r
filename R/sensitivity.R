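# Heterogeneity, pleiotropy and outlier diagnostics: Cochran's Q, Egger
# intercept (via mr_egger), leave-one-out IVW, and MR-PRESSO.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (ratio_j - beta_ivw)^2` over per-SNP Wald ratios with
#' weights `w_j = beta_exp_j^2 / se_out_j^2`; p from the upper tail of the
#' chi-square distribution with `nsnp - 1` degrees of freedom. Identical to
#' the weighted RSS of the through-origin IVW regression.
#'
#' @param dat instrument table (at least 2 rows).
#' @param ivw_beta pooled estimate to test against; default the fixed-effect
#'   IVW estimate of `dat` (which minimizes Q).
#' @return data frame: `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(dat, ivw_beta = NULL) {
  check_dat(dat, 2L, "cochran_q")
  if (any(dat$beta_exp == 0)) stop("cochran_q: zero beta_exp")
  if (is.null(ivw_beta)) ivw_beta <- ivw_core(dat)$beta
  ratio <- dat$beta_out / dat$beta_exp
  w <- dat$beta_exp^2 / dat$se_out^2
  q <- sum(w * (ratio - ivw_beta)^2)
  df <- nrow(dat) - 1L
  data.frame(q_stat = q, q_df = df,
             q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates IVW with each instrument removed in turn, using the same
#' effects model as the headline analysis, to expose estimates driven by a
#' single SNP.
#'
#' @param dat instrument table with an (optional) `rsid` column, >= 2 rows.
#' @param effects_model passed to [mr_ivw()].
#' @return data frame with one row per left-out SNP: `rsid`, `beta`, `se`,
#'   `pval`.
#' @export
leave_one_out <- function(dat, effects_model = "multiplicative_random") {
  check_dat(dat, 2L, "leave_one_out")
  rsid <- dat$rsid %||% paste0("snp", seq_len(nrow(dat)))
  rows <- lapply(seq_len(nrow(dat)), function(j) {
    r <- mr_ivw(dat[-j, , drop = FALSE], effects_model)
    data.frame(rsid = rsid[j], beta = r$beta, se = r$se, pval = r$pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Leave-one-out fixed-effect IVW betas, vectorized via sum updates.
loo_beta_vec <- function(be, bo, w) {
  sxy <- sum(w * be * bo); sxx <- sum(w * be^2)
  (sxy - w * be * bo) / (sxx - w * be^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' The observed statistic is `RSS_obs = sum_j (beta_out_j - b_(-j)
#' beta_exp_j)^2 / se_out_j^2`, with `b_(-j)` the leave-one-out fixed-effect
#' IVW estimate. Null replicates redraw `beta_out_j* ~ N(b_(-j) beta_exp_j,
#' se_out_j)` and recompute the statistic (with the leave-one-out estimates
#' re-fitted on the simulated data); the global p-value is
#' `(1 + #\{RSS_sim >= RSS_obs\}) / (n_sim + 1)`. Per-SNP outlier p-values are
#' the fraction of simulated j-th squared residuals at or above the observed
#' one, Bonferroni-adjusted by nsnp; flagged SNPs are removed and the
#' corrected IVW reported, with an informational distortion test comparing
#' the observed full-vs-corrected shift against random outlier labelings.
#'
#' @param dat instrument table with >= 4 rows (`rsid` optional).
#' @param n_sim simulation replicates (default 1000).
#' @param seed RNG seed (results are reproducible given the seed).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param effects_model IVW variant for the corrected estimate.
#' @return list: `global_pval`, `outliers` (character rsids, possibly
#'   empty), `corrected` (MR result on non-outliers, or `NULL` when every
#'   SNP is flagged), `distortion_pval` (`NA` when no outliers).
#' @export
mr_presso <- function(dat, n_sim = 1000, seed = 1, outlier_alpha = 0.05,
                      effects_model = "multiplicative_random") {
  check_dat(dat, 4L, "mr_presso")
  n <- nrow(dat)
  rsid <- dat$rsid %||% paste0("snp", seq_len(n))
  be <- dat$beta_exp; bo <- dat$beta_out; so <- dat$se_out
  w <- 1 / so^2
  b_loo <- loo_beta_vec(be, bo, w)
  res_obs <- (bo - b_loo * be)^2 * w
  rss_obs <- sum(res_obs)

  sims <- with_seed(seed, {
    mu <- b_loo * be
    bo_sim <- matrix(stats::rnorm(n * n_sim, mean = mu, sd = so), nrow = n)
    sxx <- sum(w * be^2)
    sxy_sim <- colSums(w * be * bo_sim)            # length n_sim
    # leave-one-out betas per simulated dataset: (sxy - w_j be_j bo*_jk)/(sxx - w_j be_j^2)
    num <- matrix(sxy_sim, n, n_sim, byrow = TRUE) - (w * be) * bo_sim
    den <- sxx - w * be^2
    bloo_sim <- num / den
    res_sim <- (bo_sim - bloo_sim * be)^2 * w      # n x n_sim
    list(rss = colSums(res_sim),
         exceed = rowMeans(res_sim >= res_obs))
  })

  global_pval <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  p_out <- pmin(1, sims$exceed * n)
  outliers <- rsid[p_out < outlier_alpha]

  corrected <- NULL; distortion_pval <- NA_real_
  if (length(outliers) && length(outliers) < n) {
    keep <- !(rsid %in% outliers)
    corrected <- mr_ivw(dat[keep, , drop = FALSE], effects_model)
    full <- mr_ivw(dat, effects_model)
    d_obs <- abs(corrected$beta - full$beta)
    k_out <- sum(!keep)
    distortion_pval <- with_seed(child_seed(seed, 7), {
      d_sim <- vapply(seq_len(n_sim), function(s) {
        drop_idx <- sample.int(n, k_out)
        abs(mr_ivw(dat[-drop_idx, , drop = FALSE], effects_model)$beta - full$beta)
      }, numeric(1))
      mean(d_sim >= d_obs)
    })
  } else if (length(outliers) == n) {
    log_warn("mr_presso: every instrument flagged; corrected estimate unavailable")
  }
  list(global_pval = global_pval, outliers = outliers, corrected = corrected,
       distortion_pval = distortion_pval, outlier_pvals = stats::setNames(p_out, rsid))
}

#' Assemble the full sensitivity report
#'
#' Cochran's Q, the Egger intercept, leave-one-out table, and (for
#' `nsnp >= 4`) MR-PRESSO, bundled for one exposure/outcome analysis.
#'
#' @param dat instrument table (>= 2 rows).
#' @param n_sim,seed MR-PRESSO settings.
#' @return list of class `sensitivity_report`: `q` (data frame),
#'   `egger_intercept` (data frame or NULL when nsnp < 3), `loo` (data
#'   frame), `presso` (list or NULL when nsnp < 4).
#' @export
sensitivity_report <- function(dat, n_sim = 1000, seed = 1) {
  check_dat(dat, 2L, "sensitivity_report")
  q <- cochran_q(dat)
  egger_int <- if (nrow(dat) >= 3) mr_egger(dat)$intercept else NULL
  loo <- leave_one_out(dat)
  presso <- if (nrow(dat) >= 4) mr_presso(dat, n_sim = n_sim, seed = seed) else NULL
  structure(list(q = q, egger_intercept = egger_int, loo = loo, presso = presso),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(format_sensitivity(x), sep = "\n")
  invisible(x)
}

# One-block plain-text summary (serialization used by the pipeline).
format_sensitivity <- function(x) {
  out <- sprintf("Cochran Q = %.4f (df %d), p = %.4g", x$q$q_stat, x$q$q_df, x$q$q_pval)
  if (!is.null(x$egger_intercept))
    out <- c(out, sprintf("Egger intercept = %.5f (se %.5f), p = %.4g",
                          x$egger_intercept$estimate, x$egger_intercept$se,
                          x$egger_intercept$pval))
  if (!is.null(x$presso)) {
    out <- c(out, sprintf("MR-PRESSO global p = %.4g; outliers: %s",
                          x$presso$global_pval,
                          if (length(x$presso$outliers))
                            paste(x$presso$outliers, collapse = ", ") else "none"))
  }
  out
}
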