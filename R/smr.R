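# Summary-data-based MR (SMR) and the HEIDI test separating a single shared
# causal variant from two distinct variants in linkage.

#' SMR test at the top QTL variant
#'
#' Combines a trait's strongest QTL association with the GWAS association at
#' the same variant. With `z = beta/se` for each study, the effect of the
#' molecular trait on the outcome is `b_xy = beta_gwas / beta_qtl`, and
#' `T_smr = z_qtl^2 z_gwas^2 / (z_qtl^2 + z_gwas^2)` is compared to the
#' chi-square distribution with 1 df. The harmonic form caps `T_smr` at the
#' weaker of the two signals, so significance requires both.
#'
#' @param qtl_top single-row data frame (or list) with `rsid`,
#'   `effect_allele`, `other_allele`, `beta`, `se` of the top QTL variant.
#' @param gwas_at_top same fields for the GWAS association at that variant,
#'   on the same allele frame.
#' @return list of class `smr_result`: `top_rsid`, `b_xy`, `se_xy`, `p_smr`,
#'   `p_heidi = NA`, `n_heidi_snps = 0`.
#' @export
smr_test <- function(qtl_top, gwas_at_top) {
  if (!identical(as.character(qtl_top$rsid), as.character(gwas_at_top$rsid)))
    stop("smr_test: rsid mismatch")
  if (!is.null(qtl_top$effect_allele) && !is.null(gwas_at_top$effect_allele)) {
    if (qtl_top$effect_allele != gwas_at_top$effect_allele ||
        qtl_top$other_allele != gwas_at_top$other_allele)
      stop("smr_test: allele mismatch; harmonize inputs first")
  }
  if (qtl_top$beta == 0) stop("smr_test: zero QTL beta")
  z_q <- qtl_top$beta / qtl_top$se
  z_g <- gwas_at_top$beta / gwas_at_top$se
  t_smr <- (z_q^2 * z_g^2) / (z_q^2 + z_g^2)
  b_xy <- gwas_at_top$beta / qtl_top$beta
  structure(list(top_rsid = as.character(qtl_top$rsid), b_xy = b_xy,
                 se_xy = abs(b_xy) / sqrt(t_smr), t_smr = t_smr,
                 p_smr = stats::pchisq(t_smr, 1, lower.tail = FALSE),
                 p_heidi = NA_real_, n_heidi_snps = 0L),
            class = "smr_result")
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf("<smr_result> %s: b_xy = %.4f (se %.4f), p_smr = %.3g, p_heidi = %s (%d SNPs)\n",
              x$top_rsid, x$b_xy, x$se_xy, x$p_smr,
              ifelse(is.na(x$p_heidi), "NA", sprintf("%.3g", x$p_heidi)),
              x$n_heidi_snps))
  invisible(x)
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Under a single shared causal variant, `b_xy(i) = beta_gwas_i/beta_qtl_i`
#' is the same at every variant in LD with the top association; under
#' linkage (distinct causal variants) it varies. Candidate SNPs are those
#' with `r^2` to the top variant in `[r2_min, r2_max]` and QTL significance
#' below `qtl_p_max`, ranked by QTL significance and truncated to
#' `max_snps`. For each candidate, `d_i = b_xy(i) - b_xy(top)`; the
#' covariance of `d` is propagated to first order from the signed LD
#' correlations and the per-study SEs (QTL and GWAS samples assumed
#' independent, so `cov(beta_i, beta_j) = r_ij se_i se_j` within each
#' study). The statistic `sum_i d_i^2 / var(d_i)` is referred to its null
#' distribution by seeded Monte Carlo draws from `MVN(0, Cov(d))`.
#'
#' @param qtl_region,gwas_region [summary_dataset()] objects over the region,
#'   harmonized to a common allele frame.
#' @param ld [ld_matrix()] covering the region (signed correlations).
#' @param top_rsid the top QTL variant (anchor of the test).
#' @param r2_min,r2_max LD eligibility window for candidates (defaults 0.05
#'   and 0.9 — close proxies of the top SNP carry no independent
#'   information, near-independent SNPs none at all).
#' @param max_snps,min_snps candidate count bounds (defaults 20 and 3);
#'   below `min_snps` the test is unavailable (`p_heidi = NA`).
#' @param qtl_p_max QTL significance floor for candidates (default 1.57e-3,
#'   i.e. |z| > 3.16), keeping the first-order variance propagation valid.
#' @param n_mc Monte Carlo draws (default 1e5).
#' @param seed RNG seed.
#' @param ridge diagonal inflation applied to a non-positive-definite
#'   covariance before giving up (default 1e-8).
#' @return list: `p_heidi` (NA when unavailable), `n_heidi_snps`,
#'   `statistic`, `candidates` (character rsids).
#' @export
heidi_test <- function(qtl_region, gwas_region, ld, top_rsid,
                       r2_min = 0.05, r2_max = 0.9, max_snps = 20,
                       min_snps = 3, qtl_p_max = 1.57e-3, n_mc = 1e5,
                       seed = 1, ridge = 1e-8) {
  q <- qtl_region$data; g <- gwas_region$data
  common <- Reduce(intersect, list(q$rsid, g$rsid, ld$rsids))
  if (!(top_rsid %in% common)) stop("heidi_test: top_rsid absent from inputs")
  q <- q[match(common, q$rsid), ]; g <- g[match(common, g$rsid), ]
  R <- ld$r[common, common, drop = FALSE]

  r_top <- R[, top_rsid]
  z_q <- q$beta / q$se
  elig <- common != top_rsid & r_top^2 >= r2_min & r_top^2 <= r2_max &
    2 * stats::pnorm(-abs(z_q)) < qtl_p_max
  cand <- common[elig]
  if (length(cand) > max_snps) {
    ord <- order(-abs(z_q[elig]))
    cand <- cand[ord][seq_len(max_snps)]
  }
  m <- length(cand)
  if (m < min_snps)
    return(list(p_heidi = NA_real_, n_heidi_snps = m, statistic = NA_real_,
                candidates = cand))

  sel <- c(cand, top_rsid)
  qi <- match(sel, common)
  qb <- q$beta[qi]; qs <- q$se[qi]
  gb <- g$beta[qi]; gs <- g$se[qi]
  Rs <- R[sel, sel, drop = FALSE]
  b <- gb / qb

  # first-order covariance of b_xy across SNPs (QTL and GWAS independent):
  # cov(b_i, b_j) = r_ij gs_i gs_j / (qb_i qb_j)
  #              + b_i b_j r_ij qs_i qs_j / (qb_i qb_j)
  gterm <- outer(gs / qb, gs / qb) * Rs
  qterm <- outer(b * qs / qb, b * qs / qb) * Rs
  C <- gterm + qterm

  k <- m + 1  # index of top
  Vd <- C[seq_len(m), seq_len(m), drop = FALSE] -
    matrix(C[seq_len(m), k], m, m) -
    matrix(C[seq_len(m), k], m, m, byrow = TRUE) + C[k, k]

  d <- b[seq_len(m)] - b[k]
  vdiag <- diag(Vd)
  if (any(vdiag <= 0)) stop("heidi_test: non-positive d variance")
  stat <- sum(d^2 / vdiag)

  ch <- tryCatch(chol(Vd), error = function(e) NULL)
  if (is.null(ch)) {
    Vd2 <- Vd + diag(ridge * max(vdiag), m)
    ch <- tryCatch(chol(Vd2), error = function(e)
      stop("heidi_test: covariance not positive semi-definite after ridge ",
           ridge, " (m = ", m, ", min eig = ",
           format(min(eigen(Vd, only.values = TRUE)$values)), ")"))
  }
  p <- with_seed(seed, {
    zmat <- matrix(stats::rnorm(n_mc * m), n_mc, m) %*% ch   # rows ~ MVN(0, Vd)
    stat_sim <- as.vector(zmat^2 %*% (1 / vdiag))
    (1 + sum(stat_sim >= stat)) / (n_mc + 1)
  })
  list(p_heidi = p, n_heidi_snps = m, statistic = stat, candidates = cand)
}

#' SMR + HEIDI combined test over a region
#'
#' Runs [smr_test()] at the top QTL variant of the region (largest |z|),
#' then [heidi_test()] around it, and labels the verdict by the decision
#' rule: `p_smr < alpha` and `p_heidi > alpha` indicate a shared causal
#' variant.
#'
#' @param qtl_region,gwas_region,ld as in [heidi_test()].
#' @param top_rsid anchor SNP; default the region's strongest QTL
#'   association.
#' @param alpha decision level (default 0.05).
#' @param ... passed to [heidi_test()].
#' @return `smr_result` with `p_heidi`/`n_heidi_snps` filled and a `verdict`
#'   in `pass`, `fail_smr`, `fail_heidi`, `heidi_unavailable`.
#' @export
smr_heidi <- function(qtl_region, gwas_region, ld, top_rsid = NULL,
                      alpha = 0.05, ...) {
  q <- qtl_region$data
  common <- intersect(q$rsid, gwas_region$data$rsid)
  if (is.null(top_rsid)) {
    qq <- q[q$rsid %in% common, ]
    top_rsid <- qq$rsid[which.max(abs(qq$beta / qq$se))]
  }
  g <- gwas_region$data
  res <- smr_test(q[q$rsid == top_rsid, ], g[g$rsid == top_rsid, ])
  h <- heidi_test(qtl_region, gwas_region, ld, top_rsid, ...)
  res$p_heidi <- h$p_heidi
  res$n_heidi_snps <- h$n_heidi_snps
  res$heidi_statistic <- h$statistic
  res$verdict <- if (res$p_smr >= alpha) "fail_smr"
  else if (is.na(res$p_heidi)) "heidi_unavailable"
  else if (res$p_heidi <= alpha) "fail_heidi"
  else "pass"
  res
}
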