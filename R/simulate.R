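# Synthetic GWAS summary statistics with known truth. Traits live on the
# standardized (variance-1) scale so that se = 1/sqrt(n); a binary outcome is
# represented on a continuous liability/log-odds scale. Marginal effects are
# LD-propagated joint effects (marginal = R %*% joint); observed betas add
# i.i.d. sampling noise at the per-trait SE. No individual-level genotypes
# are ever generated.

#' Simulation configuration
#'
#' Defaults describe a mid-sized molecular-trait study: 300 variants in 30
#' LD blocks, 30 instruments with standardized effect spread 0.05 (per-SNP
#' variance explained around 0.25%, F around 250 at n = 1e5), exchangeable
#' within-block correlation 0.6, MAF uniform on (0.05, 0.5), and a null
#' causal chain unless effects are supplied.
#'
#' @param n_variants total variants on one synthetic chromosome.
#' @param n_blocks LD blocks (variants split evenly; blocks are mutually
#'   independent and far apart physically).
#' @param within_block_r correlation parameter in `[0, 1)`.
#' @param ld_structure `"exchangeable"` (constant within-block r) or
#'   `"ar1"` (r^|i-j| decay, for distance-aware clumping tests).
#' @param n_instruments variants with nonzero joint effects on the exposure
#'   (spread one per block first, then recycled).
#' @param n_med_instruments mediator-specific instruments, required for an
#'   unbiased mediator-to-outcome leg (default equal to `n_instruments`).
#' @param effect_sd spread of true standardized instrument effects.
#' @param n_exp,n_med,n_out per-trait GWAS sample sizes (all >= 100).
#' @param beta1_true exposure-to-mediator causal effect.
#' @param beta2_true mediator-to-outcome causal effect.
#' @param direct_true exposure-to-outcome effect not via the mediator; the
#'   implied total effect is `direct_true + beta1_true * beta2_true`.
#' @param pleiotropy list: `type` in `"none"`, `"balanced"`,
#'   `"directional"`; `mean` (directional shift), `sd`, `frac` (fraction of
#'   exposure instruments affected).
#' @param maf_range length-2 range for uniform MAF draws.
#' @param seed RNG seed; all outputs are reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 300, n_blocks = 30, within_block_r = 0.6,
                       ld_structure = c("exchangeable", "ar1"),
                       n_instruments = 30, n_med_instruments = n_instruments,
                       effect_sd = 0.05, n_exp = 1e5, n_med = 1e5, n_out = 1e5,
                       beta1_true = 0, beta2_true = 0, direct_true = 0,
                       pleiotropy = list(type = "none", mean = 0, sd = 0, frac = 0),
                       maf_range = c(0.05, 0.5), seed = 1) {
  ld_structure <- match.arg(ld_structure)
  stopifnot(n_instruments <= n_variants,
            n_instruments + n_med_instruments <= n_variants,
            n_exp >= 100, n_med >= 100, n_out >= 100,
            within_block_r >= 0, within_block_r < 1)
  pl <- list(type = "none", mean = 0, sd = 0, frac = 0)
  pl[names(pleiotropy)] <- pleiotropy
  stopifnot(pl$type %in% c("none", "balanced", "directional"))
  structure(list(n_variants = n_variants, n_blocks = n_blocks,
                 within_block_r = within_block_r, ld_structure = ld_structure,
                 n_instruments = n_instruments,
                 n_med_instruments = n_med_instruments, effect_sd = effect_sd,
                 n_exp = n_exp, n_med = n_med, n_out = n_out,
                 beta1_true = beta1_true, beta2_true = beta2_true,
                 direct_true = direct_true, pleiotropy = pl,
                 maf_range = maf_range, seed = seed),
            class = "sim_config")
}

# Block-diagonal LD correlation matrix plus positions (blocks 10 Mb apart,
# 5 kb spacing within a block, so cross-block pairs are physically remote).
build_ld <- function(n_variants, n_blocks, rho, structure_type, rsids) {
  block_of <- rep(seq_len(n_blocks), length.out = n_variants)
  block_of <- sort(block_of)
  R <- matrix(0, n_variants, n_variants)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_of == b)
    m <- length(idx)
    if (structure_type == "exchangeable") {
      Rb <- matrix(rho, m, m); diag(Rb) <- 1
    } else {
      Rb <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
    }
    R[idx, idx] <- Rb
  }
  within_rank <- stats::ave(seq_len(n_variants), block_of, FUN = seq_along)
  pos <- (block_of - 1) * 1e7 + within_rank * 5000
  list(ld = ld_matrix(rsids, R, pos), block_of = block_of, pos = pos)
}

# Non-palindromic allele pairs only, so harmonization never drops simulated
# variants on frequency grounds.
ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

make_trait_ds <- function(rsids, chrom, pos, ea, oa, eaf, marginal, n, trait_id,
                          trait_type = "quantitative") {
  se <- rep(1 / sqrt(n), length(rsids))
  beta <- marginal + stats::rnorm(length(rsids), 0, se)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  pval[pval == 0] <- .Machine$double.xmin
  summary_dataset(data.frame(
    rsid = rsids, chrom = chrom, pos = pos, effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = beta, se = se, pval = pval, n = n,
    stringsAsFactors = FALSE), trait_id, trait_type, validate = FALSE)
}

#' Simulate a three-trait summary-statistics study with known truth
#'
#' Generates exposure, mediator, and outcome GWAS summary statistics over a
#' common set of LD-blocked variants. Joint (causal-scale) effects: the
#' chosen exposure instruments get effects `N(0, effect_sd^2)`; the mediator
#' inherits `beta1_true` times the exposure effects plus its own
#' mediator-specific instruments; the outcome combines the direct path,
#' `beta2_true` times the mediator effects, and optional pleiotropy draws
#' added straight to the outcome. Marginal effects are `R %*% joint`;
#' observed effects add independent `N(0, 1/n)` noise, and `se = 1/sqrt(n)`.
#'
#' @param config a [sim_config()].
#' @return list: `exposure`, `mediator`, `outcome` ([summary_dataset()]s),
#'   `ld` ([ld_matrix()]), and `truth` — a list with per-variant joint and
#'   marginal effects per trait, instrument indices, `beta1_true`,
#'   `beta2_true`, `direct_true`, `beta_total_true`, and `proportion_true`
#'   (NA when the total effect is zero).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    p <- cfg$n_variants
    rsids <- sprintf("rs%06d", seq_len(p))
    grid <- build_ld(p, cfg$n_blocks, cfg$within_block_r, cfg$ld_structure, rsids)
    maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
    ap <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), p, replace = TRUE), ,
                       drop = FALSE]

    # instruments: first exposure instruments one per block, then
    # mediator-specific ones on the remaining variants
    first_in_block <- which(!duplicated(grid$block_of))
    pool <- c(first_in_block, setdiff(seq_len(p), first_in_block))
    exp_idx <- pool[seq_len(cfg$n_instruments)]
    med_pool <- setdiff(pool, exp_idx)
    med_idx <- if (cfg$n_med_instruments > 0)
      med_pool[seq_len(cfg$n_med_instruments)] else integer(0)

    joint_exp <- numeric(p)
    joint_exp[exp_idx] <- stats::rnorm(length(exp_idx), 0, cfg$effect_sd)
    joint_med <- cfg$beta1_true * joint_exp
    joint_med[med_idx] <- joint_med[med_idx] +
      stats::rnorm(length(med_idx), 0, cfg$effect_sd)
    joint_out <- cfg$direct_true * joint_exp + cfg$beta2_true * joint_med

    pl <- cfg$pleiotropy
    pleio <- numeric(p)
    if (pl$type != "none" && pl$frac > 0 && length(exp_idx)) {
      k <- max(1L, round(pl$frac * length(exp_idx)))
      tgt <- sample(exp_idx, k)
      pleio[tgt] <- stats::rnorm(k, 0, pl$sd)
      if (pl$type == "directional") {
        # directional means directional with respect to the
        # exposure-increasing allele; otherwise random allele coding makes
        # any mean shift balanced by construction
        pleio[tgt] <- pleio[tgt] + pl$mean * sign(joint_exp[tgt])
      }
      joint_out <- joint_out + pleio
    }

    R <- grid$ld$r
    if (cfg$within_block_r == 0) {
      marg_exp <- joint_exp; marg_med <- joint_med; marg_out <- joint_out
    } else {
      marg_exp <- as.vector(R %*% joint_exp)
      marg_med <- as.vector(R %*% joint_med)
      marg_out <- as.vector(R %*% joint_out)
    }

    exposure <- make_trait_ds(rsids, "1", grid$pos, ap[, 1], ap[, 2], maf,
                              marg_exp, cfg$n_exp, "exposure")
    mediator <- make_trait_ds(rsids, "1", grid$pos, ap[, 1], ap[, 2], maf,
                              marg_med, cfg$n_med, "mediator")
    outcome <- make_trait_ds(rsids, "1", grid$pos, ap[, 1], ap[, 2], maf,
                             marg_out, cfg$n_out, "outcome", "binary")

    beta_total <- cfg$direct_true + cfg$beta1_true * cfg$beta2_true
    truth <- list(
      rsids = rsids, instrument_idx = exp_idx, med_instrument_idx = med_idx,
      joint = list(exposure = joint_exp, mediator = joint_med, outcome = joint_out),
      marginal = list(exposure = marg_exp, mediator = marg_med, outcome = marg_out),
      pleiotropy = pleio,
      beta1_true = cfg$beta1_true, beta2_true = cfg$beta2_true,
      direct_true = cfg$direct_true, beta_total_true = beta_total,
      proportion_true = if (beta_total != 0)
        cfg$beta1_true * cfg$beta2_true / beta_total else NA_real_)
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         ld = grid$ld, truth = truth)
  })
}

#' Simulate a QTL/GWAS region for SMR and HEIDI testing
#'
#' One LD region (AR1 correlation, decay 0.9 per 1 kb step). Under
#' `shared_causal = TRUE` a single variant drives both the QTL and the GWAS
#' signal, so the ratio `b_xy` is constant across the region (HEIDI null).
#' Otherwise two distinct causal variants, correlated at approximately
#' `r_between_causals`, drive the QTL and GWAS respectively (linkage
#' alternative). Observed z-statistics are drawn from `MVN(R lambda, R)` —
#' LD-correlated noise, matching the covariance model HEIDI assumes — and
#' converted to betas with `se = 1/sqrt(n)` (QTL n = 2e4, GWAS n = 4e5).
#'
#' @param shared_causal logical scenario switch.
#' @param r_between_causals target LD between the two causal variants in the
#'   linkage scenario (achieved as the closest AR1 power; default 0.6).
#' @param region_size number of variants (>= 25, default 50).
#' @param z_at_causal expected z of each causal variant in its own study
#'   (default 12).
#' @param seed RNG seed.
#' @return list: `qtl_region`, `gwas_region` ([summary_dataset()]s), `ld`
#'   ([ld_matrix()]), `top_rsid` (strongest observed QTL association), and
#'   `truth` (causal indices and the AR1 r actually achieved).
#' @export
simulate_smr_region <- function(shared_causal, r_between_causals = 0.6,
                                region_size = 50, z_at_causal = 12, seed = 1) {
  stopifnot(region_size >= 25)
  rho <- 0.9
  with_seed(seed, {
    m <- region_size
    rsids <- sprintf("rsr%05d", seq_len(m))
    R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
    pos <- seq_len(m) * 1000
    ld <- ld_matrix(rsids, R, pos)

    c1 <- ceiling(m / 2)
    if (shared_causal) {
      c2 <- c1
    } else {
      off <- max(1L, round(log(r_between_causals) / log(rho)))
      c2 <- min(m, c1 + off)
    }
    lam_q <- numeric(m); lam_q[c1] <- z_at_causal
    lam_g <- numeric(m); lam_g[c2] <- z_at_causal

    ch <- chol(R)
    z_q <- as.vector(R %*% lam_q) + as.vector(stats::rnorm(m) %*% ch)
    z_g <- as.vector(R %*% lam_g) + as.vector(stats::rnorm(m) %*% ch)

    n_q <- 2e4; n_g <- 4e5
    mk <- function(z, n, id) {
      se <- rep(1 / sqrt(n), m)
      pv <- 2 * stats::pnorm(-abs(z)); pv[pv == 0] <- .Machine$double.xmin
      summary_dataset(data.frame(
        rsid = rsids, chrom = "1", pos = pos, effect_allele = "A",
        other_allele = "G", eaf = 0.3, beta = z * se, se = se, pval = pv,
        n = n, stringsAsFactors = FALSE), id, validate = FALSE)
    }
    qtl <- mk(z_q, n_q, "qtl")
    gwas <- mk(z_g, n_g, "gwas")
    list(qtl_region = qtl, gwas_region = gwas, ld = ld,
         top_rsid = rsids[which.max(abs(z_q))],
         truth = list(causal_qtl = c1, causal_gwas = c2,
                      r_achieved = rho^abs(c2 - c1), shared = shared_causal))
  })
}

#' Deterministic unit-test fixtures
#'
#' Hard-coded instrument tables used across the test suite. Registry:
#' `"ivw_basic"` (5 SNPs; the weighted-least-squares-through-origin oracle
#' gives IVW beta 0.2929522591484017 on it), `"egger_affine"` (6 SNPs lying
#' exactly on `beta_out = 0.01 + 0.3 beta_exp`), `"presso_outlier"` (8 SNPs,
#' one Wald ratio 10x the rest at small SE), `"median_seven"` (7 SNPs with
#' unequal weights for the cumulative-weight scan oracle).
#'
#' @param name registry key.
#' @return data frame with `rsid`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`.
#' @export
make_fixture <- function(name) {
  fixtures <- list(
    ivw_basic = data.frame(
      rsid = paste0("fx", 1:5),
      beta_exp = c(0.10, 0.15, 0.08, 0.20, 0.12),
      se_exp = c(0.010, 0.012, 0.009, 0.015, 0.011),
      beta_out = c(0.030, 0.042, 0.025, 0.061, 0.033),
      se_out = c(0.008, 0.009, 0.007, 0.011, 0.008)),
    egger_affine = data.frame(
      rsid = paste0("fx", 1:6),
      beta_exp = c(0.05, 0.08, 0.11, 0.14, 0.17, 0.20),
      se_exp = rep(0.01, 6),
      beta_out = 0.01 + 0.3 * c(0.05, 0.08, 0.11, 0.14, 0.17, 0.20),
      se_out = c(0.006, 0.007, 0.008, 0.009, 0.010, 0.011)),
    presso_outlier = data.frame(
      rsid = paste0("fx", 1:8),
      beta_exp = c(0.10, 0.12, 0.09, 0.15, 0.11, 0.13, 0.10, 0.14),
      se_exp = rep(0.010, 8),
      beta_out = c(0.030, 0.037, 0.026, 0.044, 0.034, 0.040, 0.30, 0.042),
      se_out = rep(0.008, 8)),
    median_seven = data.frame(
      rsid = paste0("fx", 1:7),
      beta_exp = c(0.10, 0.12, 0.15, 0.09, 0.20, 0.11, 0.14),
      se_exp = rep(0.01, 7),
      beta_out = c(0.021, 0.030, 0.048, 0.017, 0.071, 0.028, 0.040),
      se_out = c(0.009, 0.008, 0.010, 0.007, 0.012, 0.008, 0.009))
  )
  if (!name %in% names(fixtures)) stop("make_fixture: unknown fixture '", name, "'")
  fixtures[[name]]
}
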