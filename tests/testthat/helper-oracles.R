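# Independent oracles, deliberately implemented through different code paths
# (lm/QR, explicit loops, grid scans) than the package functions they check.

# Weighted least squares through the origin via lm's QR decomposition.
oracle_ivw <- function(dat) {
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = dat, weights = 1 / dat$se_out^2)
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)[1]),
       se_fixed = unname(s$coefficients[1, 2]) / s$sigma,
       sigma = s$sigma)
}

# Weighted regression with intercept via lm; SEs rescaled to the
# fixed-effect form with the max(1, sigma) floor.
oracle_egger <- function(dat) {
  x <- abs(dat$beta_exp)
  y <- ifelse(dat$beta_exp < 0, -dat$beta_out, dat$beta_out)
  fit <- stats::lm(y ~ x, weights = 1 / dat$se_out^2)
  s <- summary(fit)
  infl <- max(1, s$sigma)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se_intercept = unname(s$coefficients[1, 2]) / s$sigma * infl,
       se_slope = unname(s$coefficients[2, 2]) / s$sigma * infl)
}

# Cochran's Q by an explicit term-by-term loop.
oracle_q <- function(dat, beta_pool) {
  q <- 0
  for (j in seq_len(nrow(dat))) {
    w <- dat$beta_exp[j]^2 / dat$se_out[j]^2
    q <- q + w * (dat$beta_out[j] / dat$beta_exp[j] - beta_pool)^2
  }
  q
}

# Weighted median by scanning the interpolated cumulative-weight function on
# a dense grid of ratio values.
oracle_weighted_median <- function(ratio, weight, n_grid = 2e5) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- cumsum(w) - w / 2
  grid <- seq(min(r), max(r), length.out = n_grid)
  sv <- stats::approx(r, s, xout = grid, rule = 2, ties = "ordered")$y
  grid[which.min(abs(sv - 0.5))]
}

# Greedy clumping re-implemented with set bookkeeping over the sorted list.
oracle_clump <- function(df, R, r2_thr, window_bp) {
  ord <- df$rsid[order(df$pval, df$rsid)]
  remaining <- ord
  selected <- character(0)
  while (length(remaining)) {
    idx <- remaining[1]
    selected <- c(selected, idx)
    remaining <- remaining[-1]
    if (!length(remaining)) break
    pos_i <- df$pos[df$rsid == idx]
    prune <- vapply(remaining, function(r) {
      close_by <- abs(df$pos[df$rsid == r] - pos_i) <= window_bp
      r2 <- if (idx %in% rownames(R) && r %in% rownames(R)) R[idx, r]^2 else 0
      close_by && r2 >= r2_thr
    }, logical(1))
    remaining <- remaining[!prune]
  }
  selected
}

# Random instrument table under a homogeneous causal effect.
random_dat <- function(n, beta = 0.3, seed = 1) {
  set.seed(seed)
  be <- stats::runif(n, 0.05, 0.3) * sample(c(-1, 1), n, replace = TRUE)
  se_out <- stats::runif(n, 0.005, 0.02)
  data.frame(rsid = paste0("s", seq_len(n)), beta_exp = be,
             se_exp = stats::runif(n, 0.005, 0.02),
             beta_out = beta * be + stats::rnorm(n, 0, se_out),
             se_out = se_out, stringsAsFactors = FALSE)
}

# Small well-formed sumstats data frame for I/O tests.
toy_sumstats <- function() {
  data.frame(rsid = c("rs1", "rs2", "rs3"), chrom = "1", pos = c(1000, 2000, 3000),
             effect_allele = c("A", "C", "T"), other_allele = c("G", "T", "C"),
             eaf = c(0.3, NA, 0.45), beta = c(0.1, -0.05, 0.02),
             se = c(0.01, 0.02, 0.015), pval = c(1e-10, 0.01, 0.2),
             n = c(10000, 10000, 10000), stringsAsFactors = FALSE)
}
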