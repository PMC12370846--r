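# Causal-effect estimators for two-sample summary-data MR. All operate on an
# instrument table: a data frame with columns beta_exp, se_exp, beta_out,
# se_out (rsid optional), one row per harmonized instrument. Estimates are on
# the outcome scale (log-odds for binary outcomes); odds ratios are exp().

mr_result <- function(method, nsnp, beta, se, ci_mult = Z95, pval = NULL) {
  ci_low <- beta - ci_mult * se
  ci_high <- beta + ci_mult * se
  if (is.null(pval)) pval <- p_normal(beta, se)
  data.frame(method = method, nsnp = as.integer(nsnp), beta = beta, se = se,
             ci_low = ci_low, ci_high = ci_high, pval = pval,
             odds_ratio = exp(beta), or_ci_low = exp(ci_low),
             or_ci_high = exp(ci_high), stringsAsFactors = FALSE)
}

check_dat <- function(dat, min_n = 1L, caller = "estimator") {
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  stopifnot(all(need %in% names(dat)))
  if (nrow(dat) < min_n)
    stop(sprintf("%s: needs at least %d instruments, got %d", caller, min_n, nrow(dat)))
  if (any(dat$se_out <= 0) || any(dat$se_exp <= 0))
    stop(sprintf("%s: standard errors must be positive", caller))
  invisible(dat)
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_out / beta_exp`, first-order SE `se_out / |beta_exp|`
#' (uncertainty in the exposure effect ignored, the usual leading-order
#' approximation), normal 95% CI and two-sided p.
#'
#' @param beta_exp,se_exp,beta_out,se_out the harmonized effect pair.
#' @param rsid optional identifier carried into the result.
#' @return one-row MR result data frame (`method = "wald_ratio"`).
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, rsid = NULL) {
  if (beta_exp == 0) stop("wald_ratio: beta_exp is zero, ratio undefined")
  res <- mr_result("wald_ratio", 1L, beta_out / beta_exp, se_out / abs(beta_exp))
  if (!is.null(rsid)) res$rsid <- rsid
  res
}

# Fixed-effect IVW core: returns list(beta, se_fixed, q). Weighted regression
# of beta_out on beta_exp through the origin, weights 1/se_out^2; Q is the
# weighted RSS, identical to Cochran's Q over Wald ratios.
ivw_core <- function(dat) {
  w <- 1 / dat$se_out^2
  sxx <- sum(w * dat$beta_exp^2)
  beta <- sum(w * dat$beta_exp * dat$beta_out) / sxx
  q <- sum(w * (dat$beta_out - beta * dat$beta_exp)^2)
  list(beta = beta, se_fixed = 1 / sqrt(sxx), q = q)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome on exposure effects through the origin with
#' weights `1/se_out^2`; equivalently the inverse-variance-weighted mean of
#' per-SNP Wald ratios with weights `beta_exp^2/se_out^2`. Under the
#' multiplicative random-effects model (the headline default) the fixed SE is
#' inflated by `max(1, sqrt(Q/(nsnp-1)))`, never deflated.
#'
#' @param dat instrument table.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return one-row MR result data frame; attribute `q` carries Cochran's Q.
#' @export
mr_ivw <- function(dat, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  check_dat(dat, 1L, "mr_ivw")
  core <- ivw_core(dat)
  n <- nrow(dat)
  se <- core$se_fixed
  method <- "ivw_fixed"
  if (effects_model == "multiplicative_random") {
    method <- "ivw_mre"
    if (n >= 2) se <- se * max(1, sqrt(core$q / (n - 1)))
  }
  structure(mr_result(method, n, core$beta, se), q = core$q)
}

#' MR-Egger regression
#'
#' Instruments are first oriented so every `beta_exp >= 0` (both members of a
#' pair negated where needed); then outcome effects are regressed on exposure
#' effects with an intercept, weights `1/se_out^2`. A nonzero intercept
#' indicates directional horizontal pleiotropy. SEs use the fixed-effect
#' (unit residual variance) form inflated by `max(1, sigma)` with
#' `sigma^2 = RSS/(nsnp-2)`; p-values and the 95% CI use the t distribution
#' with `nsnp - 2` degrees of freedom.
#'
#' @param dat instrument table with at least 3 rows.
#' @return list with `slope` (one-row MR result, `method = "egger"`) and
#'   `intercept` (data frame: estimate, se, pval).
#' @export
mr_egger <- function(dat) {
  check_dat(dat, 3L, "mr_egger")
  n <- nrow(dat)
  flip <- dat$beta_exp < 0
  x <- abs(dat$beta_exp)
  y <- ifelse(flip, -dat$beta_out, dat$beta_out)
  w <- 1 / dat$se_out^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - swx^2
  if (det <= 0) stop("mr_egger: degenerate design (no spread in beta_exp)")
  slope <- (sw * sxy - swx * swy) / det
  inter <- (swy * sxx - swx * sxy) / det
  rss <- sum(w * (y - inter - slope * x)^2)
  sigma <- sqrt(max(rss, 0) / (n - 2))
  infl <- max(1, sigma)
  se_slope <- sqrt(sw / det) * infl
  se_inter <- sqrt(sxx / det) * infl
  tmult <- stats::qt(0.975, df = n - 2)
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = n - 2)
  p_inter <- 2 * stats::pt(-abs(inter / se_inter), df = n - 2)
  list(
    slope = mr_result("egger", n, slope, se_slope, ci_mult = tmult,
                      pval = max(p_slope, .Machine$double.xmin)),
    intercept = data.frame(estimate = inter, se = se_inter,
                           pval = max(p_inter, .Machine$double.xmin))
  )
}

# Weighted-median point estimate given ratios and (unnormalized) weights:
# sort, form cumulative weight midpoints, linearly interpolate at 0.5.
weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  ratio <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- cumsum(w) - w / 2
  if (length(ratio) == 1L) return(ratio)
  stats::approx(s, ratio, xout = 0.5, rule = 2, ties = "ordered")$y
}

# Parametric bootstrap SE shared by median/mode: resample effect pairs from
# normals at the observed values, recompute the point estimate.
boot_se <- function(dat, point_fun, n_boot, seed) {
  if (n_boot < 1L) return(NA_real_)
  n <- nrow(dat)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      be <- stats::rnorm(n, dat$beta_exp, dat$se_exp)
      bo <- stats::rnorm(n, dat$beta_out, dat$se_out)
      point_fun(be, bo)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median estimate
#'
#' Per-SNP Wald ratios weighted by `beta_exp^2/se_out^2` (normalized); the
#' estimate is the 50% point of the interpolated cumulative weight function,
#' consistent when at least half the weight comes from valid instruments.
#' SE by parametric bootstrap (seeded, default 1000 replicates); `n_boot = 0`
#' skips the bootstrap (SE and p reported as NA).
#'
#' @param dat instrument table with at least 3 rows.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return one-row MR result data frame (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = 1) {
  check_dat(dat, 3L, "mr_weighted_median")
  if (any(dat$beta_exp == 0)) stop("mr_weighted_median: zero beta_exp")
  ratio <- dat$beta_out / dat$beta_exp
  weight <- dat$beta_exp^2 / dat$se_out^2
  est <- weighted_median_point(ratio, weight)
  se <- boot_se(dat, function(be, bo) {
    if (any(be == 0)) be[be == 0] <- .Machine$double.eps
    weighted_median_point(bo / be, be^2 / dat$se_out^2)
  }, n_boot, seed)
  if (is.na(se) || se == 0) {
    res <- mr_result("weighted_median", nrow(dat), est, 1)
    res$se <- se; res$ci_low <- res$ci_high <- est
    res$pval <- if (!is.na(se)) 0 else NA_real_
    if (is.na(se)) res$ci_low <- res$ci_high <- NA_real_
    return(res)
  }
  mr_result("weighted_median", nrow(dat), est, se)
}

# Weighted kernel-density mode on a fixed 512-point grid; ties -> lowest
# grid value. h = 0 (all ratios identical) returns that common value.
mode_point <- function(ratio, weight, phi) {
  n <- length(ratio)
  s <- stats::sd(ratio)
  iqr <- stats::IQR(ratio) / 1.34
  spread <- min(s, iqr)
  if (spread == 0) spread <- s   # tied quartiles but non-identical ratios
  h <- phi * 0.9 * spread * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(ratio[1])
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g)
    sum(weight * stats::dnorm((g - ratio) / h)), numeric(1))
  grid[which.max(dens)]
}

#' Simple- and weighted-mode estimates
#'
#' Per-SNP ratios are smoothed with a Gaussian kernel (bandwidth
#' `phi * 0.9 * min(sd, IQR/1.34) * n^(-1/5)`) over a fixed 512-point grid
#' spanning `[min - 3h, max + 3h]`; the estimate is the grid argmax (ties
#' resolved to the lowest grid value). The simple mode weights ratios
#' equally; the weighted mode weights them by `1/se(ratio)^2` with
#' `se(ratio) = se_out/|beta_exp|`. SEs by seeded parametric bootstrap.
#'
#' @param dat instrument table with at least 3 rows.
#' @param phi bandwidth multiplier (default 1; precision/smoothness knob).
#' @param n_boot,seed bootstrap settings as in [mr_weighted_median()].
#' @return list with `simple_mode` and `weighted_mode` one-row MR results.
#' @export
mr_mode <- function(dat, phi = 1, n_boot = 1000, seed = 1) {
  check_dat(dat, 3L, "mr_mode")
  if (any(dat$beta_exp == 0)) stop("mr_mode: zero beta_exp")
  ratio <- dat$beta_out / dat$beta_exp
  se_ratio <- dat$se_out / abs(dat$beta_exp)
  wts <- 1 / se_ratio^2
  n <- nrow(dat)
  one <- function(method, weight) {
    est <- mode_point(ratio, weight, phi)
    pfun <- if (identical(weight, wts))
      function(be, bo) mode_point(bo / be, be^2 / dat$se_out^2, phi)
    else
      function(be, bo) mode_point(bo / be, rep(1, n), phi)
    se <- boot_se(dat, function(be, bo) {
      if (any(be == 0)) be[be == 0] <- .Machine$double.eps
      pfun(be, bo)
    }, n_boot, seed)
    if (is.na(se) || se == 0) {
      res <- mr_result(method, n, est, 1)
      res$se <- se; res$ci_low <- res$ci_high <- est
      res$pval <- if (!is.na(se)) 0 else NA_real_
      if (is.na(se)) res$ci_low <- res$ci_high <- NA_real_
      return(res)
    }
    mr_result(method, n, est, se)
  }
  list(simple_mode = one("simple_mode", rep(1, n)),
       weighted_mode = one("weighted_mode", wts))
}

#' Run the full estimator battery
#'
#' IVW multiplicative random effects (headline) and fixed effects, MR-Egger
#' (when `nsnp >= 3`), weighted median, and both modes; a single instrument
#' reduces to the Wald ratio.
#'
#' @param dat instrument table.
#' @param n_boot,seed bootstrap settings for median/mode SEs (`n_boot = 0`
#'   reports point estimates with NA SEs — useful in large simulations).
#' @param phi mode bandwidth multiplier.
#' @return data frame, one row per method; attributes `egger_intercept`
#'   (data frame or NULL) and `q` (Cochran's Q from IVW).
#' @export
mr_all <- function(dat, n_boot = 1000, seed = 1, phi = 1) {
  check_dat(dat, 1L, "mr_all")
  if (nrow(dat) == 1L) {
    res <- wald_ratio(dat$beta_exp, dat$se_exp, dat$beta_out, dat$se_out,
                      rsid = dat$rsid %||% NULL)
    res$rsid <- NULL
    ivw <- mr_ivw(dat)
    return(structure(rbind(res, ivw), egger_intercept = NULL, q = attr(ivw, "q")))
  }
  ivw_mre <- mr_ivw(dat, "multiplicative_random")
  out <- rbind(ivw_mre, mr_ivw(dat, "fixed"))
  egger_int <- NULL
  if (nrow(dat) >= 3) {
    eg <- mr_egger(dat)
    egger_int <- eg$intercept
    md <- mr_mode(dat, phi = phi, n_boot = n_boot, seed = child_seed(seed, 2))
    out <- rbind(out, eg$slope,
                 mr_weighted_median(dat, n_boot, child_seed(seed, 1)),
                 md$weighted_mode, md$simple_mode)
  }
  rownames(out) <- NULL
  structure(out, egger_intercept = egger_int, q = attr(ivw_mre, "q"))
}

#' Write an MR results table as tab-separated text
#' @param results data frame from [mr_all()] (or rbind of such).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
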