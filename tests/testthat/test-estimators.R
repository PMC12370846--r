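# The five causal estimators against closed-form oracles and exact
# reductions.

test_that("wald_ratio is the guarded outcome/exposure ratio", {
  r <- wald_ratio(0.5, 0.01, 0.1, 0.05)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.1)
  expect_equal(r$ci_low, 0.2 - 1.959964 * 0.1)
  expect_equal(r$odds_ratio, exp(0.2))
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "zero")
})

test_that("IVW equals the WLS-through-origin oracle on seeded fixtures", {
  for (seed in 1:20) {
    dat <- random_dat(sample(3:12, 1), beta = runif(1, -0.5, 0.5), seed = seed)
    want <- oracle_ivw(dat)
    fixed <- mr_ivw(dat, "fixed")
    expect_equal(fixed$beta, want$beta, tolerance = 1e-10)
    expect_equal(fixed$se, want$se_fixed, tolerance = 1e-10)
    mre <- mr_ivw(dat, "multiplicative_random")
    expect_equal(mre$beta, want$beta, tolerance = 1e-10)
    expect_equal(mre$se, want$se_fixed * max(1, want$sigma), tolerance = 1e-10)
  }
})

test_that("IVW reduces to the Wald ratio for one SNP and to the ratio value
           for homogeneous data", {
  dat1 <- data.frame(beta_exp = 0.2, se_exp = 0.01, beta_out = 0.05, se_out = 0.02)
  expect_equal(mr_ivw(dat1, "fixed")$beta,
               wald_ratio(0.2, 0.01, 0.05, 0.02)$beta)
  expect_equal(mr_ivw(dat1, "fixed")$se, wald_ratio(0.2, 0.01, 0.05, 0.02)$se)

  be <- c(0.1, 0.2, 0.3)
  dat <- data.frame(beta_exp = be, se_exp = 0.01, beta_out = 0.3 * be,
                    se_out = c(0.01, 0.02, 0.03))
  mre <- mr_ivw(dat)
  expect_equal(mre$beta, 0.3, tolerance = 1e-12)
  expect_equal(attr(mre, "q"), 0, tolerance = 1e-20)  # zero heterogeneity
  expect_equal(mre$se, mr_ivw(dat, "fixed")$se)       # scale factor floored at 1
})

test_that("IVW-fixed equals the weighted mean of Wald ratios (identity)", {
  for (seed in 1:5) {
    dat <- random_dat(8, seed = seed)
    ratio <- dat$beta_out / dat$beta_exp
    w <- dat$beta_exp^2 / dat$se_out^2
    expect_equal(mr_ivw(dat, "fixed")$beta, sum(w * ratio) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("MR-Egger recovers exact affine data and matches the lm oracle", {
  aff <- make_fixture("egger_affine")
  eg <- mr_egger(aff)
  expect_equal(eg$intercept$estimate, 0.01, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-12)

  expect_error(mr_egger(random_dat(2)), "at least 3")

  for (seed in 1:20) {
    dat <- random_dat(sample(4:12, 1), seed = seed + 100)
    want <- oracle_egger(dat)
    got <- mr_egger(dat)
    expect_equal(got$slope$beta, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept$estimate, want$intercept, tolerance = 1e-10)
    expect_equal(got$slope$se, want$se_slope, tolerance = 1e-10)
    expect_equal(got$intercept$se, want$se_intercept, tolerance = 1e-10)
  }
})

test_that("Egger orientation makes the fit invariant to per-SNP sign flips", {
  dat <- random_dat(8, seed = 5)
  flip <- c(1, -1, 1, -1, -1, 1, 1, -1)
  dat2 <- dat
  dat2$beta_exp <- dat$beta_exp * flip
  dat2$beta_out <- dat$beta_out * flip
  expect_equal(mr_egger(dat2)$slope$beta, mr_egger(dat)$slope$beta)
  expect_equal(mr_egger(dat2)$intercept$estimate, mr_egger(dat)$intercept$estimate)
})

test_that("weighted median: equal-weight median, scan oracle, degenerate case", {
  dat <- data.frame(beta_exp = c(1, 1, 1), se_exp = 0.01,
                    beta_out = c(0.1, 0.2, 0.9), se_out = 0.05)
  expect_equal(mr_weighted_median(dat, n_boot = 0)$beta, 0.2)

  be <- c(0.1, 0.2, 0.15)
  dat2 <- data.frame(beta_exp = be, se_exp = 0.01, beta_out = 0.4 * be,
                     se_out = 0.02)
  wm <- mr_weighted_median(dat2, n_boot = 200, seed = 3)
  expect_equal(wm$beta, 0.4, tolerance = 1e-12)

  d7 <- make_fixture("median_seven")
  got <- mr_weighted_median(d7, n_boot = 0)$beta
  want <- oracle_weighted_median(d7$beta_out / d7$beta_exp,
                                 d7$beta_exp^2 / d7$se_out^2)
  expect_equal(got, want, tolerance = 1e-4)  # grid-scan oracle resolution
  expect_error(mr_weighted_median(random_dat(2), n_boot = 0), "at least 3")
})

test_that("mode estimators find the majority cluster and handle degeneracy", {
  be <- rep(0.2, 4)
  dat <- data.frame(beta_exp = c(be, 0.2), se_exp = 0.01,
                    beta_out = c(0.1 * be, 0.9 * 0.2), se_out = 0.002)
  modes <- mr_mode(dat, n_boot = 0)
  expect_lt(abs(modes$simple_mode$beta - 0.1), 0.05)
  expect_lt(abs(modes$weighted_mode$beta - 0.1), 0.05)

  # direct density-evaluation check of the grid argmax (IQR of the 4-vs-1
  # cluster is 0, so the bandwidth falls back to the sd)
  ratio <- dat$beta_out / dat$beta_exp
  h <- 0.9 * sd(ratio) * 5^(-1 / 5)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g) sum(dnorm((g - ratio) / h)), numeric(1))
  expect_equal(modes$simple_mode$beta, grid[which.max(dens)])

  dg <- data.frame(beta_exp = c(0.1, 0.2, 0.4), se_exp = 0.01,
                   beta_out = 0.25 * c(0.1, 0.2, 0.4), se_out = 0.01)
  md <- mr_mode(dg, n_boot = 0)
  expect_equal(md$simple_mode$beta, 0.25)   # zero bandwidth -> common ratio
  expect_equal(md$weighted_mode$beta, 0.25)
})

test_that("stochastic estimators are reproducible from their seed", {
  dat <- random_dat(7, seed = 9)
  a <- mr_weighted_median(dat, n_boot = 100, seed = 11)
  b <- mr_weighted_median(dat, n_boot = 100, seed = 11)
  expect_identical(a, b)
  c1 <- mr_mode(dat, n_boot = 50, seed = 12)
  c2 <- mr_mode(dat, n_boot = 50, seed = 12)
  expect_identical(c1, c2)
  expect_false(identical(a$se, mr_weighted_median(dat, n_boot = 100, seed = 13)$se))
})

test_that("estimators are scale- and sign-equivariant in the outcome", {
  dat <- random_dat(9, seed = 21)
  for (c_mult in c(0.5, 3)) {
    sc <- dat
    sc$beta_out <- dat$beta_out * c_mult
    sc$se_out <- dat$se_out * c_mult
    expect_equal(mr_ivw(sc)$beta, c_mult * mr_ivw(dat)$beta, tolerance = 1e-12)
    expect_equal(mr_ivw(sc)$se, c_mult * mr_ivw(dat)$se, tolerance = 1e-12)
    expect_equal(mr_egger(sc)$slope$beta, c_mult * mr_egger(dat)$slope$beta,
                 tolerance = 1e-12)
    expect_equal(mr_weighted_median(sc, n_boot = 0)$beta,
                 c_mult * mr_weighted_median(dat, n_boot = 0)$beta,
                 tolerance = 1e-10)
  }
  ng <- dat; ng$beta_out <- -dat$beta_out
  expect_equal(mr_ivw(ng)$beta, -mr_ivw(dat)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(ng, n_boot = 0)$beta,
               -mr_weighted_median(dat, n_boot = 0)$beta, tolerance = 1e-10)
})

test_that("mr_all bundles methods with OR/CI invariants intact", {
  res <- mr_all(make_fixture("ivw_basic"), n_boot = 50, seed = 4)
  expect_setequal(res$method, c("ivw_mre", "ivw_fixed", "egger",
                                "weighted_median", "weighted_mode", "simple_mode"))
  expect_equal(res$odds_ratio, exp(res$beta))
  expect_equal(res$or_ci_low, exp(res$ci_low))
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
  expect_true(all(res$pval > 0 & res$pval <= 1))
  expect_s3_class(attr(res, "egger_intercept"), "data.frame")

  one <- mr_all(random_dat(1, seed = 2), n_boot = 0)
  expect_true("wald_ratio" %in% one$method)
})
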