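# Instrument selection: significance, MAF, clumping, strength, F filter.

test_that("filter_significance uses a strict threshold and preserves order", {
  d <- toy_sumstats()
  d$pval <- c(1e-9, 1e-7, 5e-8)
  ds <- summary_dataset(d, "t")
  out <- filter_significance(ds, 5e-8)
  expect_equal(out$data$rsid, "rs1")
  d$pval <- rep(0.5, 3)
  expect_equal(n_variants(filter_significance(summary_dataset(d, "t"))), 0)

  set.seed(7)
  n <- 100
  d2 <- toy_sumstats()[rep(1, n), ]
  d2$rsid <- paste0("rs", 1:n)
  d2$pval <- 10^runif(n, -12, 0)
  ds2 <- summary_dataset(d2, "t")
  out2 <- filter_significance(ds2)
  expect_equal(out2$data$rsid, d2$rsid[d2$pval < 5e-8])
})

test_that("filter_maf drops both rare-allele tails, keeps missing eaf", {
  d <- toy_sumstats()[rep(1, 4), ]
  d$rsid <- paste0("rs", 1:4)
  d$eaf <- c(0.005, 0.995, 0.30, NA)
  ds <- summary_dataset(d, "t")
  expect_warning(out <- filter_maf(ds), "missing EAF")
  expect_setequal(out$data$rsid, c("rs3", "rs4"))
})

test_that("clump retains independent SNPs and prunes by p-value priority", {
  d <- toy_sumstats()
  ld0 <- ld_matrix(d$rsid, diag(3), d$pos)
  ds <- summary_dataset(d, "t")
  expect_equal(n_variants(clump(ds, ld0)), 3)

  # two correlated co-local SNPs: the smaller p survives
  d2 <- toy_sumstats()[1:2, ]
  d2$pval <- c(1e-9, 1e-10)
  r <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2)
  ld2 <- ld_matrix(d2$rsid, r, d2$pos)
  out <- clump(summary_dataset(d2, "t"), ld2, r2_threshold = 0.4)
  expect_equal(out$data$rsid, "rs2")

  # ...but not when they are farther apart than the window
  d3 <- d2; d3$pos <- c(0, 2e7)
  ld3 <- ld_matrix(d3$rsid, r, d3$pos)
  expect_equal(n_variants(clump(summary_dataset(d3, "t"), ld3, r2_threshold = 0.4)), 2)
})

test_that("clump matches the brute-force greedy oracle on chained LD blocks", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 10
    # AR1-style chained correlations within one locus
    rho <- runif(1, 0.3, 0.95)
    R <- rho^abs(outer(1:n, 1:n, "-"))
    rsids <- paste0("rs", sprintf("%02d", 1:n))
    pos <- sort(sample.int(5e4, n))
    d <- data.frame(rsid = rsids, chrom = "1", pos = pos,
                    effect_allele = "A", other_allele = "G",
                    eaf = runif(n, 0.1, 0.9), beta = rnorm(n, 0, 0.1),
                    se = 0.01, pval = 10^runif(n, -12, -2), n = 1e4)
    ld <- ld_matrix(rsids, R, pos)
    thr <- runif(1, 0.05, 0.6)
    got <- clump(summary_dataset(d, "t"), ld, r2_threshold = thr, window_kb = 30)
    want <- oracle_clump(d, ld$r, thr, 30 * 1000)
    expect_setequal(got$data$rsid, want)

    # idempotence and pairwise independence of the output
    again <- clump(got, ld, r2_threshold = thr, window_kb = 30)
    expect_equal(again$data$rsid, got$data$rsid)
    keep <- got$data$rsid
    if (length(keep) > 1) {
      for (i in seq_along(keep)) for (j in seq_len(i - 1)) {
        far <- abs(ld$positions[keep[i]] - ld$positions[keep[j]]) > 30 * 1000
        weak <- ld$r[keep[i], keep[j]]^2 < thr
        expect_true(far || weak)
      }
    }
  }
})

test_that("clump tie-breaks equal p-values by rsid and honors missing_ld", {
  d <- toy_sumstats()[1:2, ]
  d$pval <- c(1e-9, 1e-9)
  r <- matrix(c(1, 0.9, 0.9, 1), 2)
  ld <- ld_matrix(d$rsid, r, d$pos)
  out <- clump(summary_dataset(d, "t"), ld, r2_threshold = 0.5)
  expect_equal(out$data$rsid, "rs1")   # lexicographically first wins the tie

  ld1 <- ld_matrix("rs1", matrix(1), 1000)
  expect_equal(n_variants(clump(summary_dataset(d, "t"), ld1, r2_threshold = 0.5)), 2)
  expect_equal(
    clump(summary_dataset(d, "t"), ld1, r2_threshold = 0.5,
          missing_ld = "drop")$data$rsid, "rs1")
})

test_that("instrument_strength reproduces the printed-formula arithmetic", {
  st <- instrument_strength(beta = 0.1, se = 0.01, n = 1e4, eaf = 0.3, k = 1)
  # R2 = 0.01/(0.01 + 1e4 * 1e-4) = 0.01/1.01; F = R2/(1-R2) * (N-2) = 99.98
  expect_equal(unname(st["r2"]), 0.01 / 1.01, tolerance = 1e-12)
  expect_equal(unname(st["f_stat"]), 99.98, tolerance = 1e-10)

  expect_equal(instrument_strength(0, 0.01, 1e4, 0.3),
               c(r2 = 0, f_stat = 0))
  # the 2 EAF (1-EAF) factor cancels: R2 invariant to EAF
  expect_equal(instrument_strength(0.1, 0.01, 1e4, 0.3),
               instrument_strength(0.1, 0.01, 1e4, 0.4))
  expect_error(instrument_strength(0.1, 0.01, 1e4, NA), "EAF")
  expect_error(instrument_strength(0.1, 0.01, 2, 0.3), "n > k")
})

test_that("F is monotone in |beta| and in 1/SE", {
  f <- function(b, s) unname(instrument_strength(b, s, 1e4, 0.3)["f_stat"])
  betas <- seq(0.02, 0.3, by = 0.02)
  expect_true(all(diff(vapply(betas, f, numeric(1), s = 0.01)) > 0))
  ses <- seq(0.005, 0.05, by = 0.005)
  expect_true(all(diff(vapply(ses, function(s) f(0.1, s), numeric(1))) < 0))
})

test_that("filter_f excludes F < 20 strictly", {
  ins <- data.frame(rsid = c("a", "b", "c"), f_stat = c(19.99, 20, 25))
  out <- filter_f(ins)
  expect_setequal(out$rsid, c("b", "c"))   # F = 20 retained
  expect_equal(attr(out, "n_excluded"), 1L)
})

test_that("select_instruments keeps strong instruments end-to-end", {
  st <- simulate_study(sim_config(seed = 3, n_variants = 100, n_blocks = 20,
                                  n_instruments = 10, n_med_instruments = 0,
                                  effect_sd = 0.1, n_exp = 5e4))
  sel <- select_instruments(st$exposure, st$ld)
  expect_gt(n_variants(sel), 0)
  expect_true(all(attr(sel, "strength")$f_stat >= 20))
  expect_true(all(attr(sel, "strength")$r2 >= 0 & attr(sel, "strength")$r2 < 1))
})
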