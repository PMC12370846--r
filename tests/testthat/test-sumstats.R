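# Data model, I/O round-trips, and harmonization rules.

test_that("read_sumstats ingests well-formed tables and audits bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ds0 <- summary_dataset(toy_sumstats(), "t1")
  write_sumstats(ds0, path)
  ds <- read_sumstats(path, trait_id = "t1")
  expect_equal(n_variants(ds), 3)
  expect_equal(sum(attr(ds, "audit")), 0)

  # se = 0 row is skipped and counted; empty eaf is missing, not zero
  bad <- toy_sumstats()
  bad$se[2] <- 0
  writeLines(c("SNP\tEA\tOA\tEAF\tBETA\tSE\tP",
               "rs1\tA\tG\t0.3\t0.1\t0.01\t1e-5",
               "rs2\tA\tG\t\t0.1\t0\t1e-5",
               "rs3\tA\tG\t\t0.1\t0.01\t1e-5"), path)
  ds <- read_sumstats(path, trait_id = "t2")
  expect_equal(n_variants(ds), 2)
  expect_equal(unname(attr(ds, "audit")["bad_se"]), 1L)
  expect_true(is.na(ds$data$eaf[ds$data$rsid == "rs3"]))
  expect_false(any(ds$data$eaf %in% 0))
})

test_that("read_sumstats maps arbitrary source headers via column_map", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsids\tref\talt\taf_alt\tbeta\tsebeta\tpval\tnum",
               "rs1\tG\tA\t0.3\t0.12\t0.01\t1e-9\t5000"), path)
  ds <- read_sumstats(path, column_map = c(
    SNP = "rsids", OA = "ref", EA = "alt", EAF = "af_alt", BETA = "beta",
    SE = "sebeta", P = "pval", N = "num"), trait_id = "finngen_style")
  expect_equal(ds$data$effect_allele, "A")
  expect_equal(ds$data$beta, 0.12)
  expect_error(read_sumstats(path, trait_id = "x"), "mandatory")
})

test_that("write/read round-trips preserve every field including missing eaf", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ds0 <- summary_dataset(toy_sumstats(), "t1")
  write_sumstats(ds0, path)
  ds1 <- read_sumstats(path, trait_id = "t1")
  expect_equal(ds1$data, ds0$data)

  empty <- summary_dataset(toy_sumstats()[0, ], "t0")
  write_sumstats(empty, path)
  expect_length(readLines(path), 1)   # header only
  three <- summary_dataset(toy_sumstats(), "t3")
  write_sumstats(three, path)
  expect_length(readLines(path), 4)
})

test_that("summary_dataset enforces variant invariants", {
  d <- toy_sumstats()
  d$effect_allele[1] <- "G"   # equals other allele
  d$pval[2] <- 0
  ds <- summary_dataset(d, "t")
  expect_equal(n_variants(ds), 1)
  au <- attr(ds, "audit")
  expect_equal(unname(au["bad_allele"]), 1L)
  expect_equal(unname(au["bad_pval"]), 1L)
  # duplicate rsids collapse
  d2 <- rbind(toy_sumstats(), toy_sumstats())
  expect_equal(n_variants(summary_dataset(d2, "t")), 3)
})

make_pair <- function(exp_rows, out_rows) {
  list(exposure = summary_dataset(exp_rows, "exp"),
       outcome = summary_dataset(out_rows, "out"))
}

test_that("harmonize applies swap, complement, palindrome, incompatible rules", {
  e <- data.frame(rsid = c("r1", "r2", "r3", "r4", "r5", "r6"),
                  effect_allele = c("A", "A", "A", "A", "A", "A"),
                  other_allele = c("G", "G", "G", "T", "T", "T"),
                  eaf = c(0.3, 0.3, 0.3, 0.10, 0.10, 0.10),
                  beta = 0.10, se = 0.01, pval = 1e-10, n = 1e4)
  o <- data.frame(rsid = c("r1", "r2", "r3", "r4", "r5", "r6"),
                  effect_allele = c("G", "A", "T", "A", "A", "A"),
                  other_allele = c("A", "C", "C", "T", "T", "T"),
                  eaf = c(0.70, 0.30, 0.30, 0.88, 0.12, NA),
                  beta = 0.05, se = 0.01, pval = 1e-4, n = 1e5)
  p <- make_pair(e, o)
  h <- harmonize(p$exposure, p$outcome)
  pr <- h$pairs

  # r1: EA/OA swapped -> flipped, beta negated, eaf reflected
  expect_equal(pr$action[pr$rsid == "r1"], "flipped")
  expect_equal(pr$beta_out[pr$rsid == "r1"], -0.05)
  expect_equal(pr$eaf_out[pr$rsid == "r1"], 0.30)
  # r2: A/G vs A/C -> incompatible
  expect_equal(pr$action[pr$rsid == "r2"], "dropped")
  expect_equal(pr$drop_reason[pr$rsid == "r2"], "incompatible")
  # r3: T/C complements to A/G -> kept without flip
  expect_equal(pr$action[pr$rsid == "r3"], "kept")
  expect_equal(pr$beta_out[pr$rsid == "r3"], 0.05)
  # r4: palindromic, eafs on opposite sides of 0.5 -> flipped
  expect_equal(pr$action[pr$rsid == "r4"], "flipped")
  expect_equal(pr$beta_out[pr$rsid == "r4"], -0.05)
  expect_equal(pr$eaf_out[pr$rsid == "r4"], 0.12)
  # r5: palindromic, same side -> kept
  expect_equal(pr$action[pr$rsid == "r5"], "kept")
  # r6: palindromic without frequency -> dropped
  expect_equal(pr$drop_reason[pr$rsid == "r6"], "palindromic_no_freq")

  expect_equal(unname(h$audit["kept"] + h$audit["flipped"] + h$audit["dropped"]),
               unname(h$audit["n_intersection"]))
})

test_that("palindromic ambiguity window drops eaf near 0.5", {
  e <- data.frame(rsid = "r1", effect_allele = "C", other_allele = "G",
                  eaf = 0.44, beta = 0.1, se = 0.01, pval = 1e-9, n = 1e4)
  o <- data.frame(rsid = "r1", effect_allele = "C", other_allele = "G",
                  eaf = 0.30, beta = 0.05, se = 0.01, pval = 1e-3, n = 1e4)
  p <- make_pair(e, o)
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$pairs$drop_reason, "palindromic_ambiguous")
  # narrower window admits the same pair
  h2 <- harmonize(p$exposure, p$outcome, palindrome_window = 0.02)
  expect_equal(h2$pairs$action, "kept")
})

test_that("harmonize conservation and involution properties hold on random pairs", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 40
    pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "T"), c("C", "G"))
    pick <- pairs[sample(4, n, replace = TRUE), , drop = FALSE]
    e <- data.frame(rsid = paste0("r", 1:n), effect_allele = pick[, 1],
                    other_allele = pick[, 2], eaf = runif(n, 0.05, 0.95),
                    beta = rnorm(n, 0, 0.1), se = runif(n, 0.005, 0.02),
                    pval = runif(n), n = 1e4)
    swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
    o <- e
    o$beta <- rnorm(n, 0, 0.1); o$pval <- runif(n)
    o$effect_allele <- ifelse(swap, e$other_allele, e$effect_allele)
    o$other_allele <- ifelse(swap, e$effect_allele, e$other_allele)
    o$eaf <- ifelse(swap, 1 - e$eaf, e$eaf) + rnorm(n, 0, 0.01)
    o$eaf <- pmin(pmax(o$eaf, 0.01), 0.99)
    p <- make_pair(e, o)
    h <- harmonize(p$exposure, p$outcome)
    au <- h$audit
    expect_equal(unname(au["kept"] + au["flipped"] + au["dropped"]),
                 unname(au["n_intersection"]))

    # involution: swap outcome alleles, negate betas, reflect eaf -> same
    # retained set and identical final harmonized values
    o2 <- o
    o2$effect_allele <- o$other_allele; o2$other_allele <- o$effect_allele
    o2$beta <- -o$beta; o2$eaf <- 1 - o$eaf
    h2 <- harmonize(p$exposure, summary_dataset(o2, "out"))
    expect_equal(h2$pairs$action == "dropped", h$pairs$action == "dropped")
    keep <- h$pairs$action != "dropped"
    expect_equal(h2$pairs$beta_out[keep], h$pairs$beta_out[keep])
    expect_equal(h2$pairs$eaf_out[keep], h$pairs$eaf_out[keep])
  }
})

test_that("harmonize signals an empty rsid intersection", {
  e <- summary_dataset(toy_sumstats(), "exp")
  o0 <- toy_sumstats(); o0$rsid <- paste0("x", 1:3)
  o <- summary_dataset(o0, "out")
  expect_error(harmonize(e, o), "overlap")
})
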