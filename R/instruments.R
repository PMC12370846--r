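# Instrumental-variable selection: genome-wide significance screen, MAF
# filter, greedy LD clumping, and R^2/F instrument-strength filtering. All
# thresholds are strict inequalities as printed in the source conventions:
# retain p < 5e-8, MAF > 1%, independent when r^2 < 0.001, exclude F < 20.

#' Filter variants by p-value significance threshold
#'
#' @param dataset a [summary_dataset()].
#' @param p_threshold strict upper bound; variants with `pval < p_threshold`
#'   survive (default genome-wide significance 5e-8).
#' @return filtered [summary_dataset()], input order preserved.
#' @export
filter_significance <- function(dataset, p_threshold = 5e-8) {
  d <- dataset$data
  keep <- d$pval < p_threshold
  if (!any(keep)) log_info("%s: no variants at p < %g", dataset$trait_id, p_threshold)
  summary_dataset(d[keep, , drop = FALSE], dataset$trait_id, dataset$trait_type,
                  validate = FALSE)
}

#' Filter variants by minor allele frequency
#'
#' MAF is `min(eaf, 1 - eaf)`. Variants with missing EAF are retained with a
#' warning (frequency is only required for palindrome resolution and R^2).
#'
#' @param dataset a [summary_dataset()].
#' @param maf_min strict lower bound (default 0.01).
#' @return filtered [summary_dataset()].
#' @export
filter_maf <- function(dataset, maf_min = 0.01) {
  d <- dataset$data
  maf <- pmin(d$eaf, 1 - d$eaf)
  if (anyNA(maf))
    log_warn("filter_maf: %d variants with missing EAF retained", sum(is.na(maf)))
  keep <- is.na(maf) | maf > maf_min
  summary_dataset(d[keep, , drop = FALSE], dataset$trait_id, dataset$trait_type,
                  validate = FALSE)
}

#' Greedy LD clumping
#'
#' Sorts variants by ascending p-value (ties broken by rsid lexicographic
#' order for determinism), repeatedly promotes the best remaining variant to
#' an index SNP, and removes every remaining variant that lies within
#' `window_kb` of that index AND has `r^2 >= r2_threshold` with it. Index
#' SNPs form the output, in the dataset's original order.
#'
#' @param dataset a [summary_dataset()] with positions.
#' @param ld an [ld_matrix()] covering (a superset of) the dataset's rsids.
#' @param r2_threshold squared-correlation bound; pairs below it count as
#'   independent (default 0.001).
#' @param window_kb physical window in kilobases (default 10000); variants
#'   farther apart are never pruned regardless of LD.
#' @param missing_ld `"independent"` (default): SNPs absent from `ld` are
#'   assumed uncorrelated with everything (logged); `"drop"`: they are
#'   removed before clumping.
#' @return clumped [summary_dataset()].
#' @export
clump <- function(dataset, ld, r2_threshold = 0.001, window_kb = 10000,
                  missing_ld = c("independent", "drop")) {
  missing_ld <- match.arg(missing_ld)
  d <- dataset$data
  if (nrow(d) <= 1L) return(dataset)
  in_ld <- d$rsid %in% ld$rsids
  if (any(!in_ld)) {
    if (missing_ld == "drop") {
      log_info("clump: dropping %d SNPs absent from LD reference", sum(!in_ld))
      d <- d[in_ld, , drop = FALSE]
      in_ld <- rep(TRUE, nrow(d))
    } else {
      log_info("clump: %d SNPs absent from LD reference assumed independent",
               sum(!in_ld))
    }
  }
  ord <- order(d$pval, d$rsid)
  alive <- rep(TRUE, nrow(d))
  index <- logical(nrow(d))
  window_bp <- window_kb * 1000
  for (i in ord) {
    if (!alive[i]) next
    index[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (!length(cand)) break
    near <- abs(d$pos[cand] - d$pos[i]) <= window_bp
    if (d$rsid[i] %in% ld$rsids) {
      r2 <- ifelse(d$rsid[cand] %in% ld$rsids,
                   ld$r[d$rsid[i], ][d$rsid[cand]]^2, 0)
    } else r2 <- rep(0, length(cand))
    r2[is.na(r2)] <- 0
    alive[cand[near & r2 >= r2_threshold]] <- FALSE
  }
  summary_dataset(d[index, , drop = FALSE], dataset$trait_id, dataset$trait_type,
                  validate = FALSE)
}

#' Variance explained and F-statistic of one instrument
#'
#' R^2 = 2 EAF (1-EAF) b^2 / (2 EAF (1-EAF) b^2 + 2 EAF (1-EAF) N SE^2),
#' in which the 2 EAF (1-EAF) factor cancels, leaving b^2 / (b^2 + N SE^2);
#' F = R^2 (N - 1 - K) / (K (1 - R^2)).
#'
#' @param beta,se,n per-allele effect, its SE, and GWAS sample size.
#' @param eaf effect-allele frequency; required (the conventional formula is
#'   stated in terms of it) even though it cancels algebraically.
#' @param k number of instruments in the model (default 1: per-SNP F).
#' @return named numeric `c(r2 = , f_stat = )`.
#' @export
instrument_strength <- function(beta, se, n, eaf, k = 1) {
  if (any(is.na(eaf))) stop("instrument_strength: EAF required")
  if (any(!is.finite(n)) || any(n <= k + 1)) stop("instrument_strength: need n > k + 1")
  if (any(se <= 0)) stop("instrument_strength: se must be positive")
  r2 <- beta^2 / (beta^2 + n * se^2)
  f <- r2 * (n - 1 - k) / (k * (1 - r2))
  if (length(beta) == 1L) c(r2 = r2, f_stat = f)
  else data.frame(r2 = r2, f_stat = f)
}

#' Exclude weak instruments by F-statistic
#'
#' @param instruments data frame of harmonized instruments carrying an
#'   `f_stat` column (see [build_instruments()]).
#' @param f_min exclusion rule is `f_stat < f_min` (default 20), so
#'   `f_stat = f_min` is retained.
#' @return filtered data frame; attribute `n_excluded` records removals.
#' @export
filter_f <- function(instruments, f_min = 20) {
  stopifnot(!is.null(instruments$f_stat))
  keep <- instruments$f_stat >= f_min
  if (any(!keep))
    log_info("filter_f: excluded %d instruments with F < %g", sum(!keep), f_min)
  structure(instruments[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Select instruments from an exposure dataset
#'
#' The full per-exposure cascade: significance screen, MAF filter, LD
#' clumping (when an LD reference is supplied), per-SNP R^2/F annotation
#' (when EAF is available), and weak-instrument exclusion.
#'
#' @param dataset exposure [summary_dataset()].
#' @param ld optional [ld_matrix()]; `NULL` skips clumping.
#' @param p_threshold,maf_min,r2_threshold,window_kb,f_min thresholds, see the
#'   individual filters.
#' @param k instruments count for the F formula (per-SNP default 1).
#' @return [summary_dataset()] of selected instruments with an attribute
#'   `strength`: data frame `rsid`, `r2`, `f_stat` (also a joint-F summary
#'   attribute `joint_f` computed with K = number retained, informational).
#' @export
select_instruments <- function(dataset, ld = NULL, p_threshold = 5e-8,
                               maf_min = 0.01, r2_threshold = 0.001,
                               window_kb = 10000, f_min = 20, k = 1) {
  ds <- filter_significance(dataset, p_threshold)
  ds <- filter_maf(ds, maf_min)
  if (!is.null(ld) && n_variants(ds) > 1) ds <- clump(ds, ld, r2_threshold, window_kb)
  d <- ds$data
  if (!nrow(d)) return(structure(ds, strength = NULL))
  if (all(!is.na(d$eaf)) && all(!is.na(d$n))) {
    st <- instrument_strength(d$beta, d$se, d$n, d$eaf, k = k)
    st <- data.frame(rsid = d$rsid, st, stringsAsFactors = FALSE)
    keep <- st$f_stat >= f_min
    if (any(!keep))
      log_info("select_instruments: excluded %d weak instruments (F < %g)",
               sum(!keep), f_min)
    d <- d[keep, , drop = FALSE]; st <- st[keep, , drop = FALSE]
    kk <- nrow(d)
    joint_f <- if (kk > 0 && all(d$n > kk + 1)) {
      r2j <- sum(st$r2)
      r2j * (mean(d$n) - 1 - kk) / (kk * (1 - r2j))
    } else NA_real_
    out <- summary_dataset(d, ds$trait_id, ds$trait_type, validate = FALSE)
    structure(out, strength = st, joint_f = joint_f)
  } else {
    log_warn("select_instruments: EAF or N missing; F filter skipped")
    structure(ds, strength = NULL)
  }
}

#' Build a harmonized instrument table
#'
#' Convenience join of [select_instruments()] and [harmonize()]: selects
#' instruments on the exposure, harmonizes them against the outcome, and
#' returns the retained pairs annotated with per-SNP `r2` and `f_stat`.
#'
#' @inheritParams select_instruments
#' @param outcome outcome [summary_dataset()].
#' @param palindrome_window see [harmonize()].
#' @return data frame of instruments (columns of [harmonize()]'s `pairs`,
#'   retained rows only, plus `r2`/`f_stat` when available); attributes
#'   `audit` (harmonization counts) and `strength`.
#' @export
build_instruments <- function(dataset, outcome, ld = NULL, p_threshold = 5e-8,
                              maf_min = 0.01, r2_threshold = 0.001,
                              window_kb = 10000, f_min = 20,
                              palindrome_window = 0.08) {
  sel <- select_instruments(dataset, ld, p_threshold, maf_min, r2_threshold,
                            window_kb, f_min)
  if (!n_variants(sel)) {
    return(structure(data.frame(), audit = NULL, strength = NULL))
  }
  h <- harmonize(sel, outcome, palindrome_window)
  pairs <- harmonized_kept(h)
  st <- attr(sel, "strength")
  if (!is.null(st)) {
    idx <- match(pairs$rsid, st$rsid)
    pairs$r2 <- st$r2[idx]
    pairs$f_stat <- st$f_stat[idx]
  }
  structure(pairs, audit = h$audit, strength = st)
}
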