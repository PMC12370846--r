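# GWAS summary-statistics data model, delimited-text I/O, and exposure/outcome
# harmonization. One row per SNP: identifier, position, allele pair, effect
# allele frequency, per-allele effect with SE, p-value, sample size.

CANONICAL_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
MANDATORY_COLS <- c("SNP", "EA", "OA", "BETA", "SE", "P")
BASES <- c("A", "C", "G", "T")

#' Construct a summary dataset
#'
#' A `summary_dataset` is the container for one trait's GWAS summary
#' statistics: a data frame with columns `rsid`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, plus the
#' trait identifier and type. Rows violating the per-variant invariants
#' (single-base distinct alleles, `se > 0`, `pval` in (0, 1], `n >= 1`, `eaf`
#' in (0, 1) when present) are rejected.
#'
#' @param data data frame with the columns above (`chrom`, `pos`, `eaf`, `n`
#'   may be missing/NA; `eaf = NA` means unknown frequency, not zero).
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"` (binary traits carry
#'   log-odds scale betas).
#' @param validate reject invariant-violating rows (`TRUE`) or trust the
#'   caller (`FALSE`, internal fast path).
#' @return object of class `summary_dataset` with elements `trait_id`,
#'   `trait_type`, `data`, and an `audit` attribute counting skipped rows.
#' @export
summary_dataset <- function(data, trait_id, trait_type = c("quantitative", "binary"),
                            validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  need <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("summary_dataset: missing columns: ", paste(missing_cols, collapse = ", "))
  for (opt in c("chrom", "pos", "eaf", "n")) if (is.null(data[[opt]])) data[[opt]] <- NA
  data <- data.frame(
    rsid = as.character(data$rsid), chrom = as.character(data$chrom),
    pos = as.numeric(data$pos),
    effect_allele = toupper(as.character(data$effect_allele)),
    other_allele = toupper(as.character(data$other_allele)),
    eaf = as.numeric(data$eaf), beta = as.numeric(data$beta),
    se = as.numeric(data$se), pval = as.numeric(data$pval),
    n = as.numeric(data$n), stringsAsFactors = FALSE
  )
  audit <- c(bad_allele = 0L, bad_se = 0L, bad_pval = 0L, bad_n = 0L,
             bad_eaf = 0L, bad_beta = 0L, duplicate_rsid = 0L)
  if (validate && nrow(data)) {
    ok_allele <- data$effect_allele %in% BASES & data$other_allele %in% BASES &
      data$effect_allele != data$other_allele
    ok_se <- is.finite(data$se) & data$se > 0
    ok_p <- is.finite(data$pval) & data$pval > 0 & data$pval <= 1
    ok_n <- is.na(data$n) | (is.finite(data$n) & data$n >= 1)
    ok_eaf <- is.na(data$eaf) | (data$eaf > 0 & data$eaf < 1)
    ok_beta <- is.finite(data$beta)
    audit["bad_allele"] <- sum(!ok_allele)
    audit["bad_se"] <- sum(ok_allele & !ok_se)
    audit["bad_pval"] <- sum(ok_allele & ok_se & !ok_p)
    audit["bad_n"] <- sum(ok_allele & ok_se & ok_p & !ok_n)
    audit["bad_eaf"] <- sum(ok_allele & ok_se & ok_p & ok_n & !ok_eaf)
    audit["bad_beta"] <- sum(ok_allele & ok_se & ok_p & ok_n & ok_eaf & !ok_beta)
    keep <- ok_allele & ok_se & ok_p & ok_n & ok_eaf & ok_beta
    data <- data[keep, , drop = FALSE]
    dup <- duplicated(data$rsid)
    audit["duplicate_rsid"] <- sum(dup)
    data <- data[!dup, , drop = FALSE]
    if (any(audit > 0))
      log_info("%s: skipped %d invalid rows (%s)", trait_id, sum(audit),
               paste(sprintf("%s=%d", names(audit)[audit > 0], audit[audit > 0]),
                     collapse = ", "))
  }
  rownames(data) <- NULL
  structure(list(trait_id = trait_id, trait_type = trait_type, data = data),
            audit = audit, class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> trait '%s' (%s): %d variants\n",
              x$trait_id, x$trait_type, nrow(x$data)))
  invisible(x)
}

#' Number of variants in a summary dataset
#' @param x a `summary_dataset`.
#' @return integer count.
#' @export
n_variants <- function(x) nrow(x$data)

#' Read GWAS summary statistics from delimited text
#'
#' Parses a header-bearing delimited file into a [summary_dataset]. Source
#' headers are mapped to the canonical fields via `column_map`, so
#' FinnGen-style or GoDMC-style headers are handled by configuration, not
#' code. Rows violating the variant invariants are skipped and counted in the
#' `audit` attribute; an empty EAF field is parsed as missing, never as zero.
#'
#' @param path file path to delimited text with a header row.
#' @param column_map named character vector mapping canonical names (`SNP`,
#'   `CHR`, `POS`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`) to the file's
#'   column names. Defaults to the identity (canonical headers).
#' @param trait_id,trait_type passed to [summary_dataset()].
#' @param sep field separator (default tab).
#' @return a [summary_dataset]; inspect `attr(, "audit")` for skip counts.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = basename(path),
                          trait_type = "quantitative", sep = "\t") {
  if (!file.exists(path)) stop("read_sumstats: cannot read ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           check.names = FALSE, comment.char = "")
  cmap <- stats::setNames(CANONICAL_COLS, CANONICAL_COLS)
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  miss <- MANDATORY_COLS[!cmap[MANDATORY_COLS] %in% names(raw)]
  if (length(miss))
    stop("read_sumstats: mandatory columns absent: ",
         paste(cmap[miss], collapse = ", "))
  pick <- function(canon) if (cmap[[canon]] %in% names(raw)) raw[[cmap[[canon]]]] else NA
  summary_dataset(data.frame(
    rsid = pick("SNP"), chrom = pick("CHR"), pos = pick("POS"),
    effect_allele = pick("EA"), other_allele = pick("OA"),
    eaf = pick("EAF"), beta = pick("BETA"), se = pick("SE"),
    pval = pick("P"), n = pick("N"), stringsAsFactors = FALSE
  ), trait_id = trait_id, trait_type = trait_type)
}

#' Write a summary dataset as tab-separated text
#'
#' Canonical header `SNP CHR POS EA OA EAF BETA SE P N`; missing values are
#' written as empty fields so that [read_sumstats()] round-trips the dataset
#' field-for-field, including EAF missingness.
#'
#' @param dataset a [summary_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(dataset, path) {
  d <- dataset$data
  out <- data.frame(SNP = d$rsid, CHR = d$chrom, POS = d$pos, EA = d$effect_allele,
                    OA = d$other_allele, EAF = d$eaf, BETA = d$beta, SE = d$se,
                    P = d$pval, N = d$n, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("write_sumstats: cannot write ", path)
  invisible(path)
}

complement_allele <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome's effects to the exposure's allele frame on the rsid
#' intersection. Non-palindromic SNPs: identical allele pair is kept, a
#' swapped pair (EA and OA exchanged) flips the outcome (`beta_out` negated,
#' `eaf_out` reflected), and pairs matching only after strand complementation
#' (A<->T, C<->G) are complemented first; irreconcilable allele sets (e.g.
#' A/G vs A/C) are dropped as incompatible. Palindromic SNPs (A/T or C/G)
#' carry no strand information in their alleles, so orientation is inferred
#' from allele frequency: pairs with a missing EAF are dropped, pairs with
#' either EAF within `palindrome_window` of 0.5 are dropped as ambiguous, and
#' otherwise the pair is kept when both EAFs fall on the same side of 0.5 and
#' flipped when they fall on opposite sides.
#'
#' @param exposure,outcome [summary_dataset] objects.
#' @param palindrome_window half-width `w` of the ambiguity band: palindromic
#'   SNPs with EAF in `[0.5 - w, 0.5 + w]` are dropped (default 0.08).
#' @return list with `pairs` (data frame: `rsid`, `beta_exp`, `se_exp`,
#'   `eaf_exp`, `pval_exp`, `n_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `action` in kept/flipped/dropped, `drop_reason`) and `audit` (named
#'   counts; kept + flipped + dropped equals the intersection size).
#' @export
harmonize <- function(exposure, outcome, palindrome_window = 0.08) {
  stopifnot(inherits(exposure, "summary_dataset"), inherits(outcome, "summary_dataset"))
  e <- exposure$data; o <- outcome$data
  common <- intersect(e$rsid, o$rsid)
  if (!length(common))
    stop("harmonize: no overlapping rsids between '", exposure$trait_id,
         "' and '", outcome$trait_id, "'")
  e <- e[match(common, e$rsid), ]; o <- o[match(common, o$rsid), ]

  n <- length(common)
  action <- character(n); reason <- character(n)
  beta_out <- o$beta; eaf_out <- o$eaf
  pal <- is_palindromic(e$effect_allele, e$other_allele)

  same_set <- function(ea, oa) ea == e$effect_allele & oa == e$other_allele
  swapped <- function(ea, oa) ea == e$other_allele & oa == e$effect_allele

  cea <- complement_allele(o$effect_allele); coa <- complement_allele(o$other_allele)
  direct_same <- same_set(o$effect_allele, o$other_allele)
  direct_swap <- swapped(o$effect_allele, o$other_allele)
  comp_same <- same_set(cea, coa)
  comp_swap <- swapped(cea, coa)

  for (i in seq_len(n)) {
    if (pal[i]) {
      # palindromic allele pair: A/T vs A/T and its complement are the same
      # set, so alleles alone cannot orient the strand
      if (!(direct_same[i] || direct_swap[i])) {
        action[i] <- "dropped"; reason[i] <- "incompatible"; next
      }
      fe <- e$eaf[i]; fo <- o$eaf[i]
      if (is.na(fe) || is.na(fo)) {
        action[i] <- "dropped"; reason[i] <- "palindromic_no_freq"; next
      }
      w <- palindrome_window
      if (abs(fe - 0.5) <= w || abs(fo - 0.5) <= w) {
        action[i] <- "dropped"; reason[i] <- "palindromic_ambiguous"; next
      }
      if (sign(fe - 0.5) == sign(fo - 0.5)) {
        action[i] <- "kept"
      } else {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]
      }
    } else if (direct_same[i]) {
      action[i] <- "kept"
    } else if (direct_swap[i]) {
      action[i] <- "flipped"
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
    } else if (comp_same[i]) {
      action[i] <- "kept"            # strand complement, same orientation
    } else if (comp_swap[i]) {
      action[i] <- "flipped"
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
    } else {
      action[i] <- "dropped"; reason[i] <- "incompatible"
    }
  }

  pairs <- data.frame(
    rsid = common, chrom = e$chrom, pos = e$pos,
    effect_allele = e$effect_allele, other_allele = e$other_allele,
    beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf, pval_exp = e$pval,
    n_exp = e$n, beta_out = beta_out, se_out = o$se, eaf_out = eaf_out,
    pval_out = o$pval, n_out = o$n, action = action, drop_reason = reason,
    stringsAsFactors = FALSE
  )
  audit <- c(n_intersection = n, kept = sum(action == "kept"),
             flipped = sum(action == "flipped"), dropped = sum(action == "dropped"),
             incompatible = sum(reason == "incompatible"),
             palindromic_no_freq = sum(reason == "palindromic_no_freq"),
             palindromic_ambiguous = sum(reason == "palindromic_ambiguous"))
  log_info("harmonize %s vs %s: %d kept, %d flipped, %d dropped",
           exposure$trait_id, outcome$trait_id, audit["kept"], audit["flipped"],
           audit["dropped"])
  list(pairs = pairs, audit = audit)
}

# Retained (kept/flipped) pairs only — the working instrument table.
harmonized_kept <- function(h) {
  h$pairs[h$pairs$action != "dropped", , drop = FALSE]
}
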