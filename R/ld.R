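# SNP-indexed LD correlation matrix: container, validation, plain-text I/O.
# LD is an input (computed elsewhere or fabricated by the simulator); the
# package never estimates it from genotypes.

#' Construct an LD matrix object
#'
#' @param rsids character vector of SNP identifiers (order defines the matrix
#'   frame).
#' @param r square symmetric matrix of signed correlations, unit diagonal,
#'   entries in `[-1, 1]`.
#' @param positions numeric base positions, same length/order as `rsids`.
#' @param tol symmetry tolerance (default 1e-8); asymmetry beyond it is an
#'   error, below it the matrix is symmetrized.
#' @return object of class `ld_matrix` with elements `rsids`, `r`, `positions`.
#' @export
ld_matrix <- function(rsids, r, positions, tol = 1e-8) {
  rsids <- as.character(rsids)
  r <- as.matrix(r)
  stopifnot(length(rsids) == nrow(r), nrow(r) == ncol(r),
            length(positions) == length(rsids))
  if (any(abs(r - t(r)) > tol)) stop("ld_matrix: asymmetric correlation matrix")
  if (any(abs(diag(r) - 1) > tol)) stop("ld_matrix: diagonal must be 1")
  if (any(abs(r) > 1 + tol)) stop("ld_matrix: |r| must be <= 1")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- list(rsids, rsids)
  structure(list(rsids = rsids, r = r,
                 positions = stats::setNames(as.numeric(positions), rsids)),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d SNPs\n", length(x$rsids)))
  invisible(x)
}

#' Read an LD matrix from plain text
#'
#' Two layouts are accepted. Square: first line whitespace-separated rsids,
#' subsequent lines the correlation matrix rows. Long: three whitespace
#' columns `rsid_a rsid_b r` (unlisted pairs default to 0, diagonal to 1).
#' Positions come from a companion two-column file `rsid position`.
#'
#' @param path matrix file.
#' @param positions_path companion rsid/position file; if `NULL`, positions
#'   default to the SNP index (clumping then treats all SNPs as co-local).
#' @param format `"square"`, `"long"`, or `"auto"` (sniff: a 3-column body
#'   whose third field is numeric is long form).
#' @return an [ld_matrix()].
#' @export
read_ld_matrix <- function(path, positions_path = NULL, format = c("auto", "square", "long")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_ld_matrix: empty file ", path)
  if (format == "auto") {
    f1 <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    format <- if (length(f1) == 3 && !is.na(suppressWarnings(as.numeric(f1[3]))))
      "long" else "square"
  }
  if (format == "square") {
    rsids <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    rows <- lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    r <- do.call(rbind, rows)
    if (nrow(r) != length(rsids)) stop("read_ld_matrix: row count != rsid count")
  } else {
    trip <- utils::read.table(text = lines, stringsAsFactors = FALSE)
    rsids <- unique(c(trip[[1]], trip[[2]]))
    r <- diag(length(rsids))
    dimnames(r) <- list(rsids, rsids)
    for (k in seq_len(nrow(trip))) {
      r[trip[[k, 1]], trip[[k, 2]]] <- trip[[k, 3]]
      r[trip[[k, 2]], trip[[k, 1]]] <- trip[[k, 3]]
    }
  }
  pos <- seq_along(rsids)
  if (!is.null(positions_path)) {
    pt <- utils::read.table(positions_path, stringsAsFactors = FALSE)
    pos <- pt[[2]][match(rsids, pt[[1]])]
    if (anyNA(pos)) stop("read_ld_matrix: positions missing for some rsids")
  }
  ld_matrix(rsids, r, pos)
}

#' Write an LD matrix (square layout) plus positions file
#' @param ld an [ld_matrix()].
#' @param path matrix output path.
#' @param positions_path positions output path (default `<path>.pos`).
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path, positions_path = paste0(path, ".pos")) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(ld$rsids, collapse = " "), con)
  utils::write.table(format(ld$r, digits = 10, trim = TRUE), con, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(ld$rsids, ld$positions), positions_path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
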