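#' Construct a validated contact matrix
#'
#' A contact matrix holds the Hi-C interaction frequencies (IF) between all
#' pairs of chromatin bins of one chromosome at a fixed resolution. It must
#' be square, symmetric and nonnegative.
#'
#' @param values Numeric N x N matrix of nonnegative interaction frequencies.
#' @param bin_labels Optional character vector of length N with ordered
#'   genomic identifiers for the bins.
#' @return An object of class `contact_matrix`: a list with elements
#'   `values` (the N x N matrix), `n_bins`, and `bin_labels`.
#' @export
contact_matrix <- function(values, bin_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("contact matrix values must be numeric")
  }
  if (nrow(values) != ncol(values)) {
    stop(sprintf("contact matrix must be square, got %d x %d",
                 nrow(values), ncol(values)))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("contact matrix contains non-finite values")
  }
  if (any(values < 0)) {
    stop("contact matrix contains negative interaction frequencies")
  }
  if (!isSymmetric(unname(values), tol = 0)) {
    stop("contact matrix is not symmetric")
  }
  if (!is.null(bin_labels) && length(bin_labels) != nrow(values)) {
    stop("bin_labels length must equal the number of bins")
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, n_bins = nrow(values), bin_labels = bin_labels),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  nz <- sum(x$values[upper.tri(x$values, diag = TRUE)] > 0)
  cat(sprintf("<contact_matrix> %d bins, %d nonzero upper-triangle cells\n",
              x$n_bins, nz))
  invisible(x)
}

#' Construct a sparse contact record set
#'
#' Three-column sparse contacts: bin index i, bin index j, interaction
#' frequency. Indices are 0-based. Records are canonicalized to i <= j;
#' duplicate pairs after canonicalization are an input error.
#'
#' @param i,j Nonnegative integer bin indices.
#' @param if_value Nonnegative interaction frequencies.
#' @return An object of class `sparse_contacts`: a data.frame with columns
#'   `i`, `j`, `if_value`.
#' @export
sparse_contacts <- function(i, j, if_value) {
  if (length(i) != length(j) || length(i) != length(if_value)) {
    stop("i, j, if_value must have equal length")
  }
  if (length(i) == 0L) {
    stop("no contact records")
  }
  if (any(i < 0) || any(j < 0) || any(i != floor(i)) || any(j != floor(j))) {
    stop("bin indices must be nonnegative integers")
  }
  if (any(!is.finite(if_value)) || any(if_value < 0)) {
    stop("interaction frequencies must be finite and nonnegative")
  }
  # canonical ordering i <= j
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("duplicate contact record for bin pair (%s)",
                 gsub(" ", ", ", dup)))
  }
  structure(
    data.frame(i = as.integer(lo), j = as.integer(hi),
               if_value = as.numeric(if_value)),
    class = c("sparse_contacts", "data.frame")
  )
}

# read non-comment, non-blank lines; returns lines plus original line numbers
read_data_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(lines = raw[keep], lineno = which(keep))
}

#' Read a square Hi-C contact matrix from a tab-separated text file
#'
#' The file must contain N rows of N whitespace/tab-separated numeric
#' fields. Lines starting with `#` and blank lines are skipped. Slight
#' asymmetry (relative difference at most `tol`) is repaired by averaging
#' the matrix with its transpose; larger asymmetry is an error.
#'
#' @param path Path to the file.
#' @param tol Relative asymmetry tolerance (default 1e-6).
#' @return A [contact_matrix()].
#' @export
read_square_matrix <- function(path, tol = 1e-6) {
  dl <- read_data_lines(path)
  if (length(dl$lines) == 0L) {
    stop("no matrix rows found in ", path)
  }
  fields <- strsplit(trimws(dl$lines), "[\t ]+")
  n <- length(fields)
  widths <- lengths(fields)
  if (any(widths != n)) {
    bad <- which(widths != n)[1L]
    stop(sprintf(
      "shape error: %d rows but row at line %d has %d fields (expected %d)",
      n, dl$lineno[bad], widths[bad], n))
  }
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(n)))
  if (n == 1L) vals <- matrix(vals, 1L, 1L)
  # vapply gives column-per-row, so transpose back to row-major reading
  m <- t(matrix(vals, nrow = n))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error: non-numeric field at row %d, column %d",
                 bad[1L], bad[2L]))
  }
  if (any(m < 0)) {
    stop("validation error: negative interaction frequency in matrix")
  }
  asym <- abs(m - t(m))
  scale <- pmax(abs(m), abs(t(m)), 1e-300)
  if (any(asym / scale > tol & asym > 0)) {
    stop(sprintf(
      "matrix asymmetry exceeds relative tolerance %g; refusing to symmetrize",
      tol))
  }
  contact_matrix((m + t(m)) / 2)
}

# greatest common divisor of a vector of nonnegative integers
gcd_vector <- function(x) {
  gcd2 <- function(a, b) {
    while (b != 0) {
      t <- b
      b <- a %% b
      a <- t
    }
    a
  }
  x <- unique(x[x > 0])
  if (length(x) == 0L) return(1)
  Reduce(gcd2, x)
}

#' Read a sparse three-column contact list
#'
#' Each data line must have exactly three tab/whitespace-separated fields:
#' bin i, bin j, interaction frequency. Bin coordinates given as genomic
#' positions (multiples of a common resolution) are reduced to 0-based bin
#' indices by dividing by the greatest common divisor of all distinct
#' nonzero coordinates (the inferred resolution); raw 0-based indices pass
#' through unchanged because their gcd is 1.
#'
#' @param path Path to the file.
#' @return A [sparse_contacts()] object (0-based indices).
#' @export
read_sparse_contacts <- function(path) {
  dl <- read_data_lines(path)
  if (length(dl$lines) == 0L) {
    stop("no contact records in ", path)
  }
  fields <- strsplit(trimws(dl$lines), "[\t ]+")
  widths <- lengths(fields)
  if (any(widths != 3L)) {
    bad <- which(widths != 3L)[1L]
    stop(sprintf("format error at line %d: expected 3 fields, found %d",
                 dl$lineno[bad], widths[bad]))
  }
  m <- suppressWarnings(vapply(fields, as.numeric, numeric(3L)))
  if (anyNA(m)) {
    bad <- which(colSums(is.na(m)) > 0)[1L]
    stop(sprintf("parse error at line %d: non-numeric field", dl$lineno[bad]))
  }
  i <- m[1L, ]
  j <- m[2L, ]
  v <- m[3L, ]
  if (any(v < 0)) {
    bad <- which(v < 0)[1L]
    stop(sprintf("validation error at line %d: negative interaction frequency",
                 dl$lineno[bad]))
  }
  if (any(i < 0) || any(j < 0) || any(i != floor(i)) || any(j != floor(j))) {
    stop("bin coordinates must be nonnegative integers")
  }
  res <- gcd_vector(c(i, j))
  sparse_contacts(i / res, j / res, v)
}

#' Convert sparse contacts to a square contact matrix
#'
#' The matrix spans bins 0 .. max index; each record (i, j, v) fills both
#' (i, j) and (j, i); unmentioned cells are zero.
#'
#' @param sparse A [sparse_contacts()] object, or a 3-column data.frame of
#'   (i, j, if_value) which is validated first.
#' @return A [contact_matrix()].
#' @export
sparse_to_square <- function(sparse) {
  if (!inherits(sparse, "sparse_contacts")) {
    sparse <- sparse_contacts(sparse[[1L]], sparse[[2L]], sparse[[3L]])
  }
  n <- max(sparse$i, sparse$j) + 1L
  m <- matrix(0, n, n)
  idx <- cbind(sparse$i + 1L, sparse$j + 1L)
  m[idx] <- sparse$if_value
  m[idx[, 2:1, drop = FALSE]] <- sparse$if_value
  contact_matrix(m)
}

#' Extract the nonzero upper triangle of a contact matrix as sparse records
#'
#' Inverse of [sparse_to_square()] on matrices whose nonzero cells all come
#' from the sparse records (diagonal included).
#'
#' @param matrix A [contact_matrix()].
#' @return A [sparse_contacts()] object.
#' @export
square_to_sparse <- function(matrix) {
  stopifnot(inherits(matrix, "contact_matrix"))
  v <- matrix$values
  keep <- which(upper.tri(v, diag = TRUE) & v > 0, arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    stop("no contact records: matrix has no nonzero cells")
  }
  sparse_contacts(keep[, 1L] - 1L, keep[, 2L] - 1L, v[keep])
}

#' Write a contact matrix as tab-separated text
#'
#' Values are written at full double precision so that
#' `read_square_matrix(write_square_matrix(x))` reproduces `x` to numeric
#' round-trip precision.
#'
#' @param matrix A [contact_matrix()].
#' @param path Output path.
#' @export
write_square_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "contact_matrix"))
  rows <- apply(matrix$values, 1L, function(r) {
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = "\t")
  })
  writeLines(rows, path)
  invisible(path)
}
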