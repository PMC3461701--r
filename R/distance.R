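#' Compute a sample-by-sample distance matrix
#'
#' Builds the N x N distance matrix `D = (d_ij)` over the P outcome variables
#' of a samples-by-variables data matrix. Missing values are handled
#' pairwise-complete: for each pair of samples the distance is computed over
#' the variables observed in both profiles and rescaled so that magnitudes
#' stay comparable across pairs with different amounts of missingness
#' (`sqrt(P / P_shared)` for Euclidean, `P / P_shared` for Manhattan).
#'
#' @param data Numeric matrix or data frame, samples in rows (row names are
#'   sample IDs), variables in columns. `NA` marks missing values.
#' @param measure Distance measure: `"euclidean"`, `"manhattan"`, or
#'   `"pearson_corr"` (`d_ij = 1 - r_ij`, the Pearson correlation of the two
#'   profiles, range 0 to 2).
#' @param min_shared_fraction Minimum fraction of the P variables that every
#'   pair of samples must share non-missing; pairs below
#'   `ceiling(min_shared_fraction * P)` shared variables are an error.
#' @return A symmetric N x N numeric matrix with zero diagonal, sample IDs as
#'   dimnames, and the measure recorded in attribute `"measure"`.
#' @examples
#' y <- rbind(a = c(0, 0), b = c(3, 4))
#' compute_distance_matrix(y)["a", "b"]  # 5
#' @export
compute_distance_matrix <- function(data,
                                    measure = c("euclidean", "manhattan",
                                                "pearson_corr"),
                                    min_shared_fraction = 0.5) {
  measure <- match.arg(measure)
  y <- as_data_matrix(data)
  n <- nrow(y)
  p <- ncol(y)
  if (!is.numeric(min_shared_fraction) || length(min_shared_fraction) != 1 ||
      min_shared_fraction <= 0 || min_shared_fraction > 1) {
    stop("'min_shared_fraction' must be a single value in (0, 1]")
  }

  obs <- !is.na(y)
  shared <- tcrossprod(obs * 1)   # pairwise counts of co-observed variables
  need <- ceiling(min_shared_fraction * p)
  bad <- which(shared < need & upper.tri(shared), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "samples '%s' and '%s' share only %d of %d variables (need >= %d)",
      rownames(y)[i], rownames(y)[j], shared[i, j], p, need))
  }

  if (measure == "pearson_corr") {
    sds <- apply(y, 1, stats::sd, na.rm = TRUE)
    if (any(!is.finite(sds) | sds == 0)) {
      k <- which(!is.finite(sds) | sds == 0)[1]
      stop(sprintf(
        "profile '%s' has zero variance; Pearson correlation is undefined",
        rownames(y)[k]))
    }
    r <- suppressWarnings(stats::cor(t(y), use = "pairwise.complete.obs"))
    if (anyNA(r)) {
      ij <- which(is.na(r), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "correlation undefined for samples '%s' and '%s' over shared variables",
        rownames(y)[ij[1]], rownames(y)[ij[2]]))
    }
    d <- 1 - r
  } else {
    # stats::dist applies exactly the pairwise-complete rescaling used here
    d <- as.matrix(stats::dist(y, method = measure))
  }
  d[d < 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(y), rownames(y))
  attr(d, "measure") <- measure
  d
}

#' Gower double-centering of a distance matrix
#'
#' Transforms squared distances into the centered inner-product matrix
#' `G = (I - 11'/N) A (I - 11'/N)` with `A = -D^2 / 2` (elementwise square).
#' Every row and column of `G` sums to zero; for Euclidean distances on
#' complete data `G` equals the Gram matrix of the column-centered data, so
#' `tr(G)` is the total sum of squares.
#'
#' @param dm Symmetric distance matrix (zero diagonal, nonnegative), as from
#'   [compute_distance_matrix()].
#' @return The N x N centered matrix `G`, with the sample IDs of `dm`.
#' @export
gower_center <- function(dm) {
  d <- check_distance_matrix(dm)
  a <- -0.5 * d * d
  rm <- rowMeans(a)
  g <- a - outer(rm, rm, "+") + mean(a)  # A is symmetric: col means = row means
  g <- (g + t(g)) / 2
  attr(g, "measure") <- NULL
  dimnames(g) <- dimnames(d)
  g
}

#' Convert a distance matrix to a similarity matrix
#'
#' Rescales distances into `[0, 1]` similarities, `s_ij = 1 - d_ij / d_max`,
#' using either a supplied theoretical maximum distance or the empirical
#' maximum entry of the matrix.
#'
#' @param dm Distance matrix.
#' @param max_distance Positive scalar, or `"empirical"` to use the largest
#'   observed entry (the least similar pair then has similarity exactly 0).
#' @return Similarity matrix with unit diagonal; the scale used is recorded
#'   in attribute `"max_distance_used"`.
#' @export
similarity_from_distance <- function(dm, max_distance = "empirical") {
  d <- check_distance_matrix(dm)
  if (identical(max_distance, "empirical")) {
    dmax <- max(d)
    if (dmax <= 0) {
      stop("all distances are zero; empirical similarity scale is undefined")
    }
  } else {
    if (!is.numeric(max_distance) || length(max_distance) != 1 ||
        max_distance <= 0) {
      stop("'max_distance' must be a positive scalar or \"empirical\"")
    }
    dmax <- max_distance
  }
  s <- 1 - d / dmax
  attr(s, "max_distance_used") <- dmax
  s
}

#' Read and write distance matrices as CSV
#'
#' The on-disk format is a square CSV with a header row of sample IDs and a
#' leading ID column. On read, the matrix is validated (square, IDs matching,
#' symmetric within 1e-8, zero diagonal) and symmetrized.
#'
#' @param path File path.
#' @return `read_distance_matrix()` returns the validated matrix;
#'   `write_distance_matrix()` returns `path` invisibly.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(input_error(sprintf("cannot read distance matrix: '%s' not found", path)))
  }
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  d <- as.matrix(raw)
  if (nrow(d) != ncol(d)) {
    stop(input_error(sprintf("distance matrix in '%s' is not square (%d x %d)",
                             path, nrow(d), ncol(d))))
  }
  if (!identical(rownames(d), colnames(d))) {
    stop(input_error(sprintf(
      "row and column sample IDs disagree in '%s'", path)))
  }
  tryCatch(check_distance_matrix(d),
           error = function(e) stop(input_error(sprintf(
             "invalid distance matrix in '%s': %s", path, conditionMessage(e)))))
}

#' @rdname read_distance_matrix
#' @param dm Distance matrix to serialize.
#' @export
write_distance_matrix <- function(dm, path) {
  d <- check_distance_matrix(dm)
  df <- data.frame(id = rownames(d),
                   format(d, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Coerce to a validated samples-by-variables numeric matrix with unique IDs.
as_data_matrix <- function(data) {
  y <- as.matrix(data)
  if (!is.numeric(y)) stop("data must be numeric")
  if (nrow(y) < 2) stop("need at least 2 samples")
  if (ncol(y) < 1) stop("need at least 1 variable")
  if (is.null(rownames(y))) rownames(y) <- paste0("s", seq_len(nrow(y)))
  if (is.null(colnames(y))) colnames(y) <- paste0("v", seq_len(ncol(y)))
  if (anyDuplicated(rownames(y))) stop("sample IDs must be unique")
  if (anyDuplicated(colnames(y))) stop("variable IDs must be unique")
  y
}

# Validate a distance matrix: square, symmetric within tolerance, zero
# diagonal, nonnegative. Returns the symmetrized matrix.
check_distance_matrix <- function(dm, tol = 1e-8) {
  d <- as.matrix(dm)
  if (!is.numeric(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be a square numeric matrix")
  }
  if (anyNA(d)) stop("distance matrix contains missing values")
  scale <- max(abs(d), 1)
  if (max(abs(d - t(d))) > tol * scale) {
    stop(sprintf("distance matrix is asymmetric beyond tolerance %g", tol))
  }
  if (max(abs(diag(d))) > tol * scale) {
    stop("distance matrix has a nonzero diagonal")
  }
  if (min(d) < -tol * scale) stop("distances must be nonnegative")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  d
}

#' Read a samples-by-variables data table
#'
#' TSV or CSV (sniffed from the file extension, or forced via `sep`), first
#' column sample IDs, header row of variable IDs; empty cells or `NA` are
#' missing values.
#'
#' @param path File path.
#' @param sep Field separator; default `NULL` sniffs `.csv` vs anything else
#'   (tab).
#' @return Numeric matrix with sample IDs as row names.
#' @export
read_data_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    stop(input_error(sprintf("cannot read data matrix: '%s' not found", path)))
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, na.strings = c("", "NA"))
  y <- as.matrix(raw)
  storage.mode(y) <- "double"
  tryCatch(as_data_matrix(y),
           error = function(e) stop(input_error(sprintf(
             "invalid data matrix in '%s': %s", path, conditionMessage(e)))))
}

# Error subclass used by the CLI to distinguish bad input (exit 2) from
# internal failures (exit 1).
input_error <- function(msg) {
  structure(class = c("mdmreg_input_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
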