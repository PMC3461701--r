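#' Projection (hat) matrix of a design, via pivoted QR
#'
#' Forms the orthogonal projector `H` onto the span of the intercept and the
#' M regressor columns, `H = X(X'X)^{-1}X'`, using a column-pivoted
#' orthogonal-triangular decomposition so that numerically dependent columns
#' are dropped (and reported) rather than destabilizing the inverse.
#'
#' @param x N x M numeric matrix of regressors (0/1 dichotomous or
#'   continuous); column names label the predictors. A column of ones is
#'   prepended internally — do not include an intercept, and constant columns
#'   are an error.
#' @param tol Relative pivot threshold below which a column is treated as
#'   linearly dependent.
#' @return An object of class `mdmr_projection`: list with `h` (N x N
#'   projector), `rank` (rank of the full design including the intercept),
#'   `m` (number of independent regressors retained, `rank - 1`), and
#'   `dropped_columns` (labels of discarded regressors).
#' @export
build_projection <- function(x, tol = 1e-10) {
  x <- as_design_matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n <= m + 1) stop("need more samples than regressors plus intercept")
  xfull <- cbind("(intercept)" = 1, x)
  qrx <- qr(xfull, tol = tol)
  rank <- qrx$rank
  kept <- qrx$pivot[seq_len(rank)]
  dropped <- colnames(xfull)[setdiff(seq_len(m + 1L), kept)]
  if (!(1L %in% kept)) {
    # the intercept can only be pivoted out if a regressor spans it, which
    # the constant-column check forbids; guard anyway
    stop("intercept column lost during decomposition")
  }
  if (rank < 2) stop("no usable regressors (design has rank 0 after dropping)")
  q <- qr.Q(qrx)[, seq_len(rank), drop = FALSE]
  h <- tcrossprod(q)
  h <- (h + t(h)) / 2
  dimnames(h) <- list(rownames(x), rownames(x))
  structure(list(h = h, rank = rank, m = rank - 1L,
                 dropped_columns = dropped, q = q),
            class = "mdmr_projection")
}

as_design_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (!is.numeric(x)) stop("design must be numeric (code factors as 0/1 dummies)")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  const <- apply(x, 2, function(col) max(col) - min(col) == 0)
  if (any(const)) {
    stop(sprintf("constant regressor column(s) not allowed: %s",
                 paste(colnames(x)[const], collapse = ", ")))
  }
  x
}

#' Pseudo F-statistic from a Gower-centered matrix and a projector
#'
#' Computes the raw trace ratio `F = tr(HGH) / tr((I-H)G(I-H))` together with
#' both traces. By idempotence of `H`, `tr(HGH) = tr(HG)`, so the traces are
#' obtained without materializing triple products.
#'
#' @param g Gower-centered matrix from [gower_center()].
#' @param h Projection from [build_projection()] (or a bare projector matrix).
#' @return List with `f_raw`, `tr_model` (`tr(HGH)`), `tr_residual`
#'   (`tr((I-H)G(I-H))`), and `tr_total` (`tr(G)`).
#' @export
pseudo_f <- function(g, h) {
  hm <- if (inherits(h, "mdmr_projection")) h$h else h
  if (!all(dim(hm) == dim(g))) stop("dimensions of G and H do not match")
  tr_total <- sum(diag(g))
  tr_model <- sum(hm * g)            # tr(HG), H symmetric
  tr_residual <- tr_total - tr_model # cross terms vanish by idempotence
  if (abs(tr_residual) <= 1e-12 * max(abs(tr_total), 1)) {
    stop("saturated model / zero residual distance")
  }
  list(f_raw = tr_model / tr_residual,
       tr_model = tr_model, tr_residual = tr_residual, tr_total = tr_total)
}

#' Degrees of freedom and scaled pseudo-F
#'
#' Scales the raw trace ratio by the sample-space degrees of freedom,
#' `f_scaled = f_raw * (n - m - 1) / m`, and returns the reference
#' F-distribution degrees of freedom `(p*m, p*n - m - 1)`, which grow with
#' the number P of outcome variables behind the distance matrix. For a
#' single regressor this is the pair `(P, P*N - 2)`, and for `p = 1` the
#' classical ANOVA/regression degrees of freedom, making `f_scaled` the
#' ordinary F-statistic in that case.
#'
#' @param f_raw Raw trace ratio from [pseudo_f()].
#' @param n Number of samples.
#' @param p Number of outcome variables used to build the distance matrix.
#' @param m Number of (independent) regressors, excluding the intercept.
#' @return List with `f_scaled`, `df1`, `df2`, and `extrapolated_df`
#'   (`TRUE` when `m > 1`, where the multi-regressor df rule is an
#'   extrapolation from the single-regressor case).
#' @export
scaled_f <- function(f_raw, n, p, m = 1) {
  stopifnot(n >= 2, p >= 1, m >= 1)
  df1 <- p * m
  df2 <- p * n - m - 1
  if (df2 <= 0) stop("nonpositive denominator degrees of freedom")
  list(f_scaled = f_raw * (n - m - 1) / m,
       df1 = as.integer(df1), df2 = as.integer(df2),
       extrapolated_df = m > 1)
}

#' Analytic p-value from the F-distribution
#'
#' Upper-tail probability of `F(df1, df2)` at the scaled pseudo-F.
#'
#' @param f_scaled Scaled statistic from [scaled_f()].
#' @param df1,df2 Degrees of freedom.
#' @return p-value in `[0, 1]`.
#' @export
analytic_pvalue <- function(f_scaled, df1, df2) {
  stopifnot(df1 >= 1, df2 >= 1)
  stats::pf(f_scaled, df1, df2, lower.tail = FALSE)
}

#' Permutation test for the MDMR pseudo-F
#'
#' Builds the null distribution by rearranging sample labels of the
#' regressors while the distance structure stays fixed: each permutation
#' jointly permutes the rows of the regressor block (the intercept is
#' untouched) and the statistic is recomputed. When the number of distinct
#' label arrangements is at most `n_perm`, all arrangements are enumerated
#' and `p = #\{f >= f_obs\} / #arrangements` (identity included); otherwise
#' `n_perm` random permutations are drawn and the add-one estimate
#' `p = (1 + #\{f_perm >= f_obs\}) / (n_perm + 1)` is used. Ties count
#' towards the numerator.
#'
#' @param g Gower-centered matrix.
#' @param x Regressor matrix (no intercept), or an `mdmr_projection`.
#' @param n_perm Number of random permutations (and the threshold below
#'   which enumeration is exhaustive).
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit. With `NULL` the current RNG stream is used.
#' @return List with `p_permutation`, `f_obs` (raw trace ratio), `null_f`
#'   (vector of permuted statistics, excluding the observed one in sampled
#'   mode, including the identity in exhaustive mode), `exhaustive`,
#'   `n_arrangements` (exhaustive mode), and `n_perm`.
#' @export
permutation_test <- function(g, x, n_perm = 999, seed = NULL) {
  stopifnot(n_perm >= 1)
  proj <- if (inherits(x, "mdmr_projection")) x else build_projection(x)
  xr <- if (inherits(x, "mdmr_projection")) NULL else as_design_matrix(x)
  n <- nrow(g)
  obs <- pseudo_f(g, proj)
  tr_total <- obs$tr_total

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  # exhaustive enumeration when the distinct relabelings are few enough
  perms <- NULL
  exhaustive <- FALSE
  if (!is.null(xr)) {
    key <- apply(xr, 1, paste, collapse = "\r")
    counts <- table(key)
    log_arr <- lfactorial(n) - sum(lfactorial(counts))
    if (log_arr <= log(n_perm)) {
      perms <- multiset_permutations(match(key, names(counts)))
      exhaustive <- TRUE
    }
  }
  if (!exhaustive) {
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  }

  tm <- perm_model_traces(g, proj, perms)
  null_f <- tm / (tr_total - tm)

  tol <- 1e-8 * max(abs(obs$f_raw), 1)
  if (exhaustive) {
    p <- sum(null_f >= obs$f_raw - tol) / length(null_f)
  } else {
    p <- (1 + sum(null_f >= obs$f_raw - tol)) / (length(null_f) + 1)
  }
  list(p_permutation = p, f_obs = obs$f_raw, null_f = null_f,
       exhaustive = exhaustive,
       n_arrangements = if (exhaustive) length(perms) else NA_integer_,
       n_perm = length(perms))
}

# tr(H G[pi,pi]) for a list of index permutations. Fast path for a single
# regressor: H = 11'/N + uu' with u the second orthonormal QR column, so the
# model trace is a quadratic form evaluated for all permutations in one
# matrix product.
perm_model_traces <- function(g, proj, perms) {
  n <- nrow(g)
  if (proj$rank == 2L) {
    u <- proj$q[, 2]
    c0 <- sum(g) / n  # zero for centered G, constant under conjugation anyway
    v <- vapply(perms, function(pi) u[pi], numeric(n))
    c0 + colSums(v * (g %*% v))
  } else {
    h <- proj$h
    vapply(perms, function(pi) sum(h * g[pi, pi]), numeric(1))
  }
}

# All distinct permutations of a vector of class labels, as index
# permutations (a representative index permutation per distinct relabeling).
multiset_permutations <- function(labels) {
  n <- length(labels)
  idx_by_class <- split(seq_len(n), labels)
  out <- list()
  rec <- function(remaining, acc) {
    if (length(acc) == n) {
      # map the label sequence to a representative index permutation
      taken <- integer(0)
      pos <- integer(n)
      used <- lapply(idx_by_class, function(ix) 0L)
      for (a in seq_len(n)) {
        cl <- acc[a]
        used[[cl]] <- used[[cl]] + 1L
        pos[a] <- idx_by_class[[cl]][used[[cl]]]
      }
      out[[length(out) + 1L]] <<- pos
      return(invisible())
    }
    for (cl in which(remaining > 0L)) {
      remaining[cl] <- remaining[cl] - 1L
      rec(remaining, c(acc, cl))
      remaining[cl] <- remaining[cl] + 1L
    }
  }
  counts <- vapply(idx_by_class, length, integer(1))
  rec(counts, integer(0))
  out
}

#' Multivariate distance matrix regression
#'
#' Tests whether M predictor variables explain variation in the distances
#' among N samples. Accepts either the raw samples-by-variables data (from
#' which a distance matrix is computed) or a precomputed distance matrix.
#' Reports the raw trace-ratio pseudo-F, the df-scaled statistic, a
#' permutation p-value, the analytic F-distribution p-value, and the
#' fraction of distance-based variation attributable to the predictors,
#' `tr(HGH)/tr(G)`.
#'
#' @param x Predictors: N x M numeric matrix or data frame (0/1 dummies or
#'   continuous), row names are sample IDs.
#' @param y Optional samples-by-variables outcome data.
#' @param d Optional precomputed distance matrix (used instead of `y`).
#' @param measure Distance measure for `y` (see
#'   [compute_distance_matrix()]).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed for the permutation test.
#' @param p_variables Number of outcome variables P behind the distance
#'   matrix; defaults to `ncol(y)` and must be supplied when only `d` is
#'   given (it sets the analytic degrees of freedom).
#' @param per_regressor Also test each regressor marginally (one
#'   single-column MDMR per predictor)?
#' @param min_shared_fraction Passed to [compute_distance_matrix()].
#' @return An object of class `mdmr`; see Details for fields. Printing shows
#'   a compact summary.
#' @details Fields: `f_raw`, `f_scaled`, `df1`, `df2`, `p_permutation`,
#'   `p_analytic`, `n_permutations`, `variance_fraction`, `seed`,
#'   `dropped_columns`, `n`, `p_variables`, `m`, `extrapolated_df`,
#'   `exhaustive`, and optionally `per_regressor` (a data frame).
#' @examples
#' y <- matrix(c(1, 2, 3, 5), ncol = 1)
#' x <- c(0, 0, 1, 1)
#' fit <- mdmr(x, y = y, n_perm = 99)
#' fit$f_scaled       # 5, the one-way ANOVA F
#' fit$p_permutation  # 1/3, exhaustive over the 6 group relabelings
#' @export
mdmr <- function(x, y = NULL, d = NULL,
                 measure = c("euclidean", "manhattan", "pearson_corr"),
                 n_perm = 999, seed = NULL, p_variables = NULL,
                 per_regressor = FALSE, min_shared_fraction = 0.5) {
  measure <- match.arg(measure)
  if (is.null(y) && is.null(d)) stop("supply outcome data 'y' or distances 'd'")
  if (is.null(d)) {
    y <- as_data_matrix(y)
    d <- compute_distance_matrix(y, measure, min_shared_fraction)
    if (is.null(p_variables)) p_variables <- ncol(y)
  } else {
    d <- check_distance_matrix(d)
    if (is.null(p_variables)) {
      stop("'p_variables' must be given with a precomputed distance matrix")
    }
  }
  xm <- as_design_matrix(x)
  if (is.null(rownames(xm))) rownames(xm) <- rownames(d)
  aligned <- align_by_id(d, xm)
  d <- aligned$d; xm <- aligned$x

  g <- gower_center(d)
  proj <- build_projection(xm)
  # drop collinear columns from the regressor block before permuting, so the
  # permuted designs have the reported rank
  if (length(proj$dropped_columns) > 0) {
    keep <- setdiff(colnames(xm), proj$dropped_columns)
    xm_used <- xm[, keep, drop = FALSE]
  } else {
    xm_used <- xm
  }
  n <- nrow(g)
  m <- proj$m
  ftab <- pseudo_f(g, proj)
  sc <- scaled_f(ftab$f_raw, n = n, p = p_variables, m = m)
  pa <- analytic_pvalue(sc$f_scaled, sc$df1, sc$df2)
  pt <- permutation_test(g, xm_used, n_perm = n_perm, seed = seed)

  res <- structure(list(
    f_raw = ftab$f_raw,
    f_scaled = sc$f_scaled,
    df1 = sc$df1, df2 = sc$df2,
    p_permutation = pt$p_permutation,
    p_analytic = pa,
    n_permutations = pt$n_perm,
    exhaustive = pt$exhaustive,
    variance_fraction = ftab$tr_model / ftab$tr_total,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    dropped_columns = proj$dropped_columns,
    n = n, p_variables = p_variables, m = m,
    extrapolated_df = sc$extrapolated_df,
    measure = if (!is.null(attr(d, "measure"))) attr(d, "measure") else measure
  ), class = "mdmr")

  if (isTRUE(per_regressor) && ncol(xm_used) > 1) {
    rows <- lapply(colnames(xm_used), function(cn) {
      sub <- mdmr(xm_used[, cn, drop = FALSE], d = d, n_perm = n_perm,
                  seed = seed, p_variables = p_variables)
      data.frame(predictor = cn, f_raw = sub$f_raw, f_scaled = sub$f_scaled,
                 df1 = sub$df1, df2 = sub$df2,
                 p_permutation = sub$p_permutation,
                 p_analytic = sub$p_analytic,
                 variance_fraction = sub$variance_fraction)
    })
    res$per_regressor <- do.call(rbind, rows)
  }
  res
}

# Align a distance matrix and design by shared sample IDs (order of d wins);
# errors if the ID sets differ.
align_by_id <- function(d, x) {
  ids_d <- rownames(d)
  ids_x <- rownames(x)
  if (is.null(ids_x) || is.null(ids_d)) return(list(d = d, x = x))
  if (!setequal(ids_d, ids_x) || length(ids_d) != length(ids_x)) {
    stop(input_error(sprintf(
      "sample IDs of data/distances and predictors do not match (%d vs %d ids, %d shared)",
      length(ids_d), length(ids_x), length(intersect(ids_d, ids_x)))))
  }
  list(d = d, x = x[ids_d, , drop = FALSE])
}

#' @export
print.mdmr <- function(x, ...) {
  cat("Multivariate distance matrix regression\n")
  cat(sprintf("  samples: %d   outcome variables: %d   regressors: %d (%s)\n",
              x$n, x$p_variables, x$m, x$measure))
  cat(sprintf("  pseudo-F (trace ratio): %.6g   scaled F: %.6g on (%d, %d) df\n",
              x$f_raw, x$f_scaled, x$df1, x$df2))
  cat(sprintf("  variance fraction tr(HGH)/tr(G): %.4f\n", x$variance_fraction))
  cat(sprintf("  permutation p: %.4g (%s%d permutations)   analytic p: %.4g\n",
              x$p_permutation, if (x$exhaustive) "exhaustive, " else "",
              x$n_permutations, x$p_analytic))
  if (length(x$dropped_columns) > 0) {
    cat("  dropped collinear columns:", paste(x$dropped_columns, collapse = ", "), "\n")
  }
  if (!is.null(x$per_regressor)) {
    cat("  per-regressor marginal tests:\n")
    print(x$per_regressor, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize an MDMR result to JSON
#'
#' @param result An object from [mdmr()].
#' @param path Optional file path; with `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
mdmr_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "mdmr"))
  fields <- c("f_raw", "f_scaled", "df1", "df2", "p_permutation",
              "p_analytic", "n_permutations", "seed", "variance_fraction",
              "dropped_columns", "n", "p_variables", "m", "measure",
              "exhaustive", "extrapolated_df")
  x <- result[fields]
  x$dropped_columns <- as.list(x$dropped_columns)
  if (!is.null(result$per_regressor)) x$per_regressor <- result$per_regressor
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
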