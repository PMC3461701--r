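#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Agglomerative clustering that at each step merges the pair of clusters
#' with the smallest average inter-cluster distance, the merge height being
#' that average.
#'
#' @param dm Distance matrix.
#' @return An [stats::hclust] dendrogram.
#' @export
upgma <- function(dm) {
  d <- check_distance_matrix(dm)
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' @param dendrogram An `hclust` object, e.g. from [upgma()].
#' @param k Number of clusters, `1 <= k <= N`.
#' @return A `cluster_assignment`: list with `labels` (integers in `1..k`,
#'   relabeled canonically by first occurrence so downstream dummy coding is
#'   deterministic), `k`, `method`, and `linkage_heights`.
#' @export
cut_tree <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$order)
  if (k < 1 || k > n) stop(sprintf("k must be in 1..%d", n))
  labels <- canonical_labels(stats::cutree(dendrogram, k = k))
  structure(list(labels = labels, k = as.integer(k), method = "upgma_cut",
                 linkage_heights = dendrogram$height),
            class = "cluster_assignment")
}

# Relabel cluster ids 1..k in order of first occurrence.
canonical_labels <- function(labels) {
  u <- unique(labels)
  out <- match(labels, u)
  names(out) <- names(labels)
  out
}

#' Dummy-code a cluster assignment as a regressor block
#'
#' Produces `k - 1` 0/1 indicator columns (the last cluster is the
#' reference); the intercept is added downstream by [build_projection()].
#'
#' @param assignment A `cluster_assignment`, or a vector of cluster labels.
#' @return N x (k-1) indicator matrix.
#' @export
dummy_code <- function(assignment) {
  labels <- if (inherits(assignment, "cluster_assignment")) {
    assignment$labels
  } else {
    canonical_labels(assignment)
  }
  k <- max(labels)
  if (k < 2) stop("need at least 2 clusters to dummy-code")
  if (length(unique(labels)) != k) stop("empty cluster in assignment")
  x <- vapply(seq_len(k - 1L), function(j) as.numeric(labels == j),
              numeric(length(labels)))
  colnames(x) <- paste0("cluster", seq_len(k - 1L))
  rownames(x) <- names(labels)
  x
}

#' Choose the number of clusters by distance matrix regression
#'
#' For each candidate `k`, clusters the samples (UPGMA cut of the distance
#' matrix, or k-means on the raw data), dummy-codes the memberships, and
#' runs MDMR of the distance matrix on them. The selected `k` is the
#' smallest one for which moving to `k + 1` clusters does not significantly
#' improve the explained distance-based variation: the gain in `tr(HGH)`
#' from adding the `(k+1)`-clustering's indicators to the k-clustering's
#' design is assessed by permuting the added block while the k-level block
#' stays fixed. If `k = 2` is itself not significant the scan reports 1
#' cluster (no structure); if every increment is significant up to `k_max`
#' the rule is indeterminate and the `k` with the largest scaled F is
#' reported (`selected_by = "argmax_f"`).
#'
#' @param dm Distance matrix (required for `method = "upgma"`; computed
#'   from `y` by Euclidean distance when missing).
#' @param y Raw samples-by-variables data (required for
#'   `method = "kmeans"`).
#' @param k_max Largest number of clusters scanned (`2 <= k_max < N`).
#' @param method `"upgma"` or `"kmeans"` (k-means uses `nstart` restarts,
#'   best inertia kept).
#' @param n_perm Permutations per test.
#' @param alpha Significance level of the increment rule.
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @return A `cluster_scan`: list with `per_k` (data frame `k`, `f_scaled`,
#'   `p_permutation`, `variance_fraction`), `increments` (data frame `k`,
#'   `gain`, `p_gain`), `selected_k`, `selected_by`, and `assignments`.
#' @export
select_k <- function(dm = NULL, y = NULL, k_max = 5,
                     method = c("upgma", "kmeans"),
                     n_perm = 199, alpha = 0.05, seed = 1, nstart = 10) {
  method <- match.arg(method)
  if (is.null(dm)) {
    if (is.null(y)) stop("supply a distance matrix 'dm' or data 'y'")
    dm <- compute_distance_matrix(y, "euclidean")
  } else {
    dm <- check_distance_matrix(dm)
  }
  if (method == "kmeans" && is.null(y)) {
    stop("k-means clustering needs the raw data matrix 'y'")
  }
  n <- nrow(dm)
  if (k_max < 2 || k_max >= n) stop("k_max must satisfy 2 <= k_max < N")
  p_vars <- if (!is.null(y)) ncol(y) else n  # df bookkeeping only
  g <- gower_center(dm)
  set.seed(seed)
  tree <- if (method == "upgma") upgma(dm) else NULL

  assignments <- vector("list", k_max)
  per_k <- data.frame(k = 2:k_max, f_scaled = NA_real_,
                      p_permutation = NA_real_,
                      variance_fraction = NA_real_, error = NA_character_)
  for (k in 2:k_max) {
    res <- tryCatch({
      asg <- if (method == "upgma") {
        cut_tree(tree, k)
      } else {
        km <- stats::kmeans(y, centers = k, nstart = nstart)
        structure(list(labels = canonical_labels(km$cluster),
                       k = as.integer(k), method = "kmeans",
                       linkage_heights = NULL),
                  class = "cluster_assignment")
      }
      assignments[[k]] <- asg
      x <- dummy_code(asg)
      proj <- build_projection(x)
      f <- pseudo_f(g, proj)
      sc <- scaled_f(f$f_raw, n = n, p = p_vars, m = proj$m)
      pt <- permutation_test(g, x, n_perm = n_perm)
      list(f_scaled = sc$f_scaled, p = pt$p_permutation,
           vf = f$tr_model / f$tr_total)
    }, error = function(e) e)
    i <- k - 1L
    if (inherits(res, "error")) {
      per_k$error[i] <- conditionMessage(res)
    } else {
      per_k$f_scaled[i] <- res$f_scaled
      per_k$p_permutation[i] <- res$p
      per_k$variance_fraction[i] <- res$vf
    }
  }

  increments <- if (k_max > 2) {
    data.frame(k = 2:(k_max - 1L), gain = NA_real_, p_gain = NA_real_)
  } else {
    data.frame(k = integer(0), gain = numeric(0), p_gain = numeric(0))
  }
  if (k_max > 2) {
    for (k in 2:(k_max - 1L)) {
      a_k <- assignments[[k]]; a_k1 <- assignments[[k + 1L]]
      if (is.null(a_k) || is.null(a_k1)) next
      inc <- tryCatch(
        incremental_gain_test(g, dummy_code(a_k), dummy_code(a_k1), n_perm),
        error = function(e) NULL)
      if (!is.null(inc)) {
        increments$gain[k - 1L] <- inc$gain
        increments$p_gain[k - 1L] <- inc$p_gain
      }
    }
  }

  # selection rule
  selected_by <- "increment_rule"
  p2 <- per_k$p_permutation[per_k$k == 2]
  if (!is.na(p2) && p2 > alpha) {
    selected_k <- 1L
    selected_by <- "no_k_significant"
  } else {
    selected_k <- NA_integer_
    for (k in increments$k) {
      pg <- increments$p_gain[increments$k == k]
      if (length(pg) == 1 && !is.na(pg) && pg > alpha) {
        selected_k <- as.integer(k)
        break
      }
    }
    if (is.na(selected_k)) {
      ok <- !is.na(per_k$f_scaled)
      selected_k <- as.integer(per_k$k[ok][which.max(per_k$f_scaled[ok])])
      selected_by <- "argmax_f"
    }
  }
  structure(list(per_k = per_k, increments = increments,
                 selected_k = selected_k, selected_by = selected_by,
                 assignments = assignments, method = method,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "cluster_scan")
}

# Marginal contribution of a second indicator block given a base block:
# gain = tr(H_[base,added] G) - tr(H_base G), tested by permuting the rows
# of the added block with the base block fixed.
incremental_gain_test <- function(g, x_base, x_added, n_perm = 199) {
  n <- nrow(g)
  tm_base <- pseudo_f(g, build_projection(x_base))$tr_model
  tm_full <- combined_model_trace(g, x_base, x_added)
  gain_obs <- tm_full - tm_base
  gains <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pi <- sample.int(n)
    gains[b] <- combined_model_trace(g, x_base, x_added[pi, , drop = FALSE]) -
      tm_base
  }
  tol <- 1e-8 * max(abs(gain_obs), 1)
  list(gain = gain_obs,
       p_gain = (1 + sum(gains >= gain_obs - tol)) / (n_perm + 1))
}

# tr(H G) for the combined design, tolerating rank deficiency (the QR drops
# redundant columns, so nested/overlapping blocks are handled).
combined_model_trace <- function(g, x_base, x_added) {
  x <- cbind(x_base, x_added)
  colnames(x) <- make.unique(c(colnames(x_base), colnames(x_added)))
  qrx <- qr(cbind(1, x), tol = 1e-10)
  q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  sum(tcrossprod(q) * g)
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat(sprintf("MDMR cluster-count scan (%s), k = 2..%d\n",
              x$method, max(x$per_k$k)))
  print(x$per_k[, c("k", "f_scaled", "p_permutation", "variance_fraction")],
        row.names = FALSE)
  if (nrow(x$increments) > 0 && any(!is.na(x$increments$p_gain))) {
    cat("increment tests (k vs k+1):\n")
    print(x$increments, row.names = FALSE)
  }
  cat(sprintf("selected k: %d (%s)\n", x$selected_k, x$selected_by))
  invisible(x)
}
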