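# Independent brute-force oracles used across the suite. These deliberately
# recompute quantities by definition (explicit matrix products, full
# enumeration) rather than through the package's own code paths.

# Gower centering by the literal definition C A C, C = I - 11'/N.
brute_gower <- function(d) {
  n <- nrow(d)
  a <- -0.5 * d^2
  c_mat <- diag(n) - matrix(1 / n, n, n)
  c_mat %*% a %*% c_mat
}

# Hat matrix by the textbook formula with an explicit inverse.
brute_hat <- function(x) {
  xf <- cbind(1, x)
  xf %*% solve(crossprod(xf)) %*% t(xf)
}

# Raw trace-ratio pseudo-F by literal triple products.
brute_f_raw <- function(g, x) {
  h <- brute_hat(x)
  n <- nrow(g)
  r <- diag(n) - h
  sum(diag(h %*% g %*% h)) / sum(diag(r %*% g %*% r))
}

# All n! index permutations (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# Exhaustive permutation p-value by enumerating every relabeling of the
# design rows and recomputing F from scratch (ties and duplicates counted
# with multiplicity, identity included).
brute_perm_p <- function(g, x, tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x)
  f_obs <- brute_f_raw(g, x)
  fs <- vapply(all_perms(n),
               function(pi) brute_f_raw(g, x[pi, , drop = FALSE]),
               numeric(1))
  mean(fs >= f_obs - tol)
}

# UPGMA by definition: recompute all average inter-cluster distances at
# every step; returns merge heights and the membership partition just
# before each merge (i.e. memberships at k = n, n-1, ..., 1 clusters).
brute_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- part
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, partitions = partitions)
}

# Random valid distance matrix: Euclidean distances of random points.
random_distance_matrix <- function(n, p = 3) {
  y <- matrix(rnorm(n * p), n, p)
  rownames(y) <- paste0("s", seq_len(n))
  compute_distance_matrix(y)
}

# Do two label vectors describe the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# The worked four-sample one-way layout used throughout.
anova_fixture <- function() {
  list(y = matrix(c(1, 2, 3, 5), ncol = 1,
                  dimnames = list(paste0("s", 1:4), "v1")),
       x = matrix(c(0, 0, 1, 1), ncol = 1,
                  dimnames = list(paste0("s", 1:4), "group")))
}
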