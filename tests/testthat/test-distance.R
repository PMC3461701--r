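test_that("distance measures reproduce hand-computed values", {
  y <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(compute_distance_matrix(y)["a", "b"], 5)
  expect_equal(compute_distance_matrix(y, "manhattan")["a", "b"], 7)

  y2 <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3.5))
  d2 <- compute_distance_matrix(y2, "pearson_corr")
  expect_equal(d2["a", "b"], 2)          # perfect anticorrelation: 1 - (-1)
  expect_equal(diag(d2), c(a = 0, b = 0, c = 0))
})

test_that("pairwise-complete distances are rescaled by shared-variable count", {
  y <- rbind(a = c(1, 2, NA, 4), b = c(2, 2, 5, NA))
  d <- compute_distance_matrix(y, "euclidean", min_shared_fraction = 0.5)
  expect_equal(d["a", "b"], sqrt((1 - 2)^2 + 0^2) * sqrt(4 / 2))
  dm <- compute_distance_matrix(y, "manhattan", min_shared_fraction = 0.5)
  expect_equal(dm["a", "b"], 1 * (4 / 2))
})

test_that("too little pairwise overlap and degenerate profiles error clearly", {
  y <- rbind(a = c(1, NA, NA, 4), b = c(NA, 2, 5, NA), c = 1:4)
  expect_error(compute_distance_matrix(y, min_shared_fraction = 0.5),
               "'a' and 'b'")
  yz <- rbind(a = c(2, 2, 2), b = c(1, 2, 3))
  expect_error(compute_distance_matrix(yz, "pearson_corr"),
               "zero variance")
  expect_error(compute_distance_matrix(matrix(1:3, 1, 3)), "2 samples")
})

test_that("gower_center matches the explicit C A C definition", {
  d <- matrix(c(0, 2, 2, 0), 2)
  g <- gower_center(d)
  expect_equal(unname(g), matrix(c(1, -1, -1, 1), 2))

  expect_equal(unname(gower_center(matrix(0, 3, 3))), matrix(0, 3, 3))

  set.seed(11)
  for (n in c(3, 5, 9)) {
    dm <- random_distance_matrix(n)
    g <- gower_center(dm)
    expect_equal(unname(g), brute_gower(dm), tolerance = 1e-12)
    expect_lt(max(abs(rowSums(g))), 1e-8)
    expect_lt(max(abs(colSums(g))), 1e-8)
    # quadratic scaling in the distances
    expect_equal(gower_center(3 * dm), 9 * g, tolerance = 1e-12)
    # conjugate permutation
    pi <- sample(n)
    expect_equal(unname(gower_center(dm[pi, pi])), unname(g[pi, pi]),
                 tolerance = 1e-12)
  }
})

test_that("trace of G equals the total sum of squares of centered data", {
  set.seed(4)
  y <- matrix(rnorm(12 * 7), 12, 7)
  g <- gower_center(compute_distance_matrix(y))
  tss <- sum(scale(y, scale = FALSE)^2)
  expect_equal(sum(diag(g)), tss, tolerance = 1e-8)
})

test_that("similarity transform maps distances onto [0, 1]", {
  d <- matrix(c(0, 4, 4, 0), 2)
  s <- similarity_from_distance(d)
  expect_equal(unname(s), matrix(c(1, 0, 0, 1), 2), ignore_attr = TRUE)
  expect_equal(attr(s, "max_distance_used"), 4)

  s2 <- similarity_from_distance(matrix(c(0, 2, 2, 0), 2), max_distance = 4)
  expect_equal(s2[1, 2], 0.5)
  expect_equal(diag(s2), c(1, 1), ignore_attr = TRUE)

  expect_error(similarity_from_distance(matrix(0, 3, 3)), "undefined")
  expect_error(similarity_from_distance(d, max_distance = -1), "positive")
})

test_that("distance matrix CSV round-trips to 1e-12 and rejects bad input", {
  set.seed(9)
  dm <- random_distance_matrix(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_matrix(dm, path)
  back <- read_distance_matrix(path)
  expect_equal(unname(back), unname(as.matrix(dm)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(dm))

  bad <- unclass(as.matrix(dm))
  bad[1, 2] <- bad[1, 2] + 1e-3    # asymmetry beyond tolerance
  path2 <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(id = rownames(dm), bad)
  names(df)[1] <- ""
  colnames(df)[-1] <- rownames(dm)
  utils::write.table(df, path2, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_distance_matrix(path2), "asymmetric")

  expect_error(read_distance_matrix("no/such/file.csv"), "not found")
})

test_that("samples are aligned by ID, not by row order", {
  set.seed(21)
  y <- matrix(rnorm(8 * 5), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("v", 1:5)))
  x <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), ncol = 1,
              dimnames = list(paste0("s", 1:8), "group"))
  ref <- mdmr(x, y = y, n_perm = 99, seed = 5)
  shuffled <- x[sample(8), , drop = FALSE]
  fit <- mdmr(shuffled, y = y, n_perm = 99, seed = 5)
  expect_equal(fit$f_raw, ref$f_raw, tolerance = 1e-12)
  expect_equal(fit$p_permutation, ref$p_permutation)

  rownames(shuffled)[1] <- "zz"
  expect_error(mdmr(shuffled, y = y, n_perm = 9), "IDs")
})
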