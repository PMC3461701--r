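test_that("projection onto a two-group design is the block-averaging matrix", {
  proj <- build_projection(matrix(c(0, 0, 1, 1), ncol = 1))
  block <- matrix(0.5, 2, 2)
  expect_equal(unname(proj$h),
               rbind(cbind(block, matrix(0, 2, 2)),
                     cbind(matrix(0, 2, 2), block)),
               tolerance = 1e-12)
  expect_equal(proj$rank, 2L)
  expect_length(proj$dropped_columns, 0)
})

test_that("duplicated regressors are dropped and reported, H unchanged", {
  set.seed(2)
  x1 <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "a"))
  x2 <- cbind(x1, b = x1[, 1])
  p1 <- build_projection(x1)
  p2 <- build_projection(x2)
  expect_equal(p2$h, p1$h, tolerance = 1e-10)
  expect_identical(p2$dropped_columns, "b")
  expect_equal(p2$m, 1L)
})

test_that("projectors are symmetric and idempotent; degenerate designs error", {
  set.seed(3)
  for (m in 1:3) {
    x <- matrix(rnorm(12 * m), 12, m)
    h <- build_projection(x)$h
    expect_lt(max(abs(h - t(h))), 1e-10)
    expect_lt(max(abs(h %*% h - h)), 1e-8)
    expect_lt(max(abs(h %*% cbind(1, x) - cbind(1, x))), 1e-8)
  }
  expect_error(build_projection(matrix(1, 5, 1)), "constant")
  expect_error(build_projection(matrix(rnorm(6), 3, 2)), "more samples")
})

test_that("pseudo-F reproduces one-way ANOVA sums of squares", {
  fx <- anova_fixture()
  g <- gower_center(compute_distance_matrix(fx$y))
  f <- pseudo_f(g, build_projection(fx$x))
  expect_equal(f$tr_model, 6.25)
  expect_equal(f$tr_residual, 2.5)
  expect_equal(f$f_raw, 2.5)
})

test_that("trace shortcuts equal the literal triple products", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(6:15, 1)
    y <- matrix(rnorm(n * 4), n, 4)
    x <- matrix(rnorm(n * 2), n, 2)
    g <- gower_center(compute_distance_matrix(y))
    proj <- build_projection(x)
    f <- pseudo_f(g, proj)
    h <- proj$h
    r <- diag(n) - h
    expect_equal(f$tr_model, sum(diag(h %*% g %*% h)), tolerance = 1e-8)
    expect_equal(f$tr_residual, sum(diag(r %*% g %*% r)), tolerance = 1e-8)
    expect_equal(f$tr_model + f$tr_residual, sum(diag(g)), tolerance = 1e-8)
  }
})

test_that("saturated models with zero residual distance error", {
  y <- matrix(c(0, 0, 1, 1, 1, 1, 0, 0), ncol = 2)
  x <- matrix(c(0, 0, 1, 1), ncol = 1)
  g <- gower_center(compute_distance_matrix(y))
  expect_error(pseudo_f(g, build_projection(x)), "saturated")
})

test_that("degrees of freedom follow the variable-scaled rule", {
  expect_equal(scaled_f(1, n = 10, p = 1)[c("df1", "df2")],
               list(df1 = 1L, df2 = 8L))
  expect_equal(scaled_f(1, n = 100, p = 10)[c("df1", "df2")],
               list(df1 = 10L, df2 = 998L))
  sc <- scaled_f(2.5, n = 4, p = 1)
  expect_equal(sc$f_scaled, 5)
  expect_false(sc$extrapolated_df)
  expect_true(scaled_f(1, n = 10, p = 2, m = 3)$extrapolated_df)
  expect_error(scaled_f(1, n = 2, p = 1), "degrees of freedom")
})

test_that("analytic p-value is the F upper tail", {
  # closed form via t with 2 df: p = 2 P(T_2 > sqrt(5))
  expect_equal(analytic_pvalue(5, 1, 2), 2 * pt(sqrt(5), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(analytic_pvalue(5, 1, 2), 4), 0.1548)
  expect_equal(analytic_pvalue(0, 3, 10), 1)
  expect_lt(analytic_pvalue(1e8, 3, 10), 1e-10)
})

test_that("exhaustive permutation test enumerates all relabelings", {
  fx <- anova_fixture()
  g <- gower_center(compute_distance_matrix(fx$y))
  pt_res <- permutation_test(g, fx$x, n_perm = 999)
  expect_true(pt_res$exhaustive)
  expect_equal(pt_res$n_arrangements, 6L)
  expect_equal(pt_res$p_permutation, 2 / 6)
  expect_equal(sort(round(pt_res$null_f, 3)),
               c(0.029, 0.029, 0.346, 0.346, 2.5, 2.5))

  # observed statistic at the null minimum: every permutation is >= it
  x_min <- matrix(c(0, 1, 1, 0), ncol = 1)
  expect_equal(permutation_test(g, x_min, n_perm = 999)$p_permutation, 1)
})

test_that("exhaustive p matches full brute-force enumeration", {
  set.seed(13)
  for (i in 1:3) {
    n <- 5
    y <- matrix(rnorm(n * 3), n, 3)
    x <- matrix(rnorm(n), ncol = 1)
    g <- gower_center(compute_distance_matrix(y))
    res <- permutation_test(g, x, n_perm = 999)  # 5! = 120 <= 999
    expect_true(res$exhaustive)
    expect_equal(res$p_permutation, brute_perm_p(g, x), tolerance = 1e-12)
  }
})

test_that("sampled permutation p converges to the exhaustive p", {
  set.seed(17)
  n <- 6
  y <- matrix(rnorm(n * 3), n, 3)
  x <- matrix(rnorm(n), ncol = 1)
  g <- gower_center(compute_distance_matrix(y))
  p_ex <- permutation_test(g, x, n_perm = 720)$p_permutation  # exhaustive
  res <- permutation_test(g, x, n_perm = 600, seed = 99)       # sampled
  expect_false(res$exhaustive)
  se <- sqrt(p_ex * (1 - p_ex) / 600)
  expect_lt(abs(res$p_permutation - p_ex), 3 * se + 1 / 601)
})

test_that("permutation test is reproducible from its seed", {
  set.seed(31)
  y <- matrix(rnorm(20 * 5), 20, 5)
  x <- matrix(rnorm(20), ncol = 1)
  g <- gower_center(compute_distance_matrix(y))
  r1 <- permutation_test(g, x, n_perm = 99, seed = 7)
  r2 <- permutation_test(g, x, n_perm = 99, seed = 7)
  expect_identical(r1$p_permutation, r2$p_permutation)
  expect_identical(r1$null_f, r2$null_f)
})

test_that("MDMR equals classical one-way ANOVA for P = 1", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(6:14, 1)
    y <- rnorm(n)
    grp <- rbinom(n, 1, 0.5)
    if (length(unique(grp)) < 2) grp[1] <- 1 - grp[1]
    fit <- mdmr(matrix(grp, ncol = 1), y = matrix(y, ncol = 1), n_perm = 1)
    an <- anova(lm(y ~ grp))
    expect_equal(fit$f_scaled, an$`F value`[1], tolerance = 1e-8)
    expect_equal(fit$p_analytic, an$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("scaled F and variance fraction match vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(29)
  y <- matrix(rnorm(25 * 8), 25, 8)
  x <- rnorm(25)
  fit <- mdmr(matrix(x, ncol = 1), y = y, n_perm = 9)
  av <- vegan::adonis2(dist(y) ~ x, permutations = 99)
  expect_equal(fit$f_scaled, av$F[1], tolerance = 1e-10)
  expect_equal(fit$variance_fraction, av$R2[1], tolerance = 1e-10)
})

test_that("results are invariant to distance scale, regressor affine maps, and relabeling", {
  set.seed(37)
  n <- 16
  y <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(paste0("s", 1:n), paste0("v", 1:6)))
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(paste0("s", 1:n), "z"))
  d <- compute_distance_matrix(y)
  ref <- mdmr(x, d = d, p_variables = 6, n_perm = 99, seed = 11)

  scaled <- mdmr(x, d = 3 * unclass(as.matrix(d)), p_variables = 6,
                 n_perm = 99, seed = 11)
  expect_equal(scaled$f_raw, ref$f_raw, tolerance = 1e-10)
  expect_identical(scaled$p_permutation, ref$p_permutation)
  expect_equal(scaled$p_analytic, ref$p_analytic, tolerance = 1e-10)

  affine <- mdmr(2.5 * x - 7, d = d, p_variables = 6, n_perm = 99, seed = 11)
  expect_equal(affine$f_raw, ref$f_raw, tolerance = 1e-10)
  expect_identical(affine$p_permutation, ref$p_permutation)

  pi <- sample(n)
  relabeled <- mdmr(x[pi, , drop = FALSE], d = d[pi, pi], p_variables = 6,
                    n_perm = 99, seed = 11)
  expect_equal(relabeled$f_raw, ref$f_raw, tolerance = 1e-10)
  expect_equal(relabeled$p_analytic, ref$p_analytic, tolerance = 1e-10)
})

test_that("variance fraction partitions the total for Euclidean distances", {
  set.seed(41)
  y <- matrix(rnorm(30 * 10), 30, 10)
  x <- matrix(rnorm(30 * 2), 30, 2)
  fit <- mdmr(x, y = y, n_perm = 49)
  expect_gte(fit$variance_fraction, 0)
  expect_lte(fit$variance_fraction, 1)
})

test_that("per-regressor marginal tests match single-column fits", {
  set.seed(43)
  y <- matrix(rnorm(20 * 5), 20, 5)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  fit <- mdmr(x, y = y, n_perm = 49, seed = 3, per_regressor = TRUE)
  solo <- mdmr(x[, "a", drop = FALSE], y = y, n_perm = 49, seed = 3)
  expect_equal(fit$per_regressor$f_raw[fit$per_regressor$predictor == "a"],
               solo$f_raw, tolerance = 1e-12)
  expect_true(fit$extrapolated_df)
})

test_that("JSON serialization carries the full result", {
  fx <- anova_fixture()
  fit <- mdmr(fx$x, y = fx$y, n_perm = 99, seed = 1)
  js <- jsonlite::fromJSON(mdmr_to_json(fit))
  expect_equal(js$f_scaled, 5)
  expect_equal(js$p_permutation, 1 / 3, tolerance = 1e-12)
  expect_equal(js$seed, 1)
})
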