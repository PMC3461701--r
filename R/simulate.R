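#' Specification of a synthetic MDMR dataset
#'
#' Describes one simulated study condition: the marginal distribution family
#' of the P outcome variables, the sample size, the predictor type, and the
#' effect structure (a per-group mean shift for dichotomous predictors, a
#' target correlation for continuous predictors). All families are
#' standardized to mean 0 and unit variance before any shift is applied, so
#' shifts are in standard-deviation units.
#'
#' Families: `normal` (iid standard normal), `bimodal` (equal mixture of
#' N(-1, 0.5^2) and N(1, 0.5^2), standardized), `lognormal` (exp of a
#' standard normal, standardized), `mvn_equicorr` (equicorrelated
#' multivariate normal with correlation `correlation`).
#'
#' @param family Distribution family (see above).
#' @param n Number of samples.
#' @param p Number of outcome variables.
#' @param shift Group mean offset, in SD units (dichotomous designs).
#' @param shifted_fraction Fraction of the P variables receiving the shift;
#'   the first `ceiling(shifted_fraction * p)` variables are affected.
#' @param correlation Equicorrelation parameter (for `mvn_equicorr`).
#' @param regressor_type `"dichotomous"` (first `floor(n/2)` samples coded
#'   0, remainder 1) or `"continuous"` (standard normal regressor).
#' @param regressor_corr For continuous designs, the target correlation
#'   between the regressor and each affected variable.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(family = c("normal", "bimodal", "lognormal",
                                      "mvn_equicorr"),
                           n, p, shift = 0, shifted_fraction = 1,
                           correlation = 0,
                           regressor_type = c("dichotomous", "continuous"),
                           regressor_corr = 0) {
  family <- match.arg(family)
  regressor_type <- match.arg(regressor_type)
  stopifnot(n >= 2, p >= 1,
            shifted_fraction >= 0, shifted_fraction <= 1,
            correlation >= 0, correlation < 1,
            regressor_corr > -1, regressor_corr < 1)
  structure(list(family = family, n = as.integer(n), p = as.integer(p),
                 shift = shift, shifted_fraction = shifted_fraction,
                 correlation = correlation, regressor_type = regressor_type,
                 regressor_corr = regressor_corr),
            class = "generator_spec")
}

# One n x p draw from the standardized family (mean 0, variance 1 per
# variable, before any effect is added).
draw_family <- function(family, n, p, correlation = 0) {
  switch(family,
    normal = matrix(stats::rnorm(n * p), n, p),
    bimodal = {
      centers <- sample(c(-1, 1), n * p, replace = TRUE)
      raw <- centers + stats::rnorm(n * p, sd = 0.5)
      matrix(raw / sqrt(1.25), n, p)  # mixture variance 1 + 0.25
    },
    lognormal = {
      raw <- exp(matrix(stats::rnorm(n * p), n, p))
      (raw - exp(0.5)) / sqrt((exp(1) - 1) * exp(1))
    },
    mvn_equicorr = {
      common <- stats::rnorm(n)
      sqrt(correlation) * common +
        sqrt(1 - correlation) * matrix(stats::rnorm(n * p), n, p)
    })
}

#' Generate one synthetic dataset
#'
#' Draws outcome data and a predictor according to a [generator_spec()].
#' Dichotomous designs add `shift` to the affected variables of the coded-1
#' group; continuous designs build each affected variable as
#' `regressor_corr * z + sqrt(1 - regressor_corr^2) * noise` with `z` the
#' standard-normal regressor.
#'
#' @param spec A `generator_spec`.
#' @param seed Optional integer seed (caller's RNG state restored on exit).
#' @return List with `y` (N x P data matrix) and `x` (N x 1 design matrix).
#' @export
generate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  n <- spec$n; p <- spec$p
  n_aff <- ceiling(spec$shifted_fraction * p)
  if (spec$regressor_type == "dichotomous") {
    y <- draw_family(spec$family, n, p, spec$correlation)
    x <- c(rep(0, floor(n / 2)), rep(1, n - floor(n / 2)))
    if (spec$shift != 0 && n_aff > 0) {
      y[x == 1, seq_len(n_aff)] <- y[x == 1, seq_len(n_aff)] + spec$shift
    }
    xm <- matrix(x, ncol = 1, dimnames = list(NULL, "group"))
  } else {
    z <- stats::rnorm(n)
    y <- draw_family(spec$family, n, p, spec$correlation)
    if (spec$regressor_corr != 0 && n_aff > 0) {
      r <- spec$regressor_corr
      y[, seq_len(n_aff)] <- r * z + sqrt(1 - r^2) * y[, seq_len(n_aff)]
    }
    xm <- matrix(z, ncol = 1, dimnames = list(NULL, "z"))
  }
  ids <- paste0("s", seq_len(n))
  dimnames(y) <- list(ids, paste0("v", seq_len(p)))
  rownames(xm) <- ids
  list(y = y, x = xm)
}

# Shared inner loop: simulate n_sims null/effect datasets under `spec` and
# return the requested p-values. method: "permutation", "analytic", "both".
simulate_pvalues <- function(spec, n_sims, n_perm, method = "permutation") {
  p_perm <- p_analytic <- rep(NA_real_, n_sims)
  for (s in seq_len(n_sims)) {
    ds <- generate_dataset(spec)
    d <- compute_distance_matrix(ds$y, "euclidean")
    g <- gower_center(d)
    proj <- build_projection(ds$x)
    if (method %in% c("analytic", "both")) {
      f <- pseudo_f(g, proj)
      sc <- scaled_f(f$f_raw, n = spec$n, p = spec$p, m = proj$m)
      p_analytic[s] <- analytic_pvalue(sc$f_scaled, sc$df1, sc$df2)
    }
    if (method %in% c("permutation", "both")) {
      pt <- permutation_test(g, ds$x, n_perm = n_perm)
      p_perm[s] <- pt$p_permutation
    }
  }
  list(permutation = p_perm, analytic = p_analytic)
}

binom_se <- function(rate, n) sqrt(rate * (1 - rate) / n)

#' Level-accuracy experiment (null rejection rates)
#'
#' Monte-Carlo study of how closely the empirical null rejection rate of the
#' MDMR test matches its nominal level, as a function of sample size, for a
#' permutation or analytic F-distribution p-value and a dichotomous or
#' continuous predictor. Data are iid standard normal, so the null holds.
#'
#' @param n_grid Sample sizes to study.
#' @param p Number of outcome variables.
#' @param regressor_type `"dichotomous"` or `"continuous"`.
#' @param method `"permutation"` or `"analytic"`.
#' @param levels Nominal levels (fractions).
#' @param n_sims Simulations per sample size.
#' @param n_perm Permutations per simulation.
#' @param seed Integer seed; the whole table is reproducible from it.
#' @return Data frame with columns `n`, `level`, `rate`, `se` (binomial
#'   standard error) plus metadata attributes `n_sims`, `n_perm`, `method`,
#'   `regressor_type`, `seed`.
#' @export
level_accuracy_experiment <- function(n_grid = c(100, 50, 20, 10, 4),
                                      p = 10,
                                      regressor_type = "dichotomous",
                                      method = c("permutation", "analytic"),
                                      levels = c(0.01, 0.05, 0.10, 0.25,
                                                 0.50, 0.75),
                                      n_sims = 1000, n_perm = 200,
                                      seed = 1) {
  method <- match.arg(method)
  set.seed(seed)
  rows <- list()
  for (n in n_grid) {
    spec <- generator_spec("normal", n = n, p = p,
                           regressor_type = regressor_type)
    pv <- simulate_pvalues(spec, n_sims, n_perm, method)[[method]]
    for (lv in levels) {
      rate <- mean(pv <= lv)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, level = lv, rate = rate, se = binom_se(rate, n_sims))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_sims") <- n_sims; attr(out, "n_perm") <- n_perm
  attr(out, "method") <- method; attr(out, "regressor_type") <- regressor_type
  attr(out, "seed") <- seed
  out
}

#' Power of MDMR versus effect size (mean shift)
#'
#' For each combination of shift and shifted fraction, simulates two-group
#' data (half the samples receive the shift on the affected variables) and
#' records the fraction of permutation tests rejecting at `alpha`.
#'
#' @param shifts Grid of mean shifts, in SD units.
#' @param shifted_fractions Fractions of the P variables carrying the shift.
#' @param n,p Sample size and number of variables.
#' @param alpha Rejection level.
#' @param n_sims,n_perm Monte-Carlo sizes.
#' @param seed Integer seed.
#' @return Data frame `(shifted_fraction, shift, power, se)` with attribute
#'   `thresholds`: per fraction, the smallest grid shift whose empirical
#'   power reaches 0.80 (`NA` if never reached).
#' @export
power_experiment <- function(shifts = seq(0, 1, by = 0.02),
                             shifted_fractions = 1,
                             n = 30, p = 100, alpha = 0.05,
                             n_sims = 500, n_perm = 200, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (fr in shifted_fractions) {
    for (sh in shifts) {
      spec <- generator_spec("normal", n = n, p = p, shift = sh,
                             shifted_fraction = fr)
      pv <- simulate_pvalues(spec, n_sims, n_perm, "permutation")$permutation
      pow <- mean(pv <= alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        shifted_fraction = fr, shift = sh, power = pow,
        se = binom_se(pow, n_sims))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- power_thresholds(out, "shifted_fraction", "shift")
  attr(out, "n_sims") <- n_sims; attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha; attr(out, "seed") <- seed
  out
}

# Smallest grid value of `xcol` with power >= target, per group.
power_thresholds <- function(df, group_col, xcol, target = 0.8) {
  res <- lapply(split(df, df[[group_col]]), function(gdf) {
    ok <- gdf[[xcol]][gdf$power >= target]
    if (length(ok) == 0) NA_real_ else min(ok)
  })
  data.frame(group = as.numeric(names(res)),
             threshold = unlist(res), row.names = NULL)
}

#' Bonferroni-corrected univariate t-test comparator
#'
#' Familywise power of running a two-sided two-sample t-test per variable
#' and rejecting globally when any p-value falls below `alpha / p`, under
#' the same shifted-group generator as [power_experiment()].
#'
#' @inheritParams power_experiment
#' @return Data frame `(shift, power, se)` with a `thresholds` attribute
#'   (smallest grid shift with familywise power >= 0.80).
#' @export
bonferroni_t_comparator <- function(shifts = seq(0, 1, by = 0.02),
                                    shifted_fractions = 1,
                                    n = 30, p = 100, alpha = 0.05,
                                    n_sims = 500, seed = 1) {
  set.seed(seed)
  n0 <- floor(n / 2); n1 <- n - n0
  crit <- alpha / p
  rows <- list()
  for (fr in shifted_fractions) {
    for (sh in shifts) {
      spec <- generator_spec("normal", n = n, p = p, shift = sh,
                             shifted_fraction = fr)
      rej <- logical(n_sims)
      for (s in seq_len(n_sims)) {
        ds <- generate_dataset(spec)
        grp <- ds$x[, 1] == 1
        y0 <- ds$y[!grp, , drop = FALSE]; y1 <- ds$y[grp, , drop = FALSE]
        m0 <- colMeans(y0); m1 <- colMeans(y1)
        v0 <- colSums(sweep(y0, 2, m0)^2); v1 <- colSums(sweep(y1, 2, m1)^2)
        sp2 <- (v0 + v1) / (n - 2)
        tstat <- (m1 - m0) / sqrt(sp2 * (1 / n0 + 1 / n1))
        pvals <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
        rej[s] <- any(pvals <= crit)
      }
      pow <- mean(rej)
      rows[[length(rows) + 1L]] <- data.frame(
        shifted_fraction = fr, shift = sh, power = pow,
        se = binom_se(pow, n_sims))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- power_thresholds(out, "shifted_fraction", "shift")
  attr(out, "n_sims") <- n_sims; attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  out
}

#' Closed-form familywise power of the Bonferroni t comparator
#'
#' For independent variables that all carry the same shift, the familywise
#' power has the closed form `1 - (1 - pi1)^p`, where `pi1` is the power of
#' a single pooled two-sample t-test at level `alpha / p` with noncentrality
#' `shift * sqrt(n0 n1 / n)`.
#'
#' @param shift Mean shift in SD units.
#' @param n Total sample size (split `floor(n/2)` vs the rest).
#' @param p Number of variables (and tests).
#' @param alpha Familywise level before Bonferroni division.
#' @return Familywise power.
#' @export
bonferroni_t_power <- function(shift, n = 30, p = 100, alpha = 0.05) {
  n0 <- floor(n / 2); n1 <- n - n0
  crit <- stats::qt(1 - alpha / p / 2, df = n - 2)
  ncp <- shift * sqrt(n0 * n1 / n)
  pi1 <- stats::pt(crit, df = n - 2, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, df = n - 2, ncp = ncp)
  1 - (1 - pi1)^p
}

#' Power of MDMR versus sample size
#'
#' @param n_grid Sample sizes (half of each assigned to each group).
#' @param shifts Common mean shifts applied to all `p` variables of the
#'   experimental group.
#' @inheritParams power_experiment
#' @return Data frame `(shift, n, power, se)`.
#' @export
power_vs_n_experiment <- function(n_grid = c(10, 20, 30, 40, 50, 75, 100),
                                  p = 100, shifts = c(0.1, 0.2, 0.3),
                                  alpha = 0.05, n_sims = 500, n_perm = 200,
                                  seed = 1) {
  set.seed(seed)
  rows <- list()
  for (sh in shifts) {
    for (n in n_grid) {
      spec <- generator_spec("normal", n = n, p = p, shift = sh)
      pv <- simulate_pvalues(spec, n_sims, n_perm, "permutation")$permutation
      pow <- mean(pv <= alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        shift = sh, n = n, power = pow, se = binom_se(pow, n_sims))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_sims") <- n_sims; attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha; attr(out, "seed") <- seed
  out
}

#' Power of MDMR with a continuous regressor
#'
#' The regressor is standard normal and correlated at strength
#' `regressor_corr` with a fraction of the P variables.
#'
#' @param regressor_corrs Correlation strengths.
#' @param fractions Fractions of variables correlated with the regressor.
#' @inheritParams power_experiment
#' @return Data frame `(regressor_corr, fraction, power, se)`.
#' @export
continuous_power_experiment <- function(regressor_corrs = c(0.1, 0.2, 0.3, 0.4),
                                        fractions = c(0, 0.05, 0.10, 0.15,
                                                      0.25, 0.50, 1),
                                        n = 100, p = 100, alpha = 0.05,
                                        n_sims = 500, n_perm = 200, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (rc in regressor_corrs) {
    for (fr in fractions) {
      spec <- generator_spec("normal", n = n, p = p,
                             shifted_fraction = fr,
                             regressor_type = "continuous",
                             regressor_corr = rc)
      pv <- simulate_pvalues(spec, n_sims, n_perm, "permutation")$permutation
      pow <- mean(pv <= alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        regressor_corr = rc, fraction = fr, power = pow,
        se = binom_se(pow, n_sims))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_sims") <- n_sims; attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha; attr(out, "seed") <- seed
  out
}

#' Agreement between permutation and analytic p-values
#'
#' Records both p-values for each simulated null dataset and summarizes
#' their Pearson correlation, overall and stratified by small versus larger
#' sample sizes (agreement degrades markedly for N <= 8).
#'
#' @param n_range Length-2 range of sample sizes to draw uniformly (a
#'   single value fixes N).
#' @param p_range Length-2 range for the number of variables.
#' @param regressor_type Predictor type for all simulations.
#' @inheritParams power_experiment
#' @return List with `pairs` (data frame `n`, `p`, `p_permutation`,
#'   `p_analytic`), `r_overall`, `r_small` (N <= 8), `r_large` (N > 8);
#'   correlations are `NA` when a stratum is empty or degenerate.
#' @export
pvalue_agreement_study <- function(n_range = c(4, 100), p_range = c(1, 100),
                                   regressor_type = "dichotomous",
                                   n_sims = 1000, n_perm = 200, seed = 1) {
  set.seed(seed)
  n_lo <- min(n_range); n_hi <- max(n_range)
  p_lo <- min(p_range); p_hi <- max(p_range)
  out <- data.frame(n = integer(n_sims), p = integer(n_sims),
                    p_permutation = numeric(n_sims),
                    p_analytic = numeric(n_sims))
  for (s in seq_len(n_sims)) {
    n <- if (n_lo == n_hi) n_lo else sample(n_lo:n_hi, 1)
    p <- if (p_lo == p_hi) p_lo else sample(p_lo:p_hi, 1)
    spec <- generator_spec("normal", n = n, p = p,
                           regressor_type = regressor_type)
    ds <- generate_dataset(spec)
    d <- compute_distance_matrix(ds$y, "euclidean")
    g <- gower_center(d)
    proj <- build_projection(ds$x)
    f <- pseudo_f(g, proj)
    sc <- scaled_f(f$f_raw, n = n, p = p, m = proj$m)
    out$n[s] <- n; out$p[s] <- p
    out$p_analytic[s] <- analytic_pvalue(sc$f_scaled, sc$df1, sc$df2)
    out$p_permutation[s] <- permutation_test(g, ds$x,
                                             n_perm = n_perm)$p_permutation
  }
  safe_cor <- function(a, b) {
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  small <- out$n <= 8
  list(pairs = out,
       r_overall = safe_cor(out$p_permutation, out$p_analytic),
       r_small = safe_cor(out$p_permutation[small], out$p_analytic[small]),
       r_large = safe_cor(out$p_permutation[!small], out$p_analytic[!small]),
       n_sims = n_sims, n_perm = n_perm, seed = seed)
}
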