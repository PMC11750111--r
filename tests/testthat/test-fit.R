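two_cond_qt <- function(n = 50, seed = 1, times = c(0, 45, 90, 135, 180),
                        reps = 1:3) {
  set.seed(seed)
  cols <- design_cols(times = times, reps = reps)
  v <- matrix(rnorm(n * length(cols)), n,
              dimnames = list(sprintf("f%03d", seq_len(n)), cols))
  quant_table(v)
}

test_that("cell means and residual sums of squares are exact", {
  cols <- sprintf("control_0min_R%d", 1:3)
  v <- matrix(c(1.0, 1.2, 0.8), 1, dimnames = list("f", cols))
  qt <- quant_table(cbind(v, matrix(c(2, 2, 2), 1, 3,
                                    dimnames = list("f", sprintf("control_45min_R%d", 1:3)))))
  d <- design_spec(qt)
  f <- phos_fit(qt, d, stepwise_contrasts(d, "control"), moderate = FALSE)
  expect_equal(unname(f$cell_means[1, "control.0min"]), 1.0)
  expect_equal(unname(f$sigma2[1] * f$df_residual[1]), 0.08)
  expect_equal(unname(f$df_residual[1]), 4)  # 6 obs - 2 cells
})

test_that("noiseless synthetic data has zero residual variance", {
  cfg <- sim_config(n_sites = 40, noise_sd = 0, batch_sd = 0,
                    missing_rate = 0, replicate_dropout_rate = 0,
                    redundancy_rate = 0, seed = 6)
  sim <- simulate_experiment(cfg)
  d <- design_spec(sim$phospho)
  f <- phos_fit(sim$phospho, d, stepwise_contrasts(d, "mating", "control"),
                moderate = FALSE)
  expect_true(all(f$sigma2 < 1e-20))
  # and moderation refuses such input
  expect_error(phos_fit(sim$phospho, d, stepwise_contrasts(d, "mating", "control")),
               "noiseless")
})

test_that("cell means agree with a normal-equations least-squares oracle", {
  qt <- two_cond_qt(n = 50, seed = 42)
  qt$values[sample(length(qt$values), 60)] <- NA
  d <- design_spec(qt)
  f <- phos_fit(qt, d, stepwise_contrasts(d, "mating", "control"),
                moderate = FALSE)
  X_full <- model.matrix(~0 + factor(d$assign, levels = seq_along(d$labels)))
  colnames(X_full) <- d$labels
  for (i in seq_len(nrow(qt$values))) {
    y <- qt$values[i, ]
    obs <- !is.na(y)
    X <- X_full[obs, colSums(X_full[obs, , drop = FALSE]) > 0, drop = FALSE]
    beta <- solve(crossprod(X), crossprod(X, y[obs]))
    got <- f$cell_means[i, colnames(X)]
    expect_equal(unname(got), unname(drop(beta)), tolerance = 1e-10)
  }
})

test_that("difference-of-differences contrasts follow the printed arithmetic", {
  cols <- design_cols(times = c(0, 45), reps = 1)
  v <- matrix(c(0.1, 0.4, 0.0, 1.2), 1, dimnames = list("f", cols))
  qt <- quant_table(v)
  d <- design_spec(qt)
  C <- stepwise_contrasts(d, "mating", baseline = "control")
  f <- phos_fit(qt, d, C, moderate = FALSE)
  # (Mating.45 - Mating.0) - (Ctrl.45 - Ctrl.0) = (1.2 - 0.0) - (0.4 - 0.1)
  expect_equal(unname(f$coefficients[1, "Diff_45-0"]), 0.9)
  expect_true(all(abs(colSums(C)) < 1e-12))
})

test_that("identical profiles in both conditions cancel in Diff contrasts", {
  profile <- c(0, 1, 2, 2.5, 3)
  cols <- design_cols(reps = 1)
  v <- matrix(rep(profile, 2), 1, dimnames = list("f", cols))
  qt <- quant_table(v)
  d <- design_spec(qt)
  fd <- phos_fit(qt, d, stepwise_contrasts(d, "mating", "control"),
                 moderate = FALSE)
  fc <- phos_fit(qt, d, stepwise_contrasts(d, "control", prefix = "Ctrl"),
                 moderate = FALSE)
  expect_true(all(abs(fd$coefficients) < 1e-12))
  expect_true(any(abs(fc$coefficients) > 0.4))
})

test_that("variance squeezing matches the plug-in formula and its limit", {
  # plug-in identity: d0=4, s0^2=1, d=4, s^2=3 -> posterior 2
  expect_equal(squeeze_var(3, 4, df_prior = 4, var_prior = 1)$var_post, 2)
  # d0 -> infinity limit: posterior equals the prior for every feature
  expect_equal(squeeze_var(c(0.5, 3, 9), c(4, 4, 4), df_prior = Inf,
                           var_prior = 1.3)$var_post, rep(1.3, 3))
  # near-equal variances drive d0 to (effectively) infinity
  set.seed(2)
  s2 <- rep(1, 200) * exp(rnorm(200, 0, 1e-8))
  m <- squeeze_var(s2, rep(10, 200))
  expect_gt(m$df_prior, 1e5)
  expect_equal(unique(round(m$var_post, 6)),
               round(m$var_prior, 6))
})

test_that("prior variance is recovered within 10% on simulated data", {
  set.seed(77)
  d0 <- 8; s02 <- 0.04; df <- 20; n <- 5000
  true_var <- s02 * d0 / rchisq(n, d0)       # scaled inverse chi-square prior
  s2 <- true_var * rchisq(n, df) / df
  m <- squeeze_var(s2, rep(df, n))
  expect_equal(m$var_prior, s02, tolerance = 0.1)
  expect_equal(m$df_prior, d0, tolerance = 0.25 * d0)
})

test_that("moderation matches limma's empirical Bayes exactly", {
  skip_if_not_installed("limma")
  sim <- simulate_experiment(sim_config(n_sites = 300, missing_rate = 0,
                                        replicate_dropout_rate = 0,
                                        redundancy_rate = 0, seed = 3))
  x <- median_center_by_replicate(sim$phospho)
  d <- design_spec(x)
  C <- stepwise_contrasts(d, "mating", baseline = "control")
  f <- phos_fit(x, d, C)
  des <- stats::model.matrix(~0 + factor(d$assign))
  colnames(des) <- d$labels
  eb <- limma::eBayes(limma::contrasts.fit(limma::lmFit(x$values, des), C))
  expect_equal(f$moderation$df_prior, eb$df.prior, tolerance = 1e-8)
  expect_equal(f$moderation$var_prior, eb$s2.prior, tolerance = 1e-8)
  expect_equal(unname(f$coefficients), unname(eb$coefficients), tolerance = 1e-10)
  expect_equal(unname(f$F), unname(eb$F), tolerance = 1e-8)
  expect_equal(unname(f$p_value), unname(eb$F.p.value), tolerance = 1e-8)
})

test_that("moderated F handles degenerate and single-contrast cases", {
  cols <- design_cols(times = c(0, 45), reps = 1:3)
  set.seed(4)
  v <- matrix(rnorm(20 * 12, sd = 0.3), 20, dimnames = list(sprintf("f%02d", 1:20), cols))
  # feature 1: identical cell means, non-zero residuals
  v[1, ] <- rep(c(1, 1, 1, 1), each = 3) + rep(c(-0.1, 0, 0.1), 4)
  qt <- quant_table(v)
  d <- design_spec(qt)
  C <- stepwise_contrasts(d, "mating", baseline = "control")
  f <- phos_fit(qt, d, C)
  expect_equal(unname(f$F[1]), 0, tolerance = 1e-20)
  expect_equal(unname(f$p_value[1]), 1)
  # single contrast: F equals the squared moderated t
  expect_equal(unname(f$F), unname(f$t[, 1]^2), tolerance = 1e-10)
  expect_equal(unname(f$df1), rep(1, 20))
})

test_that("joint F agrees with a generalized least-squares oracle", {
  qt <- two_cond_qt(n = 20, seed = 11)
  d <- design_spec(qt)
  C <- stepwise_contrasts(d, "mating", baseline = "control")
  f <- phos_fit(qt, d, C)
  for (i in seq_len(20)) {
    V <- t(C) %*% diag(1 / f$cell_n[i, ]) %*% C
    e <- f$coefficients[i, ]
    quad <- drop(t(e) %*% solve(V) %*% e)
    expect_equal(unname(f$F[i]), unname(quad / (ncol(C) * f$s2_post[i])),
                 tolerance = 1e-6)
  }
})

test_that("a feature missing an entire design cell is tested on the rest", {
  cols <- design_cols(times = c(0, 45, 90), reps = 1:3)
  set.seed(5)
  v <- matrix(rnorm(15 * 18, sd = 0.2), 15,
              dimnames = list(sprintf("f%02d", 1:15), cols))
  # feature 1 loses the whole mating 90min cell
  v[1, grepl("mating_90min", cols)] <- NA
  qt <- quant_table(v)
  d <- design_spec(qt)
  C <- stepwise_contrasts(d, "mating", baseline = "control")
  f <- phos_fit(qt, d, C)
  expect_true(is.na(f$coefficients[1, "Diff_90-45"]))
  expect_false(is.na(f$coefficients[1, "Diff_45-0"]))
  expect_equal(unname(f$df1[1]), 1)
  expect_false(is.na(f$p_value[1]))
})

test_that("fitting per-replicate differences reproduces contrast estimates", {
  # on complete data the difference-of-differences contrast equals the mean
  # over replicates of (mating step) - (control step)
  qt <- two_cond_qt(n = 30, seed = 13)
  d <- design_spec(qt)
  C <- stepwise_contrasts(d, "mating", baseline = "control")
  f <- phos_fit(qt, d, C, moderate = FALSE)
  s <- qt$samples
  times <- sort(unique(s$time_min))
  for (j in seq_len(length(times) - 1)) {
    per_rep <- sapply(sort(unique(s$replicate)), function(r) {
      col_of <- function(cond, t) which(s$condition == cond & s$time_min == t &
                                          s$replicate == r)
      (qt$values[, col_of("mating", times[j + 1])] -
         qt$values[, col_of("mating", times[j])]) -
        (qt$values[, col_of("control", times[j + 1])] -
           qt$values[, col_of("control", times[j])])
    })
    expect_equal(unname(f$coefficients[, j]), unname(rowMeans(per_rep)),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  grid <- seq(0.01, 1, by = 0.01)
  for (len in 1:8) {
    for (rep_i in 1:200) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  }
  # missing values are excluded from the number of tests
  p <- c(0.01, NA, 0.04)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bh_oracle(c(0.01, 0.04)))
})

test_that("moderated F p-values are uniform under the null", {
  sim <- simulate_experiment(null_sim_config(seed = 42, n_sites = 10000,
                                             missing_rate = 0,
                                             replicate_dropout_rate = 0))
  d <- design_spec(sim$phospho)
  f <- phos_fit(sim$phospho, d, stepwise_contrasts(d, "mating", "control"))
  D <- suppressWarnings(stats::ks.test(f$p_value, "punif"))$statistic
  expect_lt(unname(D), 0.02)
})

test_that("fit results are invariant to feature ordering", {
  qt <- two_cond_qt(n = 25, seed = 21)
  d <- design_spec(qt)
  C <- stepwise_contrasts(d, "mating", baseline = "control")
  f1 <- phos_fit(qt, d, C)
  perm <- sample(25)
  qt2 <- quant_table(qt$values[perm, ], qt$features[perm, , drop = FALSE],
                     qt$samples)
  f2 <- phos_fit(qt2, d, C)
  expect_equal(f2$p_value[order(perm)], f1$p_value, ignore_attr = TRUE)
  expect_equal(f2$adj_p_value[order(perm)], f1$adj_p_value, ignore_attr = TRUE)
})

test_that("phos_fit accessors behave like a model object", {
  qt <- two_cond_qt(n = 15, seed = 2)
  d <- design_spec(qt)
  f <- phos_fit(qt, d, stepwise_contrasts(d, "mating", "control"))
  expect_identical(coef(f), f$coefficients)
  expect_equal(dim(fitted(f)), dim(qt$values))
  r <- residuals(f, qt)
  expect_equal(unname(rowSums(r)), rep(0, 15), tolerance = 1e-10)
  expect_output(print(f), "phos_fit")
  s <- summary(f)
  expect_s3_class(s, "summary.phos_fit")
  expect_output(print(s), "significant")
})
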