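lab2 <- voicechimera:::.factorial_label_table()
seq2 <- build_expt2_sequence(lab2, seed = 51)
X2 <- build_design_matrix(seq2)
beta_true <- c(Voice = 2, Instrument = 1, Chimera_SpectrumVoice = 1,
               Chimera_TemporalVoice = 1, intercept = 10)

test_that("the canonical HRF peaks near 6 s, starts at zero and undershoots", {
  h <- canonical_hrf(0.1)
  t <- seq(0, 32, by = 0.1)
  expect_gte(t[which.max(h)], 4)
  expect_lte(t[which.max(h)], 7)
  expect_lt(abs(h[1]), 1e-6)
  expect_lt(min(h[t > t[which.max(h)]]), 0)   # post-peak undershoot
  expect_equal(max(h), 1)                     # unit peak normalization
})

test_that("design matrices carry conditions, intercept and orthogonal modulators", {
  expect_equal(sort(colnames(X2)),
               sort(c(names(beta_true))))
  # with modulators: conditions + 5 modulators + intercept
  feat <- data.frame(id = lab2$id,
                     f0_hz = note_to_hz(lab2$pitch),
                     hnr_db = rnorm(192, 24, 3),
                     dom_scale_cpo = rnorm(192, 1.3, 0.2),
                     dom_rate_hz = rnorm(192, 6, 1),
                     centroid_hz = rnorm(192, 1200, 100))
  Xm <- build_design_matrix(seq2, modulators = feat)
  expect_equal(ncol(Xm), 4 + 5 + 1)
  mod_cols <- grep("^mod_", colnames(Xm))
  expect_equal(length(mod_cols), 5L)
  # serial orthogonalization: each modulator orthogonal to everything earlier
  base_idx <- c(which(!seq_len(ncol(Xm)) %in% mod_cols & colnames(Xm) != "intercept"))
  for (j in seq_along(mod_cols)) {
    earlier <- cbind(1, Xm[, base_idx, drop = FALSE],
                     Xm[, mod_cols[seq_len(j - 1)], drop = FALSE])
    dots <- crossprod(earlier, Xm[, mod_cols[j]])
    expect_lt(max(abs(dots)), 1e-6)
  }
  expect_error(build_design_matrix(seq2, modulators = feat[1:10, ]), "missing")
})

test_that("BOLD simulation is exact without noise and linear in betas", {
  y0 <- simulate_roi_bold(X2, beta_true, noise_sd = 0, seed = 1)
  pred <- as.numeric(unclass(X2)[, names(beta_true)] %*% beta_true)
  expect_equal(y0$values, pred, tolerance = 1e-12)
  b2 <- beta_true
  b2["Voice"] <- 4
  y2 <- simulate_roi_bold(X2, b2, noise_sd = 0, seed = 1)
  dif <- y2$values - y0$values
  expect_equal(dif, 2 * unclass(X2)[, "Voice"], tolerance = 1e-12)
  expect_error(simulate_roi_bold(X2, c(Nope = 1)), "unknown")
})

test_that("simulated noise has the requested AR(1) autocorrelation", {
  rho_hat <- sapply(1:20, function(s) {
    y <- simulate_roi_bold(X2, beta_true * 0, noise_sd = 1, ar1_rho = 0.2,
                           seed = s)
    acf(y$values, lag.max = 1, plot = FALSE)$acf[2]
  })
  expect_equal(mean(rho_hat), 0.2, tolerance = 0.05)
})

test_that("GLM fits are exact on noiseless data and unbiased under noise", {
  y0 <- simulate_roi_bold(X2, beta_true, noise_sd = 0, seed = 1)
  fit <- fit_glm(y0, X2)
  expect_equal(fit$betas[names(beta_true)], beta_true, tolerance = 1e-8)
  err <- sapply(1:200, function(s) {
    y <- simulate_roi_bold(X2, beta_true, noise_sd = 1, ar1_rho = 0.2, seed = s)
    fit_glm(y, X2)$betas[["Voice"]] - 2
  })
  expect_lt(abs(mean(err)), 0.05 * 2)        # |bias| < 5% of beta
  # residual variance approximates the white-noise variance
  s2 <- sapply(1:50, function(s) {
    y <- simulate_roi_bold(X2, beta_true, noise_sd = 1.5, ar1_rho = 0, seed = s)
    fit_glm(y, X2)$sigma2
  })
  expect_equal(mean(s2), 1.5^2, tolerance = 0.05)
  # rank deficiency is reported
  Xbad <- cbind(unclass(X2), dup = unclass(X2)[, 1])
  expect_error(fit_glm(y0, structure(Xbad, tr_s = 2, class = "design_matrix")),
               "rank")
})

test_that("paired group contrasts match the textbook formula", {
  set.seed(52)
  for (rep in 1:20) {
    a <- rnorm(5)
    b <- rnorm(5)
    ct <- group_contrast(a, b)
    d <- a - b
    t_o <- mean(d) / (sd(d) / sqrt(5))
    expect_equal(ct$t, t_o, tolerance = 1e-10)
    expect_equal(ct$p, 2 * pt(-abs(t_o), 4), tolerance = 1e-10)
    expect_equal(ct$df, 4L)
  }
  eq <- group_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  dg <- group_contrast(c(2, 3, 4), c(1, 2, 3))   # constant difference
  expect_true(dg$degenerate)
  # A vs the mean of several conditions
  B <- cbind(c(1, 2, 3, 4), c(3, 2, 1, 4), c(2, 2, 2, 4))
  ct2 <- group_contrast(c(3, 3, 3, 5), B)
  expect_equal(ct2$estimate, mean(c(3, 3, 3, 5) - rowMeans(B)), tolerance = 1e-12)
  expect_error(group_contrast(1, 2), "two subjects")
})

test_that("2x2 repeated-measures ANOVA agrees with an aov error-stratum oracle", {
  set.seed(53)
  for (rep in 1:10) {
    n <- 5
    y <- matrix(rnorm(n * 4), n, 4) + outer(rnorm(n), rep(1, 4))
    mine <- rm_anova_2x2(y)
    df <- data.frame(y = as.vector(y), subj = factor(rep(1:n, 4)),
                     TT = factor(rep(c(1, 1, 2, 2), each = n)),
                     SS = factor(rep(c(1, 2, 1, 2), each = n)))
    fit <- summary(stats::aov(y ~ TT * SS + Error(subj / (TT * SS)), data = df))
    F_o <- c(fit[["Error: subj:TT"]][[1]]["TT", "F value"],
             fit[["Error: subj:SS"]][[1]]["SS", "F value"],
             fit[["Error: subj:TT:SS"]][[1]]["TT:SS", "F value"])
    expect_equal(mine$F, F_o, tolerance = 1e-10)
    expect_true(all(mine$df1 == 1 & mine$df2 == n - 1))
  }
  flat <- matrix(5, 4, 4)
  mflat <- rm_anova_2x2(flat)
  expect_equal(mflat$F, rep(0, 3))
  expect_equal(mflat$p, rep(1, 3))
})

test_that("a pure spectrum effect drives only the S factor", {
  set.seed(54)
  hits <- matrix(0, 60, 3)
  for (i in 1:60) {
    n <- 12
    y <- matrix(rnorm(n * 4, sd = 1), n, 4)
    y[, c(1, 3)] <- y[, c(1, 3)] + 1.2        # S level 1 columns boosted
    res <- rm_anova_2x2(y, factor_T = c(1, 1, 2, 2), factor_S = c(1, 2, 1, 2))
    hits[i, ] <- res$p < 0.05
  }
  rates <- colMeans(hits)
  expect_gt(rates[2], 0.8)                    # S detected
  expect_lt(rates[1], 0.2)                    # T near the nominal rate
  expect_lt(rates[3], 0.2)                    # interaction near nominal
})

test_that("GG epsilon is bounded, matches the covariance-entry formula, and is ~1 under compound symmetry", {
  set.seed(55)
  for (rep in 1:20) {
    n <- 8
    k <- 4
    y <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * k), k, k) * 0.4 +
      outer(rnorm(n), rep(1, k))
    r <- rm_anova_gg(y)
    expect_gte(r$gg_epsilon, 1 / (k - 1))
    expect_lte(r$gg_epsilon, 1)
    expect_equal(r$df1, 3L)
    # element-wise Greenhouse-Geisser formula oracle
    S <- cov(y)
    m <- mean(S)
    md <- mean(diag(S))
    rm_ <- rowMeans(S)
    eps_o <- (k * (md - m))^2 /
      ((k - 1) * (sum(S^2) - 2 * k * sum(rm_^2) + k^2 * m^2))
    expect_equal(r$gg_epsilon, min(max(eps_o, 1 / (k - 1)), 1),
                 tolerance = 1e-10)
    # F and uncorrected dfs agree with aov
    df <- data.frame(y = as.vector(y), subj = factor(rep(1:n, k)),
                     cond = factor(rep(1:k, each = n)))
    fit <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
    expect_equal(r$F, fit[["Error: subj:cond"]][[1]]["cond", "F value"],
                 tolerance = 1e-10)
  }
  # compound symmetry: epsilon near its upper bound
  eps_cs <- sapply(1:30, function(s) {
    set.seed(500 + s)
    subj <- rnorm(20, sd = 2)
    y <- outer(subj, rep(1, 4)) + matrix(rnorm(80), 20, 4)
    rm_anova_gg(y)$gg_epsilon
  })
  expect_gt(mean(eps_cs), 0.85)
  expect_error(rm_anova_gg(matrix(1, 5, 2)), "3 conditions")
})
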