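#' Canonical double-gamma hemodynamic response function
#'
#' Standard canonical HRF: difference of two gamma densities (response peak
#' near 6 s, undershoot near 16 s, unit dispersions, undershoot ratio 1/6)
#' over a 32-s support, normalized to unit peak.
#'
#' @param dt_s Sampling interval of the kernel in seconds.
#' @param duration_s Kernel support (default 32 s).
#' @return Numeric kernel sampled at `dt_s`.
#' @export
canonical_hrf <- function(dt_s, duration_s = 32) {
  stopifnot(dt_s > 0)
  t <- seq(0, duration_s, by = dt_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build a GLM design matrix from a trial sequence
#'
#' Events of each condition are modeled as delta functions on a fine time
#' grid, convolved with the canonical HRF and sampled at the scan times. When
#' a per-stimulus feature table is supplied, parametric modulator columns are
#' added in the order pitch (f0), HNR, dominant scale, dominant rate,
#' spectral centroid: each modulator is the mean-centered feature value on
#' each event, convolved, then serially orthogonalized against the intercept,
#' the condition columns and all earlier modulators.
#'
#' @param seq A `trial_sequence`.
#' @param modulators Optional feature table (columns `id`, `f0_hz`, `hnr_db`,
#'   `dom_scale_cpo`, `dom_rate_hz`, `centroid_hz`) covering every stimulus.
#' @param tr_s Repetition time in seconds (default 2).
#' @param dt_s Microtime resolution for convolution (default 0.1 s).
#' @param model_repeats If TRUE (default) repeat trials get their own
#'   nuisance condition column instead of their category column.
#' @return A numeric matrix (scans x regressors) with named columns and
#'   attributes `tr_s` and `conditions`; class `design_matrix`.
#' @export
build_design_matrix <- function(seq, modulators = NULL, tr_s = 2, dt_s = 0.1,
                                model_repeats = TRUE) {
  run_dur <- max(seq$onset_s) + attr(seq, "soa_s") %||% 2
  n_scan <- ceiling((run_dur + 32) / tr_s)
  n_fine <- ceiling(n_scan * tr_s / dt_s) + 1L
  hrf <- canonical_hrf(dt_s)
  scan_idx <- round((seq_len(n_scan) - 1) * tr_s / dt_s) + 1L

  cond <- seq$condition
  if (model_repeats && any(seq$is_repeat)) cond[seq$is_repeat] <- "repeat_press"
  cond_names <- unique(cond)

  convolve_events <- function(onsets, heights) {
    u <- numeric(n_fine)
    at <- round(onsets / dt_s) + 1L
    for (k in seq_along(at)) u[at[k]] <- u[at[k]] + heights[k]
    v <- stats::convolve(u, rev(hrf), type = "open")[seq_len(n_fine)]
    v[scan_idx]
  }

  X <- matrix(0, nrow = n_scan, ncol = 0)
  for (cn in cond_names) {
    sel <- cond == cn
    X <- cbind(X, convolve_events(seq$onset_s[sel], rep(1, sum(sel))))
  }
  colnames(X) <- cond_names

  if (!is.null(modulators)) {
    mod_order <- c(pitch = "f0_hz", hnr = "hnr_db", dom_scale = "dom_scale_cpo",
                   dom_rate = "dom_rate_hz", centroid = "centroid_hz")
    missing_ids <- setdiff(seq$stimulus_id, modulators$id)
    if (length(missing_ids) > 0) {
      stop("feature rows missing for ", length(missing_ids), " stimuli")
    }
    row_of <- match(seq$stimulus_id, modulators$id)
    sel <- !seq$is_repeat           # modulators attach to the category events
    basis <- cbind(1, X)            # orthogonalize against intercept + conditions
    for (m in names(mod_order)) {
      vals <- modulators[[mod_order[[m]]]][row_of[sel]]
      vals <- vals - mean(vals)
      col <- convolve_events(seq$onset_s[sel], vals)
      col <- stats::lm.fit(basis, col)$residuals   # serial orthogonalization
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("mod_", m)
      basis <- cbind(basis, col)
    }
  }
  X <- cbind(X, intercept = 1)
  structure(X, tr_s = tr_s, conditions = cond_names, class = "design_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an ROI BOLD time series
#'
#' `y = X beta + e` with AR(1) Gaussian noise `e_t = rho e_{t-1} + w_t`,
#' scaled so the marginal noise standard deviation equals `noise_sd`.
#' Deterministic given `seed`.
#'
#' @param design A `design_matrix`.
#' @param true_betas Coefficient vector matching the design columns (a named
#'   subset is matched by column name; unnamed vectors must have one entry
#'   per column).
#' @param noise_sd Marginal noise SD.
#' @param ar1_rho Lag-1 autocorrelation (default 0.2).
#' @param seed RNG seed.
#' @return An `roi_timeseries`: list with `values`, `tr_s`.
#' @export
simulate_roi_bold <- function(design, true_betas, noise_sd = 1, ar1_rho = 0.2,
                              seed = 1L) {
  X <- unclass(design)
  attr(X, "tr_s") <- NULL; attr(X, "conditions") <- NULL
  b <- numeric(ncol(X))
  if (!is.null(names(true_betas))) {
    unknown <- setdiff(names(true_betas), colnames(X))
    if (length(unknown)) stop("betas name unknown columns: ",
                              paste(unknown, collapse = ", "))
    b[match(names(true_betas), colnames(X))] <- true_betas
  } else {
    if (length(true_betas) != ncol(X)) stop("beta length must match design columns")
    b <- true_betas
  }
  n <- nrow(X)
  e <- with_seed(seed, {
    w <- stats::rnorm(n, sd = noise_sd * sqrt(1 - ar1_rho^2))
    as.numeric(stats::filter(w, ar1_rho, method = "recursive"))
  })
  if (noise_sd == 0) e <- numeric(n)
  structure(list(values = as.numeric(X %*% b) + e, tr_s = attr(design, "tr_s")),
            class = "roi_timeseries")
}

#' Fit a GLM to an ROI time series
#'
#' Ordinary least squares via the QR decomposition, with residual variance on
#' `n - rank(X)` degrees of freedom and standard errors from the unscaled
#' covariance.
#'
#' @param y An `roi_timeseries` or numeric vector.
#' @param design A `design_matrix` (full column rank).
#' @return A list with `betas` (named), `se`, `sigma2`, `df`, `fitted`,
#'   `residuals`.
#' @export
fit_glm <- function(y, design) {
  yv <- if (inherits(y, "roi_timeseries")) y$values else as.numeric(y)
  X <- unclass(design)
  attr(X, "tr_s") <- NULL; attr(X, "conditions") <- NULL
  if (length(yv) != nrow(X)) stop("time series and design rows differ")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  betas <- qr.coef(qrX, yv)
  fitted <- as.numeric(X %*% betas)
  res <- yv - fitted
  df <- length(yv) - qrX$rank
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  list(betas = betas, se = sqrt(sigma2 * diag(XtXinv)), sigma2 = sigma2,
       df = df, fitted = fitted, residuals = res)
}

#' Group-level paired contrast
#'
#' Paired t test on per-subject estimates: condition A versus condition B, or
#' A versus the row mean of several conditions when `b` is a matrix
#' (e.g. voice versus the average of the three non-voice conditions),
#' df = n - 1.
#'
#' @param a Numeric vector of per-subject estimates for condition A.
#' @param b Vector, or matrix with one column per comparison condition.
#' @return A `contrast_result` list: `estimate` (mean difference), `t`, `df`,
#'   `p`, `degenerate` (TRUE when the difference has zero variance).
#' @export
group_contrast <- function(a, b) {
  if (is.matrix(b) || is.data.frame(b)) b <- rowMeans(as.matrix(b))
  if (length(a) != length(b)) stop("unequal subject counts")
  n <- length(a)
  if (n < 2L) stop("need at least two subjects")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(structure(list(estimate = mean(d),
                          t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                          df = n - 1L, p = if (mean(d) == 0) 1 else NA_real_,
                          degenerate = TRUE), class = "contrast_result"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(list(estimate = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("paired contrast: estimate %.4g, t%d = %.3f, p = %.4g%s\n",
              x$estimate, x$df, x$t, x$p,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' 2 x 2 repeated-measures ANOVA
#'
#' Within-subject ANOVA for two crossed two-level factors via per-subject
#' difference contrasts: each effect F(1, n-1) equals the squared one-sample
#' t of its contrast scores.
#'
#' @param y Subjects x 4 matrix of condition means.
#' @param factor_T,factor_S Level assignment of each column for the two
#'   factors; defaults assume column order (T1S1, T1S2, T2S1, T2S2).
#' @return A data.frame with rows `T`, `S`, `T:S` and columns `effect`
#'   (mean contrast), `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(y, factor_T = c(1, 1, 2, 2), factor_S = c(1, 2, 1, 2)) {
  y <- as.matrix(y)
  if (ncol(y) != 4L) stop("need exactly 4 condition columns")
  if (nrow(y) < 2L) stop("need at least two subjects")
  if (any(!is.finite(y))) stop("missing cells are not allowed")
  ct <- ifelse(factor_T == 1, 0.5, -0.5)
  cs <- ifelse(factor_S == 1, 0.5, -0.5)
  ci <- 4 * ct * cs                         # +/- 1 pattern for interaction
  one <- function(cvec, lab) {
    sc <- as.numeric(y %*% cvec)
    n <- length(sc)
    tval <- mean(sc) / (stats::sd(sc) / sqrt(n))
    data.frame(effect_name = lab, effect = mean(sc), F = tval^2, df1 = 1L,
               df2 = n - 1L,
               p = stats::pf(tval^2, 1, n - 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(ct, "T"), one(cs, "S"), one(ci, "T:S"))
  # identical contrast scores across subjects: F = 0 when the effect is null
  degen <- !is.finite(out$F) & out$effect == 0
  out$F[degen] <- 0
  out$p[degen] <- 1
  out
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subject F with sphericity correction: epsilon is computed
#' from the double-centered sample covariance of the conditions,
#' `eps = tr(Sc)^2 / ((k-1) sum(Sc^2))`, clamped to \[1/(k-1), 1\], and the
#' corrected degrees of freedom are `eps (k-1)` and `eps (k-1)(n-1)`.
#'
#' @param y Subjects x k matrix of condition values (k >= 3, n >= 2).
#' @return An `rm_anova_result` list: `F`, `df1`, `df2` (uncorrected),
#'   `gg_epsilon`, `df1_gg`, `df2_gg`, `p` (uncorrected), `p_gg`.
#' @export
rm_anova_gg <- function(y) {
  y <- as.matrix(y)
  n <- nrow(y); k <- ncol(y)
  if (k < 3L) stop("need at least 3 conditions")
  if (n < 2L) stop("need at least 2 subjects")
  grand <- mean(y)
  col_m <- colMeans(y)
  row_m <- rowMeans(y)
  ss_cond <- n * sum((col_m - grand)^2)
  resid <- y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fv <- (ss_cond / df1) / (ss_err / df2)
  S <- stats::cov(y)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  denom <- (k - 1) * sum(Sc^2)
  eps <- if (denom <= 0) 1 / (k - 1) else sum(diag(Sc))^2 / denom
  eps <- min(max(eps, 1 / (k - 1)), 1)
  structure(list(F = Fv, df1 = df1, df2 = df2,
                 gg_epsilon = eps, df1_gg = eps * df1, df2_gg = eps * df2,
                 p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
                 p_gg = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("RM ANOVA: F%.2f,%.1f = %.2f, p = %.4g (Greenhouse-Geisser eps = %.3f)\n",
              x$df1_gg, x$df2_gg, x$F, x$p_gg, x$gg_epsilon))
  invisible(x)
}

#' End-to-end voice-effect parameter recovery
#'
#' Simulates a group of subjects viewing the factorial chimera design in two
#' ROIs -- a "right-TVA-like" ROI whose voice response exceeds the three
#' non-voice conditions, and a "left-TVA-like" null ROI with equal responses
#' -- then runs the full design -> simulate -> fit -> group-statistics chain
#' and reports detection rates of the voice-versus-rest paired contrast.
#'
#' Per subject, the voice-condition beta is `base + delta_i` with
#' `delta_i ~ N(d * sd_between, sd_between)` in the effect ROI (so the
#' between-subject effect size of the injected effect is `d`) and
#' `delta_i ~ N(0, sd_between)` in the null ROI.
#'
#' @param n_subjects Group size (default 22).
#' @param d Injected between-subject effect size (default 0.8).
#' @param n_sims Number of simulated groups (default 200).
#' @param noise_sd Within-run marginal noise SD (default 1).
#' @param ar1_rho AR(1) noise autocorrelation (default 0.2).
#' @param sd_between Between-subject SD of the voice effect (default 0.5).
#' @param base_beta Baseline response of every condition (default 1).
#' @param alpha Detection criterion (default 0.05).
#' @param seed Master seed.
#' @param design Optional prebuilt Experiment-2 `design_matrix`; built from
#'   the standard 192-stimulus factorial sequence when NULL.
#' @return A `recovery_report` list: `detect_rate_effect`,
#'   `type1_rate_null`, `mean_contrast_effect`, `mean_contrast_null`,
#'   `n_sims`, `n_subjects`, `d`.
#' @export
recover_voice_effect <- function(n_subjects = 22, d = 0.8, n_sims = 200,
                                 noise_sd = 1, ar1_rho = 0.2, sd_between = 0.5,
                                 base_beta = 1, alpha = 0.05, seed = 1L,
                                 design = NULL) {
  if (is.null(design)) {
    lab <- .factorial_label_table()
    seq2 <- build_expt2_sequence(lab, seed = 1L)
    design <- build_design_matrix(seq2, tr_s = 2)
  }
  X <- unclass(design)
  attr(X, "tr_s") <- NULL; attr(X, "conditions") <- NULL
  conds <- c("Voice", "Instrument", "Chimera_SpectrumVoice",
             "Chimera_TemporalVoice")
  if (!all(conds %in% colnames(X))) stop("design lacks the four factorial conditions")
  qrX <- qr(X)
  n <- nrow(X)
  voice_col <- match("Voice", colnames(X))
  other_cols <- match(setdiff(conds, "Voice"), colnames(X))
  sim_group <- function(mu_delta, seed0) {
    contrasts <- with_seed(seed0, {
      vapply(seq_len(n_subjects), function(s) {
        delta <- stats::rnorm(1, mu_delta, sd_between)
        b <- numeric(ncol(X))
        b[match(conds, colnames(X))] <- base_beta
        b[voice_col] <- base_beta + delta
        w <- stats::rnorm(n, sd = noise_sd * sqrt(1 - ar1_rho^2))
        e <- as.numeric(stats::filter(w, ar1_rho, method = "recursive"))
        bh <- qr.coef(qrX, as.numeric(X %*% b) + e)
        bh[voice_col] - mean(bh[other_cols])
      }, numeric(1))
    })
    ct <- group_contrast(contrasts, rep(0, n_subjects))
    c(sig = !is.na(ct$p) && ct$p < alpha, est = mean(contrasts))
  }
  eff <- matrix(0, n_sims, 2)
  nul <- matrix(0, n_sims, 2)
  for (i in seq_len(n_sims)) {
    eff[i, ] <- sim_group(d * sd_between, seed + 2L * i)
    nul[i, ] <- sim_group(0, seed + 2L * i + 1L)
  }
  structure(list(detect_rate_effect = mean(eff[, 1]),
                 type1_rate_null = mean(nul[, 1]),
                 mean_contrast_effect = mean(eff[, 2]),
                 mean_contrast_null = mean(nul[, 2]),
                 n_sims = n_sims, n_subjects = n_subjects, d = d),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("voice-effect recovery (%d sims, n = %d, d = %.2f):\n",
                     "  detection rate (effect ROI): %.3f\n",
                     "  type-I rate (null ROI):      %.3f\n",
                     "  mean contrast: %.3f (effect), %.3f (null)\n"),
              x$n_sims, x$n_subjects, x$d, x$detect_rate_effect,
              x$type1_rate_null, x$mean_contrast_effect, x$mean_contrast_null))
  invisible(x)
}

# 192-row factorial label table (combinatorics only, no audio).
.factorial_label_table <- function() {
  donors <- c(a = "Voice", i = "Voice", violin = "Instrument",
              cello = "Instrument")
  grid <- expand.grid(pitch = names(pitch_grid()), t_id = names(donors),
                      s_id = names(donors), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  data.frame(
    id = sprintf("chim_%s_T-%s_S-%s", grid$pitch, grid$t_id, grid$s_id),
    pitch = grid$pitch,
    T_label = unname(donors[grid$t_id]),
    S_label = unname(donors[grid$s_id]),
    condition = mapply(condition_label, donors[grid$t_id], donors[grid$s_id],
                       USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Write an ROI time series and its design matrix to TSV files
#'
#' @param y An `roi_timeseries`.
#' @param design A `design_matrix`.
#' @param ts_path,design_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_simulation_tsv <- function(y, design, ts_path, design_path) {
  utils::write.table(data.frame(t_s = (seq_along(y$values) - 1) * y$tr_s,
                                bold = y$values),
                     ts_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(unclass(design)), design_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(ts_path, design_path))
}
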