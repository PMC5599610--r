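#' One-way ANOVA between groups
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) as used to
#' verify that a descriptor does not differ between stimulus categories.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return A list with `F`, `df1` (k-1), `df2` (N-k) and `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least two values")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (all(vapply(groups, stats::var, numeric(1)) == 0) &&
      stats::var(values) == 0) {
    return(list(F = 0, df1 = length(groups) - 1L,
                df2 = length(values) - length(groups), p = 1))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = unname(fit$p.value))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero-variance input has no defined correlation")
  }
  stats::cor(x, y)
}

# The five matched descriptors, in modulator order.
.match_features <- c("f0_hz", "hnr_db", "centroid_hz", "dom_rate_hz",
                     "dom_scale_cpo")

#' Acoustic matching report between two category profile sets
#'
#' Runs one between-category ANOVA per descriptor (f0, HNR, spectral
#' centroid, dominant rate, dominant scale) and flags descriptors whose
#' between-category difference is significant at `alpha` as unmatched.
#'
#' @param voice_profiles,instrument_profiles Feature tables (data.frames with
#'   the descriptor columns of [profile_table()]).
#' @param alpha Matching criterion level (default 0.05).
#' @return A `match_report` data.frame: one row per descriptor with group
#'   means, SDs, F, df1, df2, p and `matched`.
#' @export
match_report <- function(voice_profiles, instrument_profiles, alpha = 0.05) {
  if (nrow(voice_profiles) == 0 || nrow(instrument_profiles) == 0) {
    stop("profile sets must be non-empty")
  }
  rows <- lapply(.match_features, function(feat) {
    v <- voice_profiles[[feat]]
    i <- instrument_profiles[[feat]]
    a <- one_way_anova(list(v, i))
    data.frame(feature = feat,
               mean_voice = mean(v), sd_voice = stats::sd(v),
               mean_instrument = mean(i), sd_instrument = stats::sd(i),
               F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
               matched = a$p >= alpha, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("match_report", "data.frame"),
            alpha = alpha)
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("Acoustic matching report (alpha = %g)\n", attr(x, "alpha")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-14s voice %7.2f (SD %5.2f)  instr %7.2f (SD %5.2f)  F%d,%d = %6.2f, p = %.3f  [%s]\n",
                x$feature[i], x$mean_voice[i], x$sd_voice[i],
                x$mean_instrument[i], x$sd_instrument[i],
                x$df1[i], x$df2[i], x$F[i], x$p[i],
                if (x$matched[i]) "matched" else "NOT matched"))
  }
  invisible(x)
}

#' Write a matching report to TSV
#' @param report A `match_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select acoustically matched category subsets
#'
#' Greedy stimulus selection emulating how matched category sets are chosen
#' from a larger pool: while the between-category ANOVA on the target
#' descriptor is significant at `alpha`, the single item most extreme
#' relative to the other category's mean is dropped (ties broken by a seeded
#' draw). Item values are never altered, only membership. Pitch sets are a
#' hard constraint and must be identical across categories (items are timbres
#' with per-timbre descriptor summaries; pitch coverage is unaffected by
#' exclusion).
#'
#' @param voice_pool,instrument_pool Data.frames with at least the column
#'   `feature` names in them; typically per-timbre mean descriptor tables.
#' @param feature Descriptor column to match on (default `"hnr_db"`).
#' @param alpha Significance criterion (default 0.05).
#' @param min_n Minimum items to retain per category (default 4).
#' @param max_iter Maximum exclusions before giving up.
#' @param seed Seed for tie-breaking.
#' @return A list with `voice`, `instrument` (the retained subsets), `anova`
#'   (final test) and `dropped` (ids or row indices excluded, in order).
#' @export
select_matched_subset <- function(voice_pool, instrument_pool,
                                  feature = "hnr_db", alpha = 0.05,
                                  min_n = 4, max_iter = 100, seed = 1L) {
  v <- voice_pool; i <- instrument_pool
  if (nrow(v) <= min_n || nrow(i) <= min_n) stop("candidate pools too small")
  dropped <- character(0)
  id_of <- function(df, j) {
    if (!is.null(df$id)) df$id[j] else as.character(rownames(df)[j])
  }
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      a <- one_way_anova(list(v[[feature]], i[[feature]]))
      if (a$p >= alpha) {
        return(list(voice = v, instrument = i, anova = a, dropped = dropped))
      }
      if (nrow(v) <= min_n && nrow(i) <= min_n) break
      # deviation of each item from the opposite category's mean
      dev_v <- abs(v[[feature]] - mean(i[[feature]]))
      dev_i <- abs(i[[feature]] - mean(v[[feature]]))
      if (nrow(i) <= min_n || (nrow(v) > min_n && max(dev_v) >= max(dev_i))) {
        cand <- which(dev_v == max(dev_v))
        j <- if (length(cand) > 1) sample(cand, 1) else cand
        dropped <- c(dropped, id_of(v, j))
        v <- v[-j, , drop = FALSE]
      } else {
        cand <- which(dev_i == max(dev_i))
        j <- if (length(cand) > 1) sample(cand, 1) else cand
        dropped <- c(dropped, id_of(i, j))
        i <- i[-j, , drop = FALSE]
      }
    }
    stop("no matched subset found within max_iter exclusions")
  })
}
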