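# Permutation FWER control for source maps and the clinical battery.

#' Maximal-statistic permutation test for paired difference images
#'
#' Under the null that the subjects' difference images have zero mean at
#' every voxel, each subject's image is randomly sign-flipped; the maximum
#' of |t| over all voxels per permutation forms the null distribution of
#' the image-wide maximal statistic, and observed |t| values above its
#' 95th percentile are family-wise significant. When `2^subjects <=
#' n_perm` the full set of sign patterns is enumerated instead of sampled.
#'
#' @param diffs subjects x voxels matrix, or subjects x vertices x
#'   quartiles array (flattened internally).
#' @param n_perm number of permutations (>= 100; fewer makes the threshold
#'   unstable).
#' @param seed RNG seed for the sampled sign flips.
#' @param alpha family-wise level (default 0.05).
#' @return object of class `permutation_result`: `observed_t`, `max_null`,
#'   `threshold` (empirical `1 - alpha` percentile of `max_null`),
#'   `significant`, `p_corrected` (per-voxel corrected p), `n_perm`,
#'   `exact` (enumeration used), `seed`.
#' @export
permutation_max_t <- function(diffs, n_perm = 500, seed = 1, alpha = 0.05) {
  if (n_perm < 100) stopf("n_perm must be >= 100, got %d", n_perm)
  dims <- dim(diffs)
  D <- if (length(dims) == 3) matrix(diffs, dims[1]) else as.matrix(diffs)
  S <- nrow(D); V <- ncol(D)
  if (S < 2) stopf("need >= 2 subjects, got %d", S)
  ss <- colSums(D^2)
  tstat <- function(signs) {
    # signs: P x S; per-voxel mean and sd under sign flips. Because
    # (s_i d_i)^2 = d_i^2, only the mean depends on the signs.
    m <- signs %*% D / S
    v <- (matrix(ss, nrow(signs), V, byrow = TRUE) - S * m^2) / (S - 1)
    m / sqrt(pmax(v, 0) / S)
  }
  t_obs <- as.vector(tstat(matrix(1, 1, S)))
  exact <- 2^S <= n_perm
  signs <- if (exact) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), S)))
  } else {
    # the identity relabelling is always part of the permutation set
    # (Nichols-Holmes convention); the rest are sampled
    rbind(rep(1, S),
          with_seed(seed, matrix(sample(c(-1, 1), (n_perm - 1) * S,
                                        replace = TRUE), n_perm - 1, S)))
  }
  Tm <- tstat(signs)
  Tm[!is.finite(Tm)] <- Inf      # all-equal columns: max statistic saturates
  max_null <- apply(abs(Tm), 1, max)
  thr <- stats::quantile(max_null, 1 - alpha, type = 1, names = FALSE)
  p_corr <- vapply(abs(t_obs), function(t0) mean(max_null >= t0), 0)
  res <- list(observed_t = if (length(dims) == 3)
                array(t_obs, dims[2:3]) else t_obs,
              max_null = max_null, threshold = thr,
              significant = if (length(dims) == 3)
                array(abs(t_obs) > thr, dims[2:3]) else abs(t_obs) > thr,
              p_corrected = if (length(dims) == 3)
                array(p_corr, dims[2:3]) else p_corr,
              n_perm = nrow(signs), exact = exact, alpha = alpha,
              seed = seed)
  structure(res, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d voxels, %d perms%s, threshold |t| > %.3f, %d significant\n",
              length(x$observed_t), x$n_perm,
              if (x$exact) " (exact)" else "", x$threshold,
              sum(x$significant)))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with enforced monotonicity, capped at 1.
#'
#' @param pvals numeric p-values in [0, 1].
#' @return adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Paired Wilcoxon signed-rank test with Pratt zero handling
#'
#' Exact distribution (via [stats::wilcox.test()]) when there are no zero
#' differences or ties and n <= 25; otherwise a normal approximation with
#' continuity correction, with zero differences handled by Pratt's method
#' (zeros keep their ranks but drop from the statistic). All-zero
#' differences are the degenerate no-change case and report p = 1.
#'
#' @param x,y paired samples.
#' @return list with `p_value`, `statistic`, `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  if (all(d == 0))
    return(list(p_value = 1, statistic = 0, method = "degenerate (no nonzero differences)",
                degenerate = TRUE))
  nz <- d != 0
  has_ties <- anyDuplicated(abs(d[nz])) > 0
  if (all(nz) && !has_ties && length(d) <= 25) {
    wt <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    return(list(p_value = wt$p.value, statistic = unname(wt$statistic),
                method = "exact", degenerate = FALSE))
  }
  # Pratt: rank |d| including zeros, then discard the zeros' ranks
  r <- rank(abs(d))
  Wp <- sum(r[nz][d[nz] > 0])
  n <- length(d); n0 <- sum(!nz)
  mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
  sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24
  ties <- table(r[nz])
  sig2 <- sig2 - sum(ties^3 - ties) / 48
  z <- (Wp - mu - sign(Wp - mu) * 0.5) / sqrt(sig2)
  list(p_value = 2 * stats::pnorm(-abs(z)), statistic = Wp,
       method = "normal approximation (Pratt zeros, continuity correction)",
       degenerate = FALSE)
}

#' Nonparametric clinical battery with BH correction
#'
#' For every outcome measure: Kolmogorov-Smirnov normality check on the
#' pooled standardized values, within-group Wilcoxon signed-rank on the
#' paired pre/post scores (both groups), between-group Mann-Whitney on the
#' post-minus-pre deltas, and Benjamini-Hochberg adjustment across the
#' whole battery of within- and between-group tests. Subjects missing a
#' timepoint are dropped with a warning.
#'
#' @param table a `clinical_table`.
#' @return object of class `clinical_stats_report`: data.frame `tests`
#'   (measure, test, group, p, q, direction, degenerate) and data.frame
#'   `normality` (measure, ks_p).
#' @export
clinical_battery <- function(table) {
  stopifnot(inherits(table, "clinical_table"))
  df <- as.data.frame(table)
  for (tp in CLINICAL_TIMEPOINTS)
    for (g in CLINICAL_GROUPS)
      if (sum(df$timepoint == tp & df$group == g) == 0)
        stopf("missing %s rows for group %s", tp, g)
  measures <- intersect(CLINICAL_MEASURES, unique(df$measure))
  rows <- list(); norm <- list()
  for (m in measures) {
    dm <- df[df$measure == m, ]
    pooled <- dm$value
    ks <- suppressWarnings(
      stats::ks.test(scale(pooled), "pnorm"))
    norm[[m]] <- data.frame(measure = m, ks_p = ks$p.value)
    deltas <- list()
    for (g in CLINICAL_GROUPS) {
      dg <- dm[dm$group == g, ]
      wide <- merge(dg[dg$timepoint == "TPRE", c("subject_id", "value")],
                    dg[dg$timepoint == "TPOST", c("subject_id", "value")],
                    by = "subject_id", suffixes = c("_pre", "_post"))
      dropped <- setdiff(unique(dg$subject_id), wide$subject_id)
      if (length(dropped))
        warnf("measure %s, group %s: dropping unpaired subject(s) %s",
              m, g, paste(dropped, collapse = ", "))
      if (nrow(wide) < 2) stopf("group %s has < 2 paired subjects for %s", g, m)
      wt <- wilcoxon_signed_rank(wide$value_post, wide$value_pre)
      rows[[length(rows) + 1]] <- data.frame(
        measure = m, test = "wilcoxon_within", group = g, p = wt$p_value,
        direction = sign(stats::median(wide$value_post - wide$value_pre)),
        degenerate = wt$degenerate)
      deltas[[g]] <- wide$value_post - wide$value_pre
    }
    mw <- suppressWarnings(
      stats::wilcox.test(deltas$NMT, deltas$nonNMT, exact = FALSE,
                         correct = TRUE))
    rows[[length(rows) + 1]] <- data.frame(
      measure = m, test = "mannwhitney_between", group = "NMT-nonNMT",
      p = mw$p.value,
      direction = sign(stats::median(deltas$NMT) - stats::median(deltas$nonNMT)),
      degenerate = FALSE)
  }
  tests <- do.call(rbind, rows)
  tests$q <- bh_adjust(tests$p)
  structure(list(tests = tests, normality = do.call(rbind, norm)),
            class = "clinical_stats_report")
}

#' @export
print.clinical_stats_report <- function(x, ...) {
  cat("<clinical_stats_report>\n")
  print(x$tests, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Multiple correlation of a clinical change with ROI activation changes
#'
#' Experimental: the multiple correlation coefficient R, computed as the
#' square root of the coefficient of determination from an ordinary
#' least-squares fit of one clinical post-minus-pre delta on a set of ROI
#' z-score deltas. Variable selection is the caller's choice.
#'
#' @param clinical_delta numeric vector, one value per subject.
#' @param roi_z_deltas subjects x ROI matrix of z-score changes.
#' @return list with `R`, `R2`, `fit` (the `lm` object).
#' @export
multiple_correlation <- function(clinical_delta, roi_z_deltas) {
  roi_z_deltas <- as.matrix(roi_z_deltas)
  stopifnot(length(clinical_delta) == nrow(roi_z_deltas))
  if (nrow(roi_z_deltas) <= ncol(roi_z_deltas) + 1)
    warnf("more predictors than subjects support; R is inflated")
  fit <- stats::lm(clinical_delta ~ roi_z_deltas)
  r2 <- summary(fit)$r.squared
  list(R = sqrt(r2), R2 = r2, fit = fit)
}
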