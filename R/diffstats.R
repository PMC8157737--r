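#' Per-feature two-group fits
#'
#' Computes, for every feature of a values matrix (log2 intensities or
#' M-values), the group means over non-missing values, the log2 fold change
#' (treatment minus control), and the pooled residual variance
#' `s2 = sum((x - group mean)^2) / df` with `df = (n_a - 1) + (n_b - 1)`
#' using each feature's own effective sample sizes. Features with `df = 0`
#' keep their fold change but are excluded from prior estimation downstream;
#' features with an empty group get missing statistics rather than being
#' dropped.
#'
#' @param values Numeric matrix, features x samples.
#' @param groups Character or factor of length `ncol(values)` with exactly
#'   two levels.
#' @param treatment Which group level is the treatment arm (fold changes are
#'   treatment minus control). Defaults to the first level in order of
#'   appearance, with a message.
#' @return A `data.frame` with one row per feature: `feature_id`, `mean_a`
#'   (treatment), `mean_b` (control), `log2fc`, `s2`, `df`, `n_a`, `n_b`.
#'   Attribute `"treatment"` records the sign convention.
#' @export
fit_features <- function(values, groups, treatment = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop("exactly two group levels required, found: ",
         paste(lev, collapse = ", "))
  if (is.null(treatment)) {
    treatment <- lev[1L]
    message("treatment arm not given; using first level '", treatment,
            "' (fold change = ", treatment, " - ", setdiff(lev, treatment),
            ")")
  }
  if (!treatment %in% lev)
    stop("treatment level '", treatment, "' not found in groups")
  control <- setdiff(lev, treatment)
  if (sum(groups == treatment) < 2L || sum(groups == control) < 2L)
    stop("each group needs >= 2 samples")

  a <- values[, groups == treatment, drop = FALSE]
  b <- values[, groups == control, drop = FALSE]
  n_a <- rowSums(!is.na(a))
  n_b <- rowSums(!is.na(b))
  mean_a <- ifelse(n_a > 0, rowMeans(a, na.rm = TRUE), NA_real_)
  mean_b <- ifelse(n_b > 0, rowMeans(b, na.rm = TRUE), NA_real_)
  ss_a <- rowSums((a - mean_a)^2, na.rm = TRUE)
  ss_b <- rowSums((b - mean_b)^2, na.rm = TRUE)
  df <- pmax(n_a - 1L, 0L) + pmax(n_b - 1L, 0L)
  s2 <- ifelse(df > 0, (ss_a + ss_b) / df, NA_real_)

  out <- data.frame(
    feature_id = if (is.null(rownames(values)))
      as.character(seq_len(nrow(values))) else rownames(values),
    mean_a = mean_a, mean_b = mean_b,
    log2fc = mean_a - mean_b,
    s2 = s2, df = df, n_a = n_a, n_b = n_b,
    stringsAsFactors = FALSE)
  attr(out, "treatment") <- treatment
  attr(out, "control") <- control
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior `s2_g ~ s0sq * d0 / chisq(d0)`
#' across features by the method of moments on the log sample variances.
#' Writing `e_g = log(s2_g) - digamma(df_g / 2) + log(df_g / 2)` (an unbiased
#' estimator of `log(sigma2_g)` under the model), the prior degrees of
#' freedom solve
#' `trigamma(d0 / 2) = mean_g[(e_g - ebar)^2 * n / (n - 1) - trigamma(df_g / 2)]`
#' by monotone inversion of the trigamma function, and the prior variance is
#' `s0sq = exp(ebar + digamma(d0 / 2) - log(d0 / 2))`. When the moment target
#' is non-positive the data are under-dispersed relative to any finite prior
#' and the infinite-d0 limit is returned (`s0sq = exp(ebar)`, all variances
#' shrunk fully to the common value).
#'
#' @param s2 Numeric vector of per-feature residual variances.
#' @param df Numeric vector of residual degrees of freedom (recycled if
#'   length 1).
#' @return An object of class `ebayes_prior`: list with `d0` (prior degrees
#'   of freedom, possibly `Inf`), `s0sq` (prior variance), and `n_used`.
#' @export
estimate_prior <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  stopifnot(length(s2) == length(df))
  ok <- is.finite(s2) & is.finite(df) & df >= 1 & s2 > 0
  n_zero <- sum(is.finite(s2) & s2 <= 0)
  if (n_zero > 0)
    message(n_zero, " zero-variance feature(s) excluded from prior ",
            "estimation")
  s2 <- s2[ok]; df <- df[ok]
  n <- length(s2)
  if (n < 2L)
    stop("need >= 2 features with positive variance and df >= 1 to ",
         "estimate the variance prior (shrinkage is imprecise for very few ",
         "features)")
  if (n < 10L)
    warning("variance prior estimated from only ", n,
            " features; shrinkage hyperparameters will be imprecise")

  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  target <- mean((e - ebar)^2 * n / (n - 1) - trigamma(df / 2))
  if (target <= 0) {
    d0 <- Inf
    s0sq <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s0sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0sq = s0sq, n_used = n), class = "ebayes_prior")
}

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration with monotone
#' bracketing (trigamma is positive, strictly decreasing, and convex on the
#' positive axis). Tolerance 1e-8, at most 50 iterations.
#'
#' @param x Positive numeric scalar.
#' @return The positive solution `y`.
#' @keywords internal
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 50L) {
  stopifnot(is.finite(x), x > 0)
  # trigamma(y) ~ 1/y + 1/(2 y^2) for large y; ~ 1/y^2 for small y
  y <- 0.5 + 1 / x
  lo <- .Machine$double.eps
  hi <- Inf
  for (i in seq_len(max_iter)) {
    f <- trigamma(y) - x
    if (abs(f) < tol * x) break
    if (f > 0) lo <- y else hi <- y  # trigamma decreasing: f>0 means y too small
    step <- f / psigamma(y, deriv = 2L)  # Newton: f' = psigamma(., 2) < 0
    y_new <- y - step
    if (y_new <= lo || y_new >= hi)
      y_new <- if (is.finite(hi)) (lo + hi) / 2 else y * 2
    y <- y_new
  }
  y
}

#' Moderated t-statistics from fits and a variance prior
#'
#' Shrinks each feature's variance toward the prior,
#' `s2_post = (d0 * s0sq + df * s2) / (d0 + df)`, and tests the fold change
#' with `t = log2fc / sqrt(s2_post * (1/n_a + 1/n_b))` on `d0 + df` degrees
#' of freedom. Two-sided p-values use the upper-tail (survival) form for
#' numerical stability. Limits: `d0 = 0` reduces to the classical pooled
#' two-sample t-test; `d0 = Inf` gives every feature the common variance
#' `s0sq` and a Gaussian reference. Features with `df = 0` (no residual
#' replication) receive the prior variance with `d0` degrees of freedom and
#' are flagged in `flag`.
#'
#' @param fits Data frame from [fit_features()].
#' @param prior An `ebayes_prior`, or a list with elements `d0` and `s0sq`.
#' @return A `diff_result` data.frame: the fit columns plus `s2_post`,
#'   `df_total`, `t_mod`, `p`, and `flag`.
#' @export
moderated_t <- function(fits, prior) {
  d0 <- prior$d0
  s0sq <- prior$s0sq
  stopifnot(d0 >= 0, s0sq >= 0)
  s2 <- fits$s2
  df <- fits$df

  flag <- rep("", nrow(fits))
  no_resid <- df == 0 & fits$n_a >= 1 & fits$n_b >= 1
  if (is.infinite(d0)) {
    s2_post <- rep(s0sq, nrow(fits))
    df_total <- rep(Inf, nrow(fits))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- as.numeric(df)
  } else {
    s2_post <- (d0 * s0sq + df * ifelse(df > 0, s2, 0)) / (d0 + df)
    df_total <- d0 + df
  }
  flag[no_resid] <- "no_residual_df"

  se <- sqrt(s2_post * (1 / fits$n_a + 1 / fits$n_b))
  t_mod <- fits$log2fc / se
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)

  degenerate <- !is.na(se) & se == 0
  if (any(degenerate)) {
    lfc <- fits$log2fc[degenerate]
    t_mod[degenerate] <- ifelse(lfc == 0, 0, sign(lfc) * Inf)
    p[degenerate] <- ifelse(lfc == 0, 1, 0)
    flag[degenerate] <- paste0(flag[degenerate],
                               ifelse(flag[degenerate] == "", "", ";"),
                               "zero_variance")
  }
  empty_group <- fits$n_a < 1 | fits$n_b < 1
  p[empty_group] <- NA_real_
  t_mod[empty_group] <- NA_real_
  flag[empty_group] <- "missing_group"

  out <- fits
  out$s2_post <- s2_post
  out$df_total <- df_total
  out$t_mod <- t_mod
  out$p <- p
  out$flag <- flag
  attr(out, "prior") <- prior
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply `p_(i)` by `m / i`,
#' enforce monotonicity by a cumulative minimum from the largest rank, cap at
#' 1. Missing p-values are propagated and do not count toward `m`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of BH-adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Flag significant features
#'
#' A feature is called significant when its BH-adjusted p-value is below
#' `alpha` AND its absolute log2 fold change exceeds `log2(fc_threshold)`
#' (the symmetric two-sided reading of "fold change > 2").
#'
#' @param results A `diff_result` (from [moderated_t()]).
#' @param alpha FDR threshold; default 0.05.
#' @param fc_threshold Fold-change threshold on the linear scale; default 2.
#' @return `results` with columns `p_adj` and `significant` added and
#'   attributes `"alpha"` / `"fc_threshold"` set.
#' @export
call_significant <- function(results, alpha = 0.05, fc_threshold = 2) {
  results$p_adj <- bh_adjust(results$p)
  results$significant <- !is.na(results$p_adj) &
    results$p_adj < alpha &
    abs(results$log2fc) > log2(fc_threshold)
  attr(results, "alpha") <- alpha
  attr(results, "fc_threshold") <- fc_threshold
  results
}

#' Two-group moderated differential abundance analysis
#'
#' The full pipeline on a values matrix: per-feature fits, empirical-Bayes
#' variance prior, moderated t-statistics, BH adjustment, and significance
#' calls.
#'
#' @inheritParams fit_features
#' @inheritParams call_significant
#' @param annotations Optional data.frame of feature annotations (must
#'   contain `feature_id`) merged onto the result.
#' @return A `diff_result` data.frame ordered as the input features.
#' @export
diff_abundance <- function(values, groups, treatment = NULL, alpha = 0.05,
                           fc_threshold = 2, annotations = NULL) {
  fits <- fit_features(values, groups, treatment = treatment)
  prior <- estimate_prior(fits$s2, fits$df)
  res <- moderated_t(fits, prior)
  res <- call_significant(res, alpha = alpha, fc_threshold = fc_threshold)
  if (!is.null(annotations)) {
    keep_attrs <- attributes(res)[c("treatment", "control", "prior",
                                    "alpha", "fc_threshold")]
    res <- merge(annotations, res, by = "feature_id", sort = FALSE)
    res <- res[match(fits$feature_id, res$feature_id), , drop = FALSE]
    rownames(res) <- NULL
    for (a in names(keep_attrs)) attr(res, a) <- keep_attrs[[a]]
    class(res) <- c("diff_result", "data.frame")
  }
  res
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat("empirical-Bayes variance prior: d0 =", format(x$d0),
      " s0sq =", format(x$s0sq), " (from", x$n_used, "features)\n")
  invisible(x)
}
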