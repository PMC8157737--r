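#' Log2-transform an intensity matrix
#'
#' @param x Non-negative numeric matrix of intensities.
#' @param zero_policy How measured zeros are handled: `"missing"` (default;
#'   a zero carries no usable abundance on the log scale) or `"pseudocount"`
#'   (log2(x + 1)).
#' @return Matrix of log2 intensities, same dimensions as `x`.
#' @export
log2_transform <- function(x, zero_policy = c("missing", "pseudocount")) {
  zero_policy <- match.arg(zero_policy)
  if (any(x < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (zero_policy == "pseudocount") return(log2(x + 1))
  out <- x
  out[!is.na(out) & out == 0] <- NA_real_
  log2(out)
}

#' Total-intensity normalization of a PTM table
#'
#' Divides each modification's intensity by the sum of all modification
#' intensities in that sample (not just those of its peptide family). This is
#' robust to peptides carrying any number of modifications and makes the
#' per-sample values sum to one.
#'
#' @param ptm A `ptm_table`.
#' @return Matrix of per-sample proportions (rows = modifications).
#' @export
total_intensity_normalize <- function(ptm) {
  x <- ptm$intensities
  totals <- colSums(x, na.rm = TRUE)
  zero <- totals <= 0
  if (any(zero))
    stop("sample(s) with zero total intensity: ",
         paste(colnames(x)[zero], collapse = ", "))
  sweep(x, 2L, totals, "/")
}

#' Compute beta-values (regularized relative abundances)
#'
#' For modification i in peptide family F of sample s,
#' `beta_i = x_i / (sum_{j in F} x_j + offset)`: the share of the family's
#' signal carried by that modification state, with an additive offset in the
#' denominator that regularizes low-intensity families (shrinking their betas
#' toward zero). With `offset = 0` this is the plain percent-of-family value;
#' the default offset of 100 is on the raw intensity scale, so betas become
#' scale-dependent — the offset in force is recorded in the result.
#'
#' @param ptm A `ptm_table` (families defined at read time).
#' @param offset Non-negative regularization constant added to each family
#'   denominator; default 100.
#' @param eps Clamp width used when converting boundary betas to M-values.
#' @return `ptm` with `$beta` and `$m` matrices filled and attribute
#'   `"beta_offset"` set.
#' @export
compute_beta <- function(ptm, offset = 100, eps = 1e-6) {
  stopifnot(inherits(ptm, "ptm_table"), offset >= 0)
  x <- ptm$intensities
  fam <- ptm$keys$family_key
  beta <- x
  for (f in unique(fam)) {
    rows <- fam == f
    denom <- colSums(x[rows, , drop = FALSE], na.rm = TRUE) + offset
    denom[denom == 0] <- 1  # all-zero family with offset 0: betas stay 0
    beta[rows, ] <- sweep(x[rows, , drop = FALSE], 2L, denom, "/")
  }
  ptm$beta <- beta
  ptm$m <- beta_to_m(beta, eps = eps)
  attr(ptm, "beta_offset") <- offset
  ptm
}

#' Percent-of-family relative abundance
#'
#' The offset-free beta: each modification's intensity divided by its peptide
#' family total, so the nonzero families sum to one.
#'
#' @param ptm A `ptm_table`.
#' @return Matrix of within-family proportions.
#' @export
family_percent <- function(ptm) {
  compute_beta(ptm, offset = 0)$beta
}

#' Logit (M-value) transform of beta-values
#'
#' `M = log2(beta / (1 - beta))`. The M-value is unbounded and far closer to
#' Gaussian than the \[0, 1)-bounded beta, which is what the moderated t-test
#' assumes. Betas at exactly 0 or 1 are clamped to `eps` / `1 - eps` with a
#' warning (the logit is infinite there).
#'
#' @param beta Numeric vector or matrix of beta-values in \[0, 1\].
#' @param eps Clamp width for boundary values; default 1e-6.
#' @return M-values, same shape as `beta`.
#' @seealso [m_to_beta()] for the inverse.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  bound <- !is.na(beta) & (beta <= 0 | beta >= 1)
  if (any(bound)) {
    warning(sum(bound), " beta value(s) at the 0/1 boundary clamped to [",
            format(eps), ", ", format(1 - eps), "] before the logit")
    beta[!is.na(beta) & beta <= 0] <- eps
    beta[!is.na(beta) & beta >= 1] <- 1 - eps
  }
  log2(beta / (1 - beta))
}

#' Inverse logit: M-value back to beta
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta-values in (0, 1).
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Row-wise z-scoring of a log2 matrix
#'
#' Centers and scales each feature across samples: `(x - mean) / sd` with the
#' sample (n - 1) standard deviation, the usual scaling for heatmap display.
#' Constant rows (sd = 0) become all zeros with a warning; rows need at least
#' two non-missing values.
#'
#' @param x Numeric matrix (features x samples), typically log2 intensities.
#' @return Matrix of z-scores, same dimensions.
#' @export
zscore_rows <- function(x) {
  n_ok <- rowSums(!is.na(x))
  if (any(n_ok < 2L))
    stop("every row needs >= 2 non-missing values to z-score; ",
         sum(n_ok < 2L), " row(s) fail")
  mu <- rowMeans(x, na.rm = TRUE)
  sd_ <- apply(x, 1L, stats::sd, na.rm = TRUE)
  const <- sd_ == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) z-scored to all zeros")
    sd_[const] <- 1
  }
  (x - mu) / sd_
}
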