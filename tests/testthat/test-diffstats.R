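two_group <- function(n_per_group = 3) {
  rep(c("Treatment", "Control"), each = n_per_group)
}

test_that("per-feature fits compute pooled variance with honest df", {
  y <- rbind(a = c(1, 1, 3, 3),
             b = c(0, 2, 0, 2),
             c = c(1, NA, 3, 3))
  g <- c("Treatment", "Treatment", "Control", "Control")
  fits <- fit_features(y, g, treatment = "Treatment")
  expect_equal(fits$log2fc[1], -2)
  expect_equal(fits$s2[1], 0)
  expect_equal(fits$log2fc[2], 0)
  expect_equal(fits$s2[2], 2)   # pooled: (2 + 2) / 2
  expect_equal(fits$df[2], 2)
  expect_equal(fits$df[3], 1)   # one missing value costs one df
  expect_equal(fits$n_a[3], 1)

  expect_error(fit_features(y, rep("A", 4)), "two group")
  expect_error(fit_features(y, c("A", "A", "B", "C")), "two group")
})

test_that("trigamma inversion solves trigamma(y) = x across magnitudes", {
  for (x in c(1e-4, 0.01, 0.1, 1, 5, 100)) {
    y <- ptmdiff:::trigamma_inverse(x)
    expect_equal(trigamma(y), x, tolerance = 1e-7)
  }
})

test_that("prior estimation recovers its own generative model", {
  set.seed(301)
  d0 <- 8; s0sq <- 4; df <- 4
  s2 <- s0sq * d0 / rchisq(5000, df = d0) *
    rchisq(5000, df = df) / df
  prior <- estimate_prior(s2, df)
  expect_lt(abs(prior$d0 - d0) / d0, 0.2)
  expect_lt(abs(prior$s0sq - s0sq) / s0sq, 0.1)
})

test_that("prior estimation edge branches behave", {
  # under-dispersed variances force the infinite-d0 limit
  prior <- estimate_prior(rep(2, 200), df = 50)
  expect_true(is.infinite(prior$d0))
  expect_equal(prior$s0sq, exp(mean(log(2) - digamma(25) + log(25))),
               tolerance = 1e-10)

  expect_error(estimate_prior(c(1), df = 3), ">= 2")
  expect_warning(p2 <- estimate_prior(c(1, 2), df = 3), "only 2")
  expect_true(is.finite(p2$s0sq))
})

test_that("prior estimation matches the reference empirical-Bayes fit", {
  set.seed(302)
  s2 <- 0.5 * 6 / rchisq(800, df = 6) * rchisq(800, df = 4) / 4
  prior <- estimate_prior(s2, df = 4)
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(prior$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(prior$s0sq, sq$var.prior, tolerance = 1e-6)
})

test_that("moderated t reduces to the classical pooled t at d0 = 0", {
  set.seed(303)
  y <- matrix(rnorm(50 * 6), 50, 6)
  g <- two_group(3)
  fits <- fit_features(y, g, treatment = "Treatment")
  res <- moderated_t(fits, list(d0 = 0, s0sq = 1))
  for (i in seq_len(10)) {
    tt <- t.test(y[i, g == "Treatment"], y[i, g == "Control"],
                 var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("moderated t limits and degenerate variances are handled", {
  fits <- fit_features(rbind(a = c(1, 1, 3, 3), b = c(2, 2, 2, 2)),
                       c("T", "T", "C", "C"), treatment = "T")
  # infinite d0: every feature shares s0sq, Gaussian reference
  res <- moderated_t(fits, list(d0 = Inf, s0sq = 0.5))
  expect_equal(res$s2_post, c(0.5, 0.5))
  expect_equal(res$p[1], 2 * pnorm(abs(res$t_mod[1]), lower.tail = FALSE))
  # both s2 and s0sq zero: p = 0 for a real shift, 1 for none
  res0 <- moderated_t(fits, list(d0 = 4, s0sq = 0))
  expect_equal(res0$p, c(0, 1))
  expect_match(res0$flag[1], "zero_variance")
})

test_that("moderated t matches the reference pipeline end to end", {
  set.seed(304)
  y <- matrix(rnorm(200 * 6, sd = rep(sqrt(0.3 * 5 / rchisq(200, 5)), 6)),
              200, 6)
  g <- two_group(3)
  fits <- fit_features(y, g, treatment = "Treatment")
  prior <- estimate_prior(fits$s2, fits$df)
  res <- call_significant(moderated_t(fits, prior))

  design <- cbind(1, as.numeric(g == "Treatment"))
  eb <- limma::eBayes(limma::lmFit(y, design))
  expect_equal(prior$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(prior$s0sq, eb$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(eb$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(eb$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(305)
  for (i in 1:5) {
    p <- runif(97)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= 0))
  }
})

test_that("significance calls gate on both FDR and fold change", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    log2fc = c(1.5, 0.5, 3),
                    p = c(0.001, 0.001, 0.002))
  # construct p so BH-adjusted values land near 0.04 / 0.04 / 0.06 cases
  res$p <- c(0.013, 0.0265, 0.06)
  out <- call_significant(res, alpha = 0.05, fc_threshold = 2)
  expect_equal(out$p_adj >= out$p, rep(TRUE, 3))
  direct <- data.frame(feature_id = "x", log2fc = 1.5, p = 0.04)
  direct <- call_significant(direct)
  expect_true(direct$significant)
  expect_false(call_significant(
    data.frame(feature_id = "x", log2fc = 0.5, p = 0.04))$significant)
  expect_false(call_significant(
    data.frame(feature_id = "x", log2fc = 3, p = 0.06))$significant)
})

test_that("moderated test dominates the classical t on planted effects", {
  # with planted log2fc = 2 at 10% of features and n = 3/group, the
  # moderated test should find at least as many true positives at fixed
  # FDR on almost every seed
  wins <- 0L
  for (seed in 1:10) {
    sim <- simulate_protein(n_features = 800, n_per_group = 3,
                            frac_diff = 0.1, log2fc_effect = 2,
                            d0 = 8, s0sq = 0.25, seed = seed)
    y <- log2_transform(sim$matrix$intensities)
    g <- sim$meta$experimental_group
    fits <- fit_features(y, g, treatment = "Treatment")
    prior <- estimate_prior(fits$s2, fits$df)
    mod <- call_significant(moderated_t(fits, prior))
    cls <- call_significant(moderated_t(fits, list(d0 = 0, s0sq = 1)))
    truth <- sim$truth$is_differential
    if (sum(mod$significant & truth) >= sum(cls$significant & truth))
      wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("features with missing groups get flagged missing statistics", {
  y <- rbind(a = c(NA, NA, NA, 1, 2, 3), b = c(1, 2, 3, 4, 5, 6))
  fits <- fit_features(y, two_group(3), treatment = "Treatment")
  res <- moderated_t(fits, list(d0 = 4, s0sq = 0.5))
  expect_true(is.na(res$p[1]))
  expect_equal(res$flag[1], "missing_group")
  expect_false(is.na(res$p[2]))
})
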