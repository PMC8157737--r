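make_ptm <- function(keys, x) {
  rn <- paste(keys$histone_protein, paste0(keys$site, keys$modification),
              sep = "_")
  keys$family_key <- paste(keys$histone_protein, keys$site, sep = ":")
  keys <- cbind(feature_id = rn, keys, stringsAsFactors = FALSE)
  rownames(x) <- rn
  structure(list(keys = keys, intensities = x, beta = NULL, m = NULL),
            class = "ptm_table")
}

test_that("log2 transform handles zeros by policy and rejects negatives", {
  expect_equal(log2_transform(matrix(8)), matrix(3))
  expect_true(is.na(log2_transform(matrix(0))))
  expect_equal(log2_transform(matrix(0), zero_policy = "pseudocount"),
               matrix(0))
  expect_error(log2_transform(matrix(-1)), ">= 0")
})

test_that("total-intensity normalization yields per-sample proportions", {
  ptm <- make_ptm(data.frame(histone_protein = "H3",
                             site = c("K4", "K9", "K27"),
                             modification = "me"),
                  cbind(s1 = c(200, 300, 500)))
  expect_equal(unname(total_intensity_normalize(ptm)[, 1]),
               c(0.2, 0.3, 0.5))

  one <- make_ptm(data.frame(histone_protein = "H3", site = "K4",
                             modification = "me"), cbind(s1 = 42))
  expect_equal(unname(total_intensity_normalize(one)[, 1]), 1)

  set.seed(401)
  big <- make_ptm(data.frame(histone_protein = "H3",
                             site = paste0("K", 1:50),
                             modification = "me"),
                  matrix(runif(200, 1, 100), 50,
                         dimnames = list(NULL, paste0("s", 1:4))))
  sums <- colSums(total_intensity_normalize(big))
  expect_true(all(abs(sums - 1) < 1e-12))

  zero <- make_ptm(data.frame(histone_protein = "H3", site = "K4",
                              modification = "me"),
                   cbind(s1 = 0, s2 = 5))
  expect_error(total_intensity_normalize(zero), "zero total")
})

test_that("beta-values follow the offset-regularized family share", {
  ptm <- make_ptm(data.frame(histone_protein = "H3", site = "K27",
                             modification = c("me3", "ac")),
                  cbind(s1 = c(900, 100)))
  b <- compute_beta(ptm, offset = 100)$beta
  expect_equal(unname(b[, 1]), c(900 / 1100, 100 / 1100))

  zb <- compute_beta(make_ptm(data.frame(histone_protein = "H3",
                                         site = "K27",
                                         modification = c("me3", "ac")),
                              cbind(s1 = c(0, 0))), offset = 100)$beta
  expect_equal(unname(zb[, 1]), c(0, 0))

  b0 <- compute_beta(make_ptm(data.frame(histone_protein = "H3",
                                         site = "K27",
                                         modification = c("me3", "ac")),
                              cbind(s1 = c(1, 3))), offset = 0)$beta
  expect_equal(unname(b0[, 1]), c(0.25, 0.75))
})

test_that("beta properties: bounds, monotonicity, and scale behaviour", {
  set.seed(402)
  keys <- data.frame(histone_protein = rep(c("H3", "H4"), each = 6),
                     site = rep(c("K9", "K27", "K16", "K20"), each = 3),
                     modification = rep(c("unmod", "me", "ac"), 4))
  x <- matrix(runif(24, 0, 5000), 12,
              dimnames = list(NULL, c("s1", "s2")))
  ptm <- make_ptm(keys, x)
  bt <- compute_beta(ptm, offset = 100)
  expect_true(all(bt$beta >= 0 & bt$beta < 1))
  # family sums stay strictly below one because of the offset
  fam_sums <- rowsum(bt$beta, bt$keys$family_key)
  expect_true(all(fam_sums < 1))
  # within a family and sample, larger intensity means larger beta
  for (f in unique(keys$site)) {
    rows <- bt$keys$site == f
    expect_equal(order(x[rows, 1]), order(bt$beta[rows, 1]))
  }
  # offset 0: invariant to a common rescaling; offset > 0: downscaling
  # strictly decreases betas
  ptm_small <- make_ptm(keys, x / 10)
  expect_equal(compute_beta(ptm_small, offset = 0)$beta,
               compute_beta(ptm, offset = 0)$beta)
  expect_true(all(compute_beta(ptm_small, offset = 100)$beta <
                  compute_beta(ptm, offset = 100)$beta))
})

test_that("family percentages sum to one within each nonzero family", {
  set.seed(403)
  keys <- data.frame(histone_protein = "H3",
                     site = rep(paste0("K", c(4, 9, 27)), each = 4),
                     modification = rep(c("unmod", "me", "me2", "ac"), 3))
  x <- matrix(runif(36, 1, 100), 12,
              dimnames = list(NULL, paste0("s", 1:3)))
  ptm <- make_ptm(keys, x)
  fp <- family_percent(ptm)
  # oracle: independent group-by summation
  for (f in unique(ptm$keys$family_key)) {
    rows <- ptm$keys$family_key == f
    expect_equal(unname(colSums(fp[rows, , drop = FALSE])), rep(1, 3),
                 tolerance = 1e-12)
  }
  single <- make_ptm(data.frame(histone_protein = "H3", site = "K4",
                                modification = "me"), cbind(s1 = 7))
  expect_equal(unname(family_percent(single)[, 1]), 1)
})

test_that("the logit M-value transform and its inverse agree", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_warning(m0 <- beta_to_m(0), "clamped")
  expect_equal(m0, log2(1e-6 / (1 - 1e-6)))
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
  # strictly increasing, and inverse identity on the open interval
  b <- seq(1e-5, 1 - 1e-5, length.out = 101)
  m <- beta_to_m(b)
  expect_true(all(diff(m) > 0))
  expect_equal(m_to_beta(m), b, tolerance = 1e-12)
})

test_that("row z-scoring centers and scales with the n-1 convention", {
  expect_equal(unname(zscore_rows(rbind(c(1, 2, 3)))[1, ]), c(-1, 0, 1))
  expect_warning(zc <- zscore_rows(rbind(c(5, 5, 5))), "constant")
  expect_equal(unname(zc[1, ]), c(0, 0, 0))
  expect_error(zscore_rows(rbind(c(1, NA, NA))), ">= 2")

  set.seed(404)
  x <- matrix(rnorm(600), 100, 6)
  z <- zscore_rows(x)
  # oracle: direct recomputation per row
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
})
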