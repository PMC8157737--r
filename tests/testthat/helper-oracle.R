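# Independent oracles, written as literal transcriptions of the closed-form
# definitions with plain loops. They deliberately share no code with the
# package internals they check.

# Per-feature two-group fit by explicit iteration.
oracle_fits <- function(y, groups, treatment) {
  control <- setdiff(unique(groups), treatment)
  out <- data.frame(log2fc = numeric(nrow(y)), s2 = NA_real_, df = 0,
                    n_a = 0, n_b = 0)
  for (g in seq_len(nrow(y))) {
    xa <- y[g, groups == treatment]
    xb <- y[g, groups == control]
    xa <- xa[!is.na(xa)]
    xb <- xb[!is.na(xb)]
    out$n_a[g] <- length(xa)
    out$n_b[g] <- length(xb)
    out$log2fc[g] <- mean(xa) - mean(xb)
    df <- (length(xa) - 1) + (length(xb) - 1)
    out$df[g] <- df
    if (df > 0)
      out$s2[g] <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / df
  }
  out
}

# Moderated t and two-sided p for given prior hyperparameters.
oracle_modt <- function(fits, d0, s0sq) {
  n <- nrow(fits)
  t_mod <- p <- numeric(n)
  for (g in seq_len(n)) {
    df <- fits$df[g]
    if (is.infinite(d0)) {
      s2_post <- s0sq
      df_total <- Inf
    } else if (d0 == 0) {
      s2_post <- fits$s2[g]
      df_total <- df
    } else {
      s2_post <- (d0 * s0sq + df * fits$s2[g]) / (d0 + df)
      df_total <- d0 + df
    }
    se <- sqrt(s2_post * (1 / fits$n_a[g] + 1 / fits$n_b[g]))
    t_mod[g] <- fits$log2fc[g] / se
    p[g] <- 2 * pt(abs(t_mod[g]), df = df_total, lower.tail = FALSE)
  }
  data.frame(t_mod = t_mod, p = p)
}

# Benjamini-Hochberg step-up by the textbook recipe.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Write a data.frame as a throw-away CSV and return the path.
tmp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

# Small well-formed protein table + matching metadata for IO tests.
toy_protein_csv <- function() {
  tmp_csv(data.frame(
    uniprot_id = c("P10000", "P20000", "P30000"),
    gene_id = c("Oxt", "Slc6a11", "Prmt5"),
    description = c("oxytocin", "GABA transporter 3",
                    "arginine methyltransferase 5"),
    s1 = c(100, 200, 300), s2 = c(110, 190, 310),
    s3 = c(400, 50, 305), s4 = c(390, 60, 295),
    check.names = FALSE))
}

toy_metadata_csv <- function(files = c("s1", "s2", "s3", "s4")) {
  tmp_csv(data.frame(
    "File name" = files,
    "Sample group" = "Nucleus Accumbens",
    "Replicate" = c(1, 2, 1, 2),
    "Experimental group" = c("Treatment", "Treatment",
                             "Control", "Control"),
    check.names = FALSE))
}
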