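#' Simulate a whole-proteome intensity matrix with known ground truth
#'
#' Draws data from the generative model the moderated t-test assumes: each
#' feature's true variance comes from a scaled inverse-chi-square prior
#' (`sigma2_g = s0sq * d0 / chisq(d0)`), log2 abundances are Gaussian around
#' a feature baseline, a fixed fraction of features carries a mean shift of
#' `log2fc_effect` (random sign) in the treatment arm, and the matrix is
#' exported on the raw exponentiated intensity scale so the pipeline's own
#' log2 step is exercised. A configurable number of gene symbols is drawn
#' from the bundled modifier catalogue so annotation matching is exercised
#' too.
#'
#' @param n_features Number of protein features.
#' @param n_per_group Samples per arm (>= 2).
#' @param frac_diff Fraction of features with a planted effect.
#' @param log2fc_effect Planted mean shift in log2 units.
#' @param d0,s0sq Variance-prior hyperparameters of the generative model.
#' @param baseline_mean,baseline_sd Feature baseline log2 abundances are
#'   `Normal(baseline_mean, baseline_sd)`; defaults 25 and 3, the typical
#'   location and spread of log2 MS1 intensities.
#' @param miss_rate Missing-completely-at-random cell rate; default 0.
#' @param n_modifier_genes How many features receive gene symbols from the
#'   bundled modifier catalogue.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed (caller RNG state is untouched).
#' @return List with `matrix` (a `protein_matrix`), `meta`
#'   (`sample_metadata`), `truth` (data.frame: `feature_id`,
#'   `is_differential`, `true_log2fc`, `true_s2`), and `params`.
#' @export
simulate_protein <- function(n_features = 2000, n_per_group = 3,
                             frac_diff = 0.1, log2fc_effect = 2,
                             d0 = 8, s0sq = 0.25,
                             baseline_mean = 25, baseline_sd = 3,
                             miss_rate = 0, n_modifier_genes = 10,
                             seed = 1) {
  stopifnot(n_features >= 1, frac_diff >= 0, frac_diff <= 1,
            d0 > 0, s0sq > 0, miss_rate >= 0, miss_rate < 1)
  if (n_per_group < 2) stop("n_per_group must be >= 2")

  with_seed(seed, {
    n_samp <- 2L * n_per_group
    is_trt <- rep(c(TRUE, FALSE), each = n_per_group)

    sigma2 <- if (is.infinite(d0)) rep(s0sq, n_features)
              else s0sq * d0 / stats::rchisq(n_features, df = d0)
    baseline <- stats::rnorm(n_features, baseline_mean, baseline_sd)

    n_diff <- round(frac_diff * n_features)
    diff_idx <- sample.int(n_features, n_diff)
    true_lfc <- numeric(n_features)
    if (n_diff > 0)
      true_lfc[diff_idx] <- log2fc_effect *
        sample(c(-1, 1), n_diff, replace = TRUE)

    y <- baseline +
      outer(true_lfc, as.numeric(is_trt)) +
      matrix(stats::rnorm(n_features * n_samp, sd = rep(sqrt(sigma2), n_samp)),
             n_features, n_samp)
    intens <- 2^y
    if (miss_rate > 0)
      intens[stats::runif(length(intens)) < miss_rate] <- NA_real_

    ids <- sprintf("P%05d", seq_len(n_features))
    genes <- sprintf("Gene%04d", seq_len(n_features))
    mod_genes <- bundled_modifier_genes()
    k <- min(n_modifier_genes, length(mod_genes), n_features)
    if (k > 0) genes[sample.int(n_features, k)] <- mod_genes[seq_len(k)]

    colnames(intens) <- sprintf("intensity_%d", seq_len(n_samp))
    rownames(intens) <- ids
    ann <- data.frame(feature_id = ids, uniprot_id = ids, gene_id = genes,
                      description = sprintf("synthetic protein %d",
                                            seq_len(n_features)),
                      stringsAsFactors = FALSE)
    mat <- structure(list(annotations = ann, intensities = intens),
                     class = "protein_matrix")

    meta <- data.frame(
      file_name = colnames(intens),
      sample_group = "Synthetic Tissue",
      replicate = rep(seq_len(n_per_group), 2L),
      experimental_group = ifelse(is_trt, "Treatment", "Control"),
      stringsAsFactors = FALSE)
    meta <- validate_metadata(meta)

    truth <- data.frame(feature_id = ids,
                        is_differential = true_lfc != 0,
                        true_log2fc = true_lfc,
                        true_s2 = sigma2,
                        stringsAsFactors = FALSE)
    list(matrix = mat, meta = meta, truth = truth,
         params = list(n_features = n_features, n_per_group = n_per_group,
                       frac_diff = frac_diff, log2fc_effect = log2fc_effect,
                       d0 = d0, s0sq = s0sq, miss_rate = miss_rate,
                       seed = seed))
  })
}

#' Simulate a histone PTM intensity table with known ground truth
#'
#' Each peptide family's within-family composition follows a Dirichlet
#' distribution around group-specific mean proportions; planted shifts move
#' the treatment-arm mean proportion of chosen modifications. Absolute family
#' abundance is log-normal around `intensity_scale`, so exported intensities
#' are on a realistic raw scale. Site labels follow histone nomenclature
#' (H3 K9me, H3 K27me3, H4 K16ac, ...), exercising label handling downstream.
#'
#' @param families Integer vector of family sizes (modification states per
#'   site).
#' @param n_per_group Samples per arm (>= 2).
#' @param planted_shifts Data frame with columns `family` (index into
#'   `families`), `member` (index within the family), and `delta` (additive
#'   shift of that member's treatment-arm mean proportion; the remaining
#'   members are rescaled to keep the composition on the simplex). `NULL`
#'   (default) plants nothing.
#' @param intensity_scale Median total family intensity; default 1e5.
#' @param concentration Dirichlet concentration controlling replicate
#'   noise; default 200 (roughly 2-4% SD on mid-range proportions, typical
#'   of replicate histone PTM measurements).
#' @param seed Integer seed.
#' @return List with `ptm` (a `ptm_table`), `meta`, `truth` (per-row mean
#'   proportions in both arms and the differential flag), and `params`.
#' @export
simulate_ptm <- function(families = rep(4L, 20L), n_per_group = 3,
                         planted_shifts = NULL, intensity_scale = 1e5,
                         concentration = 200, seed = 1) {
  stopifnot(all(families >= 1), intensity_scale > 0, concentration > 0)
  if (n_per_group < 2) stop("n_per_group must be >= 2")

  with_seed(seed, {
    n_fam <- length(families)
    cat_sites <- histone_site_catalogue(n_fam)
    n_samp <- 2L * n_per_group
    is_trt <- rep(c(TRUE, FALSE), each = n_per_group)

    keys <- NULL
    p_ctl_all <- p_trt_all <- numeric(0)
    intens <- NULL
    is_diff_all <- logical(0)

    for (f in seq_len(n_fam)) {
      k <- families[f]
      mods <- modification_labels(k)
      p <- stats::rgamma(k, shape = 2)
      p <- p / sum(p)
      q <- p
      is_diff <- logical(k)
      if (!is.null(planted_shifts)) {
        sh <- planted_shifts[planted_shifts$family == f, , drop = FALSE]
        for (j in seq_len(nrow(sh))) {
          m <- sh$member[j]
          q[m] <- p[m] + sh$delta[j]
          is_diff[m] <- TRUE
        }
        rest <- setdiff(seq_len(k), sh$member)
        if (length(rest))
          q[rest] <- p[rest] * (1 - sum(q[sh$member])) / sum(p[rest])
        if (any(q <= 0 | q >= 1) || abs(sum(q) - 1) > 1e-8)
          stop("infeasible planted shift in family ", f,
               ": mean proportions must stay inside (0, 1)")
      }
      prop <- matrix(0, k, n_samp)
      for (s in seq_len(n_samp)) {
        mean_p <- if (is_trt[s]) q else p
        g <- stats::rgamma(k, shape = concentration * mean_p)
        prop[, s] <- g / sum(g)
      }
      total <- exp(stats::rnorm(n_samp, log(intensity_scale), 0.3))
      x <- sweep(prop, 2L, total, "*")

      keys <- rbind(keys, data.frame(
        histone_protein = cat_sites$histone[f],
        site = cat_sites$site[f],
        modification = mods,
        stringsAsFactors = FALSE))
      p_ctl_all <- c(p_ctl_all, p)
      p_trt_all <- c(p_trt_all, q)
      is_diff_all <- c(is_diff_all, is_diff)
      intens <- rbind(intens, x)
    }

    keys$family_key <- paste(keys$histone_protein, keys$site, sep = ":")
    rn <- paste(keys$histone_protein,
                paste0(keys$site, keys$modification), sep = "_")
    keys <- cbind(feature_id = rn, keys, stringsAsFactors = FALSE)
    rownames(intens) <- rn
    colnames(intens) <- sprintf("intensity_%d", seq_len(n_samp))

    ptm <- structure(list(keys = keys, intensities = intens,
                          beta = NULL, m = NULL), class = "ptm_table")

    meta <- data.frame(
      file_name = colnames(intens),
      sample_group = "Synthetic Tissue",
      replicate = rep(seq_len(n_per_group), 2L),
      experimental_group = ifelse(is_trt, "Treatment", "Control"),
      stringsAsFactors = FALSE)
    meta <- validate_metadata(meta)

    truth <- data.frame(feature_id = rn,
                        is_differential = is_diff_all,
                        mean_prop_treatment = p_trt_all,
                        mean_prop_control = p_ctl_all,
                        stringsAsFactors = FALSE)
    list(ptm = ptm, meta = meta, truth = truth,
         params = list(families = families, n_per_group = n_per_group,
                       intensity_scale = intensity_scale,
                       concentration = concentration, seed = seed))
  })
}

# Real histone sites, recycled with numeric suffixes when more families are
# requested than the catalogue holds.
histone_site_catalogue <- function(n) {
  base <- data.frame(
    histone = c("H3", "H3", "H4", "H3", "H3", "H3.3", "H4", "H4", "H4",
                "H2A", "H2B", "H3", "H3", "H4", "H3.3"),
    site = c("K9", "K27", "K16", "K4", "K36", "K27", "K5", "K8", "K12",
             "K5", "K120", "K14", "K18", "K20", "K36"),
    stringsAsFactors = FALSE)
  idx <- ((seq_len(n) - 1L) %% nrow(base)) + 1L
  out <- base[idx, , drop = FALSE]
  round_ <- (seq_len(n) - 1L) %/% nrow(base)
  out$site <- ifelse(round_ > 0, paste0(out$site, ".", round_), out$site)
  rownames(out) <- NULL
  out
}

modification_labels <- function(k) {
  pool <- c("unmod", "me", "me2", "me3", "ac", "ph", "ub")
  if (k <= length(pool)) pool[seq_len(k)]
  else c(pool, sprintf("mod%d", seq_len(k - length(pool))))
}

bundled_modifier_genes <- function() {
  path <- system.file("extdata", "modifier_catalogue.csv",
                      package = "ptmdiff")
  if (!nzchar(path)) return(character(0))
  unique(utils::read.csv(path, stringsAsFactors = FALSE)$protein_id)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a simulated dataset as the CSV files the readers consume
#'
#' Emits `data.csv` (annotations or PTM keys plus raw intensities),
#' `metadata.csv` (the sample-metadata schema), and `truth.csv` (the
#' ground-truth sidecar, kept separate from the data file).
#'
#' @param sim Result of [simulate_protein()] or [simulate_ptm()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "data.csv")
  meta_path <- file.path(dir, "metadata.csv")
  truth_path <- file.path(dir, "truth.csv")

  if (!is.null(sim$matrix)) {
    df <- cbind(sim$matrix$annotations[, c("uniprot_id", "gene_id",
                                           "description")],
                as.data.frame(sim$matrix$intensities))
  } else {
    df <- cbind(sim$ptm$keys[, c("histone_protein", "site", "modification")],
                as.data.frame(sim$ptm$intensities))
    names(df)[1] <- "histone_protein"
  }
  utils::write.csv(df, data_path, row.names = FALSE)

  meta <- as.data.frame(sim$meta)
  names(meta) <- c("File name", "Sample group", "Replicate",
                   "Experimental group", "Custom ID")
  utils::write.csv(meta, meta_path, row.names = FALSE)
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  invisible(c(data = data_path, metadata = meta_path, truth = truth_path))
}
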