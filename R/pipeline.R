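#' Run the whole-proteome differential abundance workflow
#'
#' End-to-end protein analysis: read the intensity matrix and metadata, bind
#' them, log2-transform, run the moderated differential analysis, optionally
#' annotate chromatin modifiers, and write all artifacts into `out_dir`:
#' the four result tables (all results; significant only; normalized log2
#' abundances for all proteins; normalized abundances of the significant
#' set), preliminary plots, volcano and heatmap with their data sidecars,
#' and a run log echoing every parameter so the run is reproducible from the
#' log alone.
#'
#' @param data_path CSV of protein intensities (see
#'   [read_protein_matrix()]).
#' @param metadata_path CSV of sample metadata (see [read_metadata()]).
#' @param modifier_db_path Optional CSV of writer/eraser/reader proteins.
#' @param organism Organism for modifier matching (required with
#'   `modifier_db_path`).
#' @param treatment Experimental-group level treated as the treatment arm;
#'   default: first level in order of appearance in the metadata.
#' @param alpha FDR threshold; default 0.05.
#' @param fc_threshold Fold-change threshold; default 2.
#' @param zero_policy Zero handling for the log2 transform.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the `diff_result` table.
#' @export
run_protein <- function(data_path, metadata_path, modifier_db_path = NULL,
                        organism = NULL, treatment = NULL, alpha = 0.05,
                        fc_threshold = 2,
                        zero_policy = c("missing", "pseudocount"),
                        out_dir = ".") {
  zero_policy <- match.arg(zero_policy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pm <- read_protein_matrix(data_path)
  meta <- read_metadata(metadata_path)
  pm <- bind_samples(pm, meta)
  if (is.null(treatment)) treatment <- attr(meta, "arms")[1L]

  log2_mat <- log2_transform(pm$intensities, zero_policy = zero_policy)
  res <- diff_abundance(log2_mat, pm$meta$experimental_group,
                        treatment = treatment, alpha = alpha,
                        fc_threshold = fc_threshold,
                        annotations = pm$annotations)
  if (!is.null(modifier_db_path)) {
    if (is.null(organism))
      stop("organism must be given when a modifier catalogue is supplied")
    db <- read_modifier_db(modifier_db_path)
    res <- match_modifiers(res, db, organism)
  }

  write_result_tables(res, log2_mat, pm$annotations, out_dir)

  prelim <- preliminary_plots(log2_mat, pm$meta)
  for (nm in names(prelim))
    save_plot(prelim[[nm]], file.path(out_dir, paste0(nm, ".png")),
              file.path(out_dir, paste0(nm, "_data.csv")))
  save_plot(plot_volcano(res), file.path(out_dir, "volcano.png"),
            file.path(out_dir, "volcano_data.csv"))
  sig_ids <- res$feature_id[res$significant]
  if (length(sig_ids) >= 1L) {
    z_rows <- log2_mat[sig_ids, , drop = FALSE]
    z_rows <- z_rows[rowSums(!is.na(z_rows)) >= 2L, , drop = FALSE]
    hm <- plot_heatmap(zscore_rows(z_rows), pm$meta)
    save_plot(hm, file.path(out_dir, "heatmap.png"),
              file.path(out_dir, "heatmap_data.csv"))
  } else {
    message("no significant features to draw; skipping heatmap")
  }

  write_run_log(file.path(out_dir, "run_log.txt"), list(
    workflow = "protein", data = data_path, metadata = metadata_path,
    modifier_db = modifier_db_path %||% "none",
    organism = organism %||% "none",
    treatment = treatment,
    fold_change_convention = paste0(treatment, " - ",
                                    attr(res, "control")),
    alpha = alpha, fc_threshold = fc_threshold,
    zero_policy = zero_policy,
    prior_d0 = attr(res, "prior")$d0, prior_s0sq = attr(res, "prior")$s0sq,
    n_features = nrow(res), n_significant = sum(res$significant)))
  invisible(res)
}

#' Run the histone PTM differential abundance workflow
#'
#' Reads a PTM intensity table and metadata, computes beta and M relative
#' abundances with the configured family offset, runs the moderated
#' differential analysis on M-values (or on log2 intensities), and writes
#' the beta/M-augmented PTM table, the result tables, the stacked beta bar
#' chart, the significant-PTM M-value heatmap, volcano, and a run log.
#'
#' @inheritParams run_protein
#' @param data_path CSV of PTM intensities (see [read_ptm_table()]).
#' @param value_mode Values handed to the moderated t-test: `"m_value"`
#'   (default; the logit relative abundances) or `"log2_intensity"`.
#' @param offset Beta-value regularization offset; default 100.
#' @param family_key_rule Passed to [read_ptm_table()].
#' @return Invisibly, the `diff_result` table.
#' @export
run_ptm <- function(data_path, metadata_path,
                    value_mode = c("m_value", "log2_intensity"),
                    offset = 100, treatment = NULL, alpha = 0.05,
                    fc_threshold = 2,
                    family_key_rule = c("histone_site", "histone_peptide"),
                    out_dir = ".") {
  value_mode <- match.arg(value_mode)
  family_key_rule <- match.arg(family_key_rule)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ptm <- read_ptm_table(data_path, family_key_rule = family_key_rule)
  meta <- read_metadata(metadata_path)
  ptm <- bind_samples(ptm, meta)
  if (is.null(treatment)) treatment <- attr(meta, "arms")[1L]
  ptm <- compute_beta(ptm, offset = offset)

  aug <- cbind(ptm$keys,
               as.data.frame(ptm$intensities),
               stats::setNames(as.data.frame(ptm$beta),
                               paste0("beta_", colnames(ptm$beta))),
               stats::setNames(as.data.frame(ptm$m),
                               paste0("m_", colnames(ptm$m))))
  utils::write.csv(aug, file.path(out_dir, "ptm_relative_abundance.csv"),
                   row.names = FALSE)

  values <- if (value_mode == "m_value") ptm$m
            else log2_transform(ptm$intensities)
  res <- diff_abundance(values, ptm$meta$experimental_group,
                        treatment = treatment, alpha = alpha,
                        fc_threshold = fc_threshold,
                        annotations = ptm$keys)
  write_result_tables(res, values, ptm$keys, out_dir,
                      value_label = value_mode)

  save_plot(plot_stacked_bars(ptm),
            file.path(out_dir, "stacked_bars.png"),
            file.path(out_dir, "stacked_bars_data.csv"))
  save_plot(plot_volcano(res), file.path(out_dir, "volcano.png"),
            file.path(out_dir, "volcano_data.csv"))
  sig_ids <- res$feature_id[res$significant]
  hm <- plot_ptm_heatmap(ptm, sig_ids)
  save_plot(hm, file.path(out_dir, "ptm_heatmap.png"),
            file.path(out_dir, "ptm_heatmap_data.csv"))

  write_run_log(file.path(out_dir, "run_log.txt"), list(
    workflow = "ptm", data = data_path, metadata = metadata_path,
    value_mode = value_mode, beta_offset = offset,
    family_key_rule = family_key_rule,
    treatment = treatment,
    fold_change_convention = paste0(treatment, " - ", attr(res, "control")),
    alpha = alpha, fc_threshold = fc_threshold,
    prior_d0 = attr(res, "prior")$d0, prior_s0sq = attr(res, "prior")$s0sq,
    n_features = nrow(res), n_significant = sum(res$significant)))
  invisible(res)
}

#' Generate and write a synthetic dataset
#'
#' Thin wrapper over [simulate_protein()] / [simulate_ptm()] +
#' [write_simulation()] for scripted use.
#'
#' @param kind `"protein"` or `"ptm"`.
#' @param params Named list of generator arguments (see the simulators).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
run_simulate <- function(kind = c("protein", "ptm"), params = list(),
                         seed = 1, out_dir = ".") {
  kind <- match.arg(kind)
  params$seed <- seed
  sim <- do.call(if (kind == "protein") simulate_protein else simulate_ptm,
                 params)
  paths <- write_simulation(sim, out_dir)
  write_run_log(file.path(out_dir, "run_log.txt"),
                c(list(workflow = paste0("simulate_", kind)), sim$params))
  invisible(paths)
}

write_result_tables <- function(res, values, annotations, out_dir,
                                value_label = "log2") {
  res_df <- as.data.frame(res)
  utils::write.csv(res_df, file.path(out_dir, "results_all.csv"),
                   row.names = FALSE)
  utils::write.csv(res_df[res_df$significant, , drop = FALSE],
                   file.path(out_dir, "results_significant.csv"),
                   row.names = FALSE)
  norm <- cbind(annotations, as.data.frame(values))
  utils::write.csv(norm, file.path(out_dir, "normalized_all.csv"),
                   row.names = FALSE)
  utils::write.csv(
    norm[res_df$significant, , drop = FALSE],
    file.path(out_dir, "normalized_significant.csv"), row.names = FALSE)
  invisible(NULL)
}

write_run_log <- function(path, fields) {
  lines <- c(
    paste0("ptmdiff ", as.character(utils::packageVersion("ptmdiff"))),
    paste0("R ", R.version.string),
    paste0("date ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    vapply(names(fields), function(k)
      paste0(k, " = ", paste(format(fields[[k]]), collapse = " ")),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}
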