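#' Preliminary diagnostic plots of a bound log2 matrix
#'
#' Builds the four standard quality-control views of a bound dataset:
#' a histogram of all log2 abundances, per-sample boxplots labelled by
#' `custom_id`, a PCA of the samples on centered log2 values (features as
#' variables, complete rows only, percent variance in the axis labels), and a
#' classical MDS on Euclidean sample distances. Each element pairs a ggplot
#' with the data frame behind it so plots are testable without pixel
#' comparison.
#'
#' @param values Numeric matrix of log2 values, features x samples, columns
#'   named by `custom_id`.
#' @param meta The `sample_metadata` bound to the matrix.
#' @return List with elements `histogram`, `boxplot`, `pca`, `mds`, each a
#'   list of `plot` (ggplot) and `data` (data.frame).
#' @export
preliminary_plots <- function(values, meta) {
  if (ncol(values) < 2L) stop("need >= 2 samples for preliminary plots")
  long <- data.frame(
    custom_id = rep(colnames(values), each = nrow(values)),
    value = as.vector(values),
    stringsAsFactors = FALSE)
  long <- long[is.finite(long$value), , drop = FALSE]
  long$experimental_group <-
    meta$experimental_group[match(long$custom_id, meta$custom_id)]

  hist_p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey40") +
    ggplot2::labs(x = "log2 abundance", y = "count",
                  title = "Abundance distribution")
  box_p <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data$custom_id, y = .data$value,
      fill = .data$experimental_group)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "log2 abundance", fill = "group") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))

  complete <- values[stats::complete.cases(values), , drop = FALSE]
  if (nrow(complete) < 3L)
    stop("need >= 3 complete feature rows for PCA, found ", nrow(complete))
  pc <- stats::prcomp(t(complete), center = TRUE, scale. = FALSE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  pca_df <- data.frame(custom_id = colnames(values),
                       PC1 = pc$x[, 1L], PC2 = pc$x[, 2L],
                       experimental_group = meta$experimental_group[
                         match(colnames(values), meta$custom_id)],
                       stringsAsFactors = FALSE)
  pca_p <- ggplot2::ggplot(pca_df, ggplot2::aes(
      x = .data$PC1, y = .data$PC2, colour = .data$experimental_group,
      label = .data$custom_id)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1L]),
                  y = sprintf("PC2 (%.1f%%)", pct[2L]), colour = "group")

  mds <- stats::cmdscale(stats::dist(t(complete)), k = 2)
  mds_df <- data.frame(custom_id = colnames(values),
                       dim1 = mds[, 1L], dim2 = mds[, 2L],
                       experimental_group = pca_df$experimental_group,
                       stringsAsFactors = FALSE)
  mds_p <- ggplot2::ggplot(mds_df, ggplot2::aes(
      x = .data$dim1, y = .data$dim2, colour = .data$experimental_group,
      label = .data$custom_id)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "group")

  list(histogram = list(plot = hist_p, data = long),
       boxplot = list(plot = box_p, data = long),
       pca = list(plot = pca_p, data = pca_df),
       mds = list(plot = mds_p, data = mds_df))
}

#' Volcano plot of differential results
#'
#' Scatter of log2 fold change against `-log10` of either the raw or the
#' BH-adjusted p-value, with the significant set in red, modifier-catalogue
#' matches in blue, dashed threshold lines at the fold-change and alpha
#' cut-offs, and the hover fields (Uniprot id, gene id, description, log2FC,
#' p) carried in the category table. `modifiers_only = TRUE` restricts the
#' display to catalogue matches.
#'
#' @param results A `diff_result` with `p_adj`/`significant` (see
#'   [call_significant()]); modifier columns are used when present.
#' @param alpha,fc_threshold Thresholds drawn as dashed lines; default to the
#'   values stored on `results`.
#' @param y_mode `"adjusted"` (default) plots `-log10(p_adj)`, `"raw"` plots
#'   `-log10(p)`.
#' @param modifiers_only Show only modifier-catalogue matches.
#' @return List of `plot` and `data` (one row per result row: hover fields,
#'   `neg_log10`, `category`).
#' @export
plot_volcano <- function(results, alpha = attr(results, "alpha"),
                         fc_threshold = attr(results, "fc_threshold"),
                         y_mode = c("adjusted", "raw"),
                         modifiers_only = FALSE) {
  y_mode <- match.arg(y_mode)
  if (is.null(alpha)) alpha <- 0.05
  if (is.null(fc_threshold)) fc_threshold <- 2
  y_p <- if (y_mode == "adjusted") results$p_adj else results$p

  neg_log10 <- -log10(y_p)
  finite_max <- suppressWarnings(max(neg_log10[is.finite(neg_log10)],
                                     na.rm = TRUE))
  if (!is.finite(finite_max)) finite_max <- 0
  # -log10(0) is clipped to the largest finite value plus one unit
  neg_log10[!is.na(y_p) & y_p == 0] <- finite_max + 1

  category <- rep("other", nrow(results))
  if (!is.null(results$is_modifier)) category[results$is_modifier] <- "modifier"
  category[isTRUE_vec(results$significant)] <- "significant"

  dat <- data.frame(
    feature_id = results$feature_id,
    uniprot_id = results$uniprot_id %||% NA_character_,
    gene_id = results$gene_id %||% NA_character_,
    description = results$description %||% NA_character_,
    log2fc = results$log2fc,
    p = results$p,
    p_adj = results$p_adj,
    neg_log10 = neg_log10,
    category = category,
    stringsAsFactors = FALSE)
  shown <- if (modifiers_only) dat[dat$category == "modifier" |
                                   (!is.null(results$is_modifier) &
                                    isTRUE_vec(results$is_modifier)), ,
                                   drop = FALSE] else dat

  p <- ggplot2::ggplot(shown, ggplot2::aes(
      x = .data$log2fc, y = .data$neg_log10, colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(significant = "red",
                                            modifier = "blue",
                                            other = "grey60")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change",
                  y = if (y_mode == "adjusted") "-log10 adjusted p"
                      else "-log10 p")
  list(plot = p, data = dat)
}

#' Clustered heatmap of significant features
#'
#' Rows (features) are ordered by hierarchical clustering on Euclidean
#' distance with complete linkage; columns stay in metadata order, labelled
#' by `custom_id`. With zero rows the function messages and returns `NULL`
#' (an informative no-op, not a crash); a single row is drawn without
#' clustering.
#'
#' @param values Numeric matrix of the significant features (z-scores for
#'   protein data, M-values for PTM data), columns named by `custom_id`.
#' @param meta The bound `sample_metadata` (fixes column order).
#' @param value_name Legend label; default `"z-score"`.
#' @param cluster_method Agglomeration method passed to [stats::hclust()].
#' @return `NULL` if `values` has no rows, else a list of `plot`, `data`
#'   (long form: feature, custom_id, value), and `row_order`.
#' @export
plot_heatmap <- function(values, meta, value_name = "z-score",
                         cluster_method = "complete") {
  if (is.null(values) || nrow(values) == 0L) {
    message("no significant features to draw; skipping heatmap")
    return(invisible(NULL))
  }
  cols <- intersect(meta$custom_id, colnames(values))
  values <- values[, cols, drop = FALSE]
  row_order <- if (nrow(values) > 1L) {
    hc <- stats::hclust(stats::dist(values), method = cluster_method)
    rownames(values)[hc$order]
  } else rownames(values)

  dat <- data.frame(
    feature = factor(rep(rownames(values), ncol(values)),
                     levels = row_order),
    custom_id = factor(rep(colnames(values), each = nrow(values)),
                       levels = cols),
    value = as.vector(values),
    stringsAsFactors = FALSE)
  p <- ggplot2::ggplot(dat, ggplot2::aes(
      x = .data$custom_id, y = .data$feature, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", name = value_name) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  list(plot = p, data = dat, row_order = row_order)
}

#' Stacked bar chart of PTM beta-values per amino-acid position
#'
#' One bar per amino-acid position (or per replicate and position), with
#' stacked segments for the modification states and segment heights equal to
#' the beta-values — in group-mean mode the arithmetic mean over the arm's
#' replicates. Because betas are regularized family shares, every bar's total
#' stays below one.
#'
#' @param ptm A `ptm_table` bound to metadata with betas computed.
#' @param histone Optional histone protein filter (e.g. `"H3"`).
#' @param positions Optional character vector of site filters (e.g.
#'   `"K27"`).
#' @param mode `"group_mean"` (default; mean beta per arm) or `"replicate"`
#'   (one bar per sample).
#' @return List of `plot` and `data` (long form with `histone_protein`,
#'   `site`, `modification`, `beta`, and the grouping columns).
#' @export
plot_stacked_bars <- function(ptm, histone = NULL, positions = NULL,
                              mode = c("group_mean", "replicate")) {
  mode <- match.arg(mode)
  if (is.null(ptm$beta)) stop("betas not computed; run compute_beta() first")
  if (is.null(ptm$meta)) stop("ptm table is not bound to metadata")
  keys <- ptm$keys
  keep <- rep(TRUE, nrow(keys))
  if (!is.null(histone)) keep <- keep & keys$histone_protein %in% histone
  if (!is.null(positions)) keep <- keep & keys$site %in% positions
  if (!any(keep))
    stop("no modifications left after filtering; available histones: ",
         paste(unique(keys$histone_protein), collapse = ", "),
         "; sites: ", paste(unique(keys$site), collapse = ", "))

  beta <- ptm$beta[keep, , drop = FALSE]
  keys <- keys[keep, , drop = FALSE]
  meta <- ptm$meta
  dat <- data.frame(
    histone_protein = rep(keys$histone_protein, ncol(beta)),
    site = rep(keys$site, ncol(beta)),
    modification = rep(keys$modification, ncol(beta)),
    custom_id = rep(colnames(beta), each = nrow(beta)),
    beta = as.vector(beta),
    stringsAsFactors = FALSE)
  dat$experimental_group <-
    meta$experimental_group[match(dat$custom_id, meta$custom_id)]

  if (mode == "group_mean") {
    dat <- stats::aggregate(
      beta ~ histone_protein + site + modification + experimental_group,
      data = dat, FUN = mean)
    p <- ggplot2::ggplot(dat, ggplot2::aes(
        x = .data$site, y = .data$beta, fill = .data$modification)) +
      ggplot2::geom_col() +
      ggplot2::facet_grid(experimental_group ~ histone_protein,
                          scales = "free_x", space = "free_x")
  } else {
    p <- ggplot2::ggplot(dat, ggplot2::aes(
        x = .data$custom_id, y = .data$beta, fill = .data$modification)) +
      ggplot2::geom_col() +
      ggplot2::facet_grid(site ~ histone_protein) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
  p <- p + ggplot2::labs(x = "amino acid position", y = "beta value",
                         fill = "modification")
  list(plot = p, data = dat)
}

#' Heatmap of significant PTM M-values
#'
#' As [plot_heatmap()], but cells are the M-values themselves (one column
#' per sample); optional row z-scoring is offered as a flag.
#'
#' @param ptm A bound `ptm_table` with M-values computed.
#' @param features Feature ids (rows) to display, typically the significant
#'   set.
#' @param zscore Z-score rows before display; default `FALSE` (raw
#'   M-values).
#' @inheritParams plot_heatmap
#' @return As [plot_heatmap()].
#' @export
plot_ptm_heatmap <- function(ptm, features, zscore = FALSE,
                             cluster_method = "complete") {
  if (is.null(ptm$m)) stop("M-values not computed; run compute_beta() first")
  m <- ptm$m[rownames(ptm$m) %in% features, , drop = FALSE]
  if (zscore && nrow(m) > 0L) m <- zscore_rows(m)
  plot_heatmap(m, ptm$meta,
               value_name = if (zscore) "z(M-value)" else "M-value")
}

#' Save a plot object and its data sidecar
#'
#' Writes the ggplot as PNG and the backing data frame as CSV, so every
#' figure has a text twin that can be regenerated and diffed.
#'
#' @param obj A list with `plot` and `data`, as returned by the plot
#'   builders.
#' @param path_png,path_csv Output paths.
#' @param width,height Device size in inches.
#' @return Invisibly, the two paths.
#' @export
save_plot <- function(obj, path_png, path_csv, width = 7, height = 5) {
  if (is.null(obj)) return(invisible(NULL))
  ggplot2::ggsave(path_png, obj$plot, width = width, height = height,
                  dpi = 150)
  utils::write.csv(obj$data, path_csv, row.names = FALSE)
  invisible(c(path_png, path_csv))
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x
`%||%` <- function(a, b) if (is.null(a)) b else a
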