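#' Read a protein intensity matrix from CSV
#'
#' Parses a comma-delimited file with one row per protein and columns for
#' feature annotations (Uniprot accession, gene symbol, description) followed
#' by per-sample MS1 intensities. Annotation columns are recognised by name
#' (case-insensitive match on `uniprot`, `gene`, `description`); every other
#' column must be numeric and is treated as a sample.
#'
#' Non-numeric intensity cells become missing values (`NA`); a measured zero
#' stays zero. Negative intensities are an error. Duplicate feature
#' identifiers are disambiguated by appending the row ordinal — rows are never
#' aggregated, because aggregation would change the downstream statistics.
#'
#' @param path Path to a comma-delimited CSV file with a header row.
#' @return An object of class `protein_matrix`: a list with `annotations`
#'   (data.frame with columns `feature_id`, `uniprot_id`, `gene_id`,
#'   `description`) and `intensities` (numeric matrix, features x samples,
#'   rownames = `feature_id`).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(uniprot_id = c("P1", "P2"), gene_id = c("A", "B"),
#'                      description = c("a", "b"), s1 = c(10, 20),
#'                      s2 = c(30, 40)), f, row.names = FALSE)
#' pm <- read_protein_matrix(f)
#' dim(pm$intensities)
read_protein_matrix <- function(path) {
  df <- read_csv_checked(path)
  ann_idx <- grep("uniprot|gene|description", names(df), ignore.case = TRUE)
  if (length(ann_idx) < 1L)
    stop("no annotation column found (expected uniprot/gene/description)")
  sample_idx <- setdiff(seq_along(df), ann_idx)
  if (length(sample_idx) < 2L)
    stop("need at least 2 sample intensity columns, found ",
         length(sample_idx))

  intens <- as.matrix(as.data.frame(
    lapply(df[sample_idx], function(x) suppressWarnings(as.numeric(x))),
    check.names = FALSE))
  colnames(intens) <- names(df)[sample_idx]
  if (any(intens < 0, na.rm = TRUE))
    stop("negative intensities found; intensities must be >= 0")

  pick <- function(pat) {
    i <- grep(pat, names(df), ignore.case = TRUE)
    if (length(i)) as.character(df[[i[1L]]]) else rep(NA_character_, nrow(df))
  }
  ann <- data.frame(
    uniprot_id = pick("uniprot"),
    gene_id = pick("gene"),
    description = pick("description"),
    stringsAsFactors = FALSE)

  id <- ann$uniprot_id
  if (all(is.na(id))) id <- as.character(df[[ann_idx[1L]]])
  dup <- duplicated(id) | duplicated(id, fromLast = TRUE)
  if (any(dup)) id[dup] <- paste0(id[dup], ".", which(dup))
  if (anyDuplicated(id))
    stop("duplicate feature ids remain after disambiguation: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  ann <- cbind(feature_id = id, ann, stringsAsFactors = FALSE)
  rownames(intens) <- id

  structure(list(annotations = ann, intensities = intens),
            class = "protein_matrix")
}

#' Read a histone PTM intensity table from CSV
#'
#' Expects columns identifying the histone protein (e.g. `H3.3`), the amino
#' acid position (`K27`), and the modification type (`me3`, `ac`, `unmod`),
#' plus one intensity column per sample. Columns prefixed `beta_` or `m_` are
#' read as precomputed relative abundances; when absent they are left unset so
#' that [compute_beta()] can fill them from the intensities.
#'
#' @param path Path to a comma-delimited CSV file.
#' @param family_key_rule Which columns define a peptide family for
#'   relative-abundance normalization: `"histone_site"` (all modification
#'   states of one site on one histone, the default) or `"histone_peptide"`
#'   (requires a `peptide` column; all modifications on the same tryptic
#'   peptide).
#' @return An object of class `ptm_table`: list with `keys` (data.frame:
#'   `histone_protein`, `site`, `modification`, `family_key`), `intensities`
#'   (matrix), and `beta` / `m` (matrices or `NULL` when not yet computed).
#' @export
read_ptm_table <- function(path, family_key_rule = c("histone_site",
                                                     "histone_peptide")) {
  family_key_rule <- match.arg(family_key_rule)
  df <- read_csv_checked(path)
  nm <- tolower(names(df))
  req <- c(histone_protein = "^histone", site = "^site$|^position",
           modification = "^modification|^ptm$|^mod$")
  idx <- vapply(req, function(p) {
    i <- grep(p, nm)
    if (!length(i)) NA_integer_ else i[1L]
  }, integer(1))
  if (anyNA(idx))
    stop("missing required key column(s): ",
         paste(names(req)[is.na(idx)], collapse = ", "))

  keys <- data.frame(
    histone_protein = as.character(df[[idx["histone_protein"]]]),
    site = as.character(df[[idx["site"]]]),
    modification = as.character(df[[idx["modification"]]]),
    stringsAsFactors = FALSE)
  pep_i <- grep("^peptide$", nm)
  if (family_key_rule == "histone_peptide") {
    if (!length(pep_i))
      stop("family_key_rule 'histone_peptide' requires a 'peptide' column")
    keys$family_key <- paste(keys$histone_protein, df[[pep_i[1L]]], sep = ":")
  } else {
    keys$family_key <- paste(keys$histone_protein, keys$site, sep = ":")
  }
  trip <- paste(keys$histone_protein, keys$site, keys$modification, sep = "|")
  if (anyDuplicated(trip))
    stop("duplicate (histone, site, modification) rows: ",
         paste(unique(trip[duplicated(trip)]), collapse = ", "))

  beta_i <- grep("^beta_", nm)
  m_i <- grep("^m_", nm)
  used <- c(idx, pep_i, beta_i, m_i)
  sample_idx <- setdiff(seq_along(df), used)
  if (!length(sample_idx)) stop("no per-sample intensity columns found")

  intens <- as.matrix(as.data.frame(
    lapply(df[sample_idx], function(x) suppressWarnings(as.numeric(x))),
    check.names = FALSE))
  colnames(intens) <- names(df)[sample_idx]
  if (any(intens < 0, na.rm = TRUE))
    stop("negative PTM intensities found; intensities must be >= 0")

  grab <- function(ii, prefix) {
    if (!length(ii)) return(NULL)
    m <- as.matrix(as.data.frame(lapply(df[ii], as.numeric),
                                 check.names = FALSE))
    colnames(m) <- sub(paste0("^", prefix, "_"), "", names(df)[ii],
                       ignore.case = TRUE)
    m
  }
  beta <- grab(beta_i, "beta")
  if (!is.null(beta) && any(beta < 0 | beta >= 1, na.rm = TRUE))
    stop("precomputed beta values outside [0, 1)")
  m <- grab(m_i, "m")

  rn <- paste(keys$histone_protein, paste0(keys$site, keys$modification),
              sep = "_")
  rownames(intens) <- rn
  keys <- cbind(feature_id = rn, keys, stringsAsFactors = FALSE)
  if (!is.null(beta)) rownames(beta) <- rn
  if (!is.null(m)) rownames(m) <- rn

  structure(list(keys = keys, intensities = intens, beta = beta, m = m),
            class = "ptm_table")
}

#' Read and validate the sample metadata table
#'
#' The metadata binds intensity columns to the experimental design. Required
#' columns (matched case-insensitively, separators ignored): `file_name` (the
#' exact intensity column name), `sample_group` (free-text label such as a
#' tissue region), `replicate` (positive integer), and `experimental_group`
#' (the comparison arm; exactly two levels, each with at least two samples —
#' otherwise the per-group variance is undefined). An optional `custom_id`
#' column gives unique display labels; when absent, ids are synthesized as
#' `<group-initials>_<replicate>` with the first-listed arm's initial as
#' suffix.
#'
#' @param path Path to a comma-delimited CSV file.
#' @return A `data.frame` of class `sample_metadata` with columns
#'   `file_name`, `sample_group`, `replicate`, `experimental_group`,
#'   `custom_id`. The attribute `"arms"` stores the two experimental-group
#'   levels in order of first appearance.
#' @export
read_metadata <- function(path) {
  df <- read_csv_checked(path)
  canon <- gsub("[^a-z0-9]+", "_", tolower(names(df)))
  names(df) <- sub("_$", "", canon)
  req <- c("file_name", "sample_group", "replicate", "experimental_group")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  meta <- df[, intersect(c(req, "custom_id"), names(df)), drop = FALSE]
  meta$file_name <- as.character(meta$file_name)
  meta$sample_group <- as.character(meta$sample_group)
  meta$experimental_group <- as.character(meta$experimental_group)

  rep_num <- suppressWarnings(as.numeric(meta$replicate))
  if (anyNA(rep_num) || any(rep_num != round(rep_num)) || any(rep_num < 1))
    stop("replicate must be a positive integer for every sample")
  meta$replicate <- as.integer(rep_num)

  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  arms <- unique(meta$experimental_group)
  if (length(arms) != 2L)
    stop("experimental_group must have exactly 2 levels, found ",
         length(arms), ": ", paste(arms, collapse = ", "))
  n_arm <- table(meta$experimental_group)
  if (any(n_arm < 2L))
    stop("each experimental group needs >= 2 samples (variance undefined ",
         "otherwise); counts: ",
         paste(names(n_arm), n_arm, sep = "=", collapse = ", "))
  if (anyDuplicated(meta$file_name))
    stop("duplicate file_name entries in metadata")

  if (is.null(meta$custom_id) || all(is.na(meta$custom_id))) {
    initials <- vapply(strsplit(meta$sample_group, "[ _]+"), function(w)
      paste(toupper(substr(w, 1L, 1L)), collapse = ""), character(1))
    suffix <- ifelse(meta$experimental_group == arms[1L],
                     paste0("_", toupper(substr(arms[1L], 1L, 1L))), "")
    meta$custom_id <- paste0(initials, "_", meta$replicate, suffix)
  }
  meta$custom_id <- as.character(meta$custom_id)
  if (anyDuplicated(meta$custom_id))
    stop("custom_id values must be unique; duplicated: ",
         paste(unique(meta$custom_id[duplicated(meta$custom_id)]),
               collapse = ", "))
  attr(meta, "arms") <- arms
  class(meta) <- c("sample_metadata", "data.frame")
  meta
}

#' Bind an intensity table to its sample metadata
#'
#' Matches each metadata `file_name` to an intensity column by exact string
#' comparison (no fuzzy matching — a silent mis-binding is worse than an
#' error), renames the matched columns to `custom_id`, drops unreferenced
#' columns with a warning, and orders samples canonically (by `custom_id`) so
#' the result is invariant to both metadata row order and matrix column
#' order.
#'
#' @param x A `protein_matrix` or `ptm_table`.
#' @param meta A `sample_metadata` data.frame.
#' @return `x` with intensity (and beta/m, if present) columns subset,
#'   renamed to `custom_id`, and the reordered metadata attached as `$meta`.
#' @export
bind_samples <- function(x, meta) {
  stopifnot(inherits(meta, "sample_metadata"))
  cols <- colnames(x$intensities)
  missing_cols <- setdiff(meta$file_name, cols)
  if (length(missing_cols))
    stop("metadata file_name(s) not found in the intensity table: ",
         paste(missing_cols, collapse = ", "))
  dropped <- setdiff(cols, meta$file_name)
  if (length(dropped))
    warning("dropping ", length(dropped),
            " intensity column(s) not referenced by the metadata: ",
            paste(dropped, collapse = ", "))

  ord <- order(meta$custom_id)
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL

  take <- function(mat) {
    if (is.null(mat)) return(NULL)
    out <- mat[, meta$file_name, drop = FALSE]
    colnames(out) <- meta$custom_id
    out
  }
  x$intensities <- take(x$intensities)
  if (!is.null(x$beta)) x$beta <- take(x$beta)
  if (!is.null(x$m)) x$m <- take(x$m)
  x$meta <- meta
  x
}

#' Read a writer/eraser/reader modifier-protein table
#'
#' The table catalogues chromatin-modifying proteins: writers add a mark,
#' erasers remove it, readers bind it. Expected columns: `protein_id` (gene
#' symbol and/or accession), `organism`, `role` (one of writer / eraser /
#' reader), `mark` (acetylation or methylation).
#'
#' @param path Path to a comma-delimited CSV file.
#' @return A validated `data.frame` of class `modifier_db`.
#' @export
read_modifier_db <- function(path) {
  df <- read_csv_checked(path)
  names(df) <- tolower(names(df))
  req <- c("protein_id", "organism", "role", "mark")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("modifier table is missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, req, drop = FALSE]
  df[] <- lapply(df, as.character)
  df$role <- tolower(df$role)
  df$mark <- tolower(df$mark)
  bad_role <- setdiff(unique(df$role), c("writer", "eraser", "reader"))
  if (length(bad_role))
    stop("invalid role value(s): ", paste(bad_role, collapse = ", "))
  bad_mark <- setdiff(unique(df$mark), c("acetylation", "methylation"))
  if (length(bad_mark))
    stop("invalid mark value(s): ", paste(bad_mark, collapse = ", "))
  class(df) <- c("modifier_db", "data.frame")
  df
}

# Shared CSV reader: comma-delimited with header, UTF-8, "." decimal.
# Tab-delimited input is rejected outright rather than mis-parsed into a
# single column.
read_csv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header) && !grepl(",", header))
    stop("file appears tab-delimited; a comma-delimited .csv is required: ",
         path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  if (ncol(df) < 2L)
    stop("fewer than 2 columns parsed from ", path,
         "; is the file comma-delimited?")
  df
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat("protein_matrix:", nrow(x$intensities), "features x",
      ncol(x$intensities), "samples\n")
  invisible(x)
}

#' @export
print.ptm_table <- function(x, ...) {
  cat("ptm_table:", nrow(x$intensities), "modifications x",
      ncol(x$intensities), "samples;",
      length(unique(x$keys$family_key)), "peptide families;",
      if (is.null(x$beta)) "beta/m unset" else "beta/m computed", "\n")
  invisible(x)
}
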