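#' Flag chromatin-modifier proteins in differential results
#'
#' Cross-references a differential abundance table against a
#' writer/eraser/reader catalogue for one organism. A feature matches when
#' its gene symbol equals a catalogue `protein_id` case-insensitively
#' (modifier catalogues are symbol-centric); features without a gene match
#' fall back to an exact Uniprot accession comparison. Matches carry the
#' modifier role(s) and mark(s); a feature matching several catalogue rows
#' keeps all of them, separated by `";"`, and is flagged ambiguous rather
#' than arbitrarily resolved.
#'
#' @param results A `diff_result` data.frame carrying `gene_id` and/or
#'   `uniprot_id` columns.
#' @param db A `modifier_db` (see [read_modifier_db()]).
#' @param organism Organism to match against; must be present in `db` unless
#'   the catalogue is empty.
#' @return `results` with columns `is_modifier`, `modifier_role`,
#'   `modifier_mark`, `modifier_ambiguous` added.
#' @export
match_modifiers <- function(results, db, organism) {
  n <- nrow(results)
  results$is_modifier <- rep(FALSE, n)
  results$modifier_role <- rep(NA_character_, n)
  results$modifier_mark <- rep(NA_character_, n)
  results$modifier_ambiguous <- rep(FALSE, n)
  if (nrow(db) == 0L) return(results)

  orgs <- unique(db$organism)
  if (!organism %in% orgs)
    stop("organism '", organism, "' not in the modifier catalogue; ",
         "available: ", paste(orgs, collapse = ", "))
  db <- db[db$organism == organism, , drop = FALSE]

  key_db <- tolower(db$protein_id)
  gene <- if (!is.null(results$gene_id)) tolower(results$gene_id)
          else rep(NA_character_, n)
  acc <- if (!is.null(results$uniprot_id)) results$uniprot_id
         else rep(NA_character_, n)

  for (i in seq_len(n)) {
    hit <- !is.na(gene[i]) & key_db == gene[i]
    if (!any(hit) && !is.na(acc[i])) hit <- db$protein_id == acc[i]
    if (any(hit)) {
      results$is_modifier[i] <- TRUE
      results$modifier_role[i] <- paste(db$role[hit], collapse = ";")
      results$modifier_mark[i] <- paste(db$mark[hit], collapse = ";")
      results$modifier_ambiguous[i] <- sum(hit) > 1L
    }
  }
  results
}
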