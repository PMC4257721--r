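# Candidate gene screening: (i) flowering-related DEGs via e-value
# filtered homology hits; (ii) the catalogue-shaped flowering-time gene
# expression report.

# Best hit per query: lowest e-value, ties by highest bit score, then
# lexicographic subject id.
best_hits <- function(hits) {
  o <- order(hits$query_id, hits$e_value, -hits$bit_score, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Screen DEGs for homology to a reference gene catalogue
#'
#' Keeps genes that are called differentially expressed AND have at least
#' one homology hit with e-value at or below `e_max` (inclusive, matching
#' the conventional `1e-5` screen). The filter accepts any qualifying hit;
#' the single best hit (lowest e-value, ties by bit score then subject id)
#' decorates the output record.
#'
#' @param degs A `diff_expr_table` from [call_degs()], or any data frame
#'   with columns `gene_id` and `is_deg`.
#' @param hits Homology hits data frame as from [read_hits()].
#' @param e_max Maximum e-value for a qualifying hit, default `1e-5`.
#' @return Data frame with one row per candidate gene: the gene's
#'   differential-expression columns plus its best hit's `subject_id`,
#'   `percent_identity`, `e_value`, `bit_score`.
#' @export
screen_flowering_related <- function(degs, hits, e_max = 1e-5) {
  if (!is.finite(e_max) || e_max < 0) domain_error("e_max must be non-negative")
  qualifying <- hits[hits$e_value <= e_max, , drop = FALSE]
  deg_ids <- degs$gene_id[degs$is_deg]
  keep_ids <- intersect(deg_ids, unique(qualifying$query_id))
  best <- best_hits(qualifying)
  d <- degs[match(keep_ids, degs$gene_id), , drop = FALSE]
  b <- best[match(keep_ids, best$query_id), , drop = FALSE]
  res <- cbind(as.data.frame(d, stringsAsFactors = FALSE),
               b[, c("subject_id", "percent_identity", "e_value", "bit_score"),
                 drop = FALSE])
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# "72.5x"-style raw fold: truncated, not rounded, to one decimal.
format_raw_fold <- function(reads_L, reads_S) {
  if (reads_L > 0) sprintf("%.1f", trunc(10 * reads_S / reads_L) / 10)
  else if (reads_S > 0) "inf"
  else NA_character_
}

#' Flowering-time gene expression report
#'
#' One row per catalogue entry, grouped by the six flowering-pathway
#' categories in [flowering_categories()] order (catalogue order within a
#' category), carrying gene length, both read counts, the zero-substituted
#' log2 RPKM ratio (S over L), and the raw read fold `reads_S / reads_L`
#' truncated to one decimal (`"inf"` when the L count is zero). Catalogue
#' genes absent from the count table are flagged `"not quantified"` with a
#' warning rather than an error.
#'
#' @param catalog Catalogue data frame (see [read_flowering_catalog()]).
#' @param counts Count data frame with `gene_id`, `length_bp`, `reads_L`,
#'   `reads_S`.
#' @param libs A [library_pair()].
#' @param config A [test_config()] (supplies the zero substitute and the
#'   RPKM scale).
#' @return Data frame with columns `category`, `gene_id`, `length_bp`,
#'   `reads_L`, `reads_S`, `rpkm_L`, `rpkm_S`, `log2_ratio`, `raw_fold`,
#'   `homolog_name`, `accession`, `status`.
#' @export
flowering_time_report <- function(catalog, counts, libs,
                                  config = test_config()) {
  if (!inherits(libs, "library_pair")) domain_error("libs must be a library_pair")
  cat_order <- order(match(catalog$category, flowering_categories()))
  cat_sorted <- catalog[cat_order, , drop = FALSE]
  idx <- match(cat_sorted$gene_id, counts$gene_id)
  missing <- is.na(idx)
  if (any(missing))
    warning(sprintf("%d catalogue gene(s) not quantified: %s",
                    sum(missing),
                    paste(utils::head(cat_sorted$gene_id[missing], 5L),
                          collapse = ", ")))
  n <- nrow(cat_sorted)
  out <- data.frame(
    category = cat_sorted$category,
    gene_id = cat_sorted$gene_id,
    length_bp = counts$length_bp[idx],
    reads_L = counts$reads_L[idx],
    reads_S = counts$reads_S[idx],
    rpkm_L = NA_real_, rpkm_S = NA_real_, log2_ratio = NA_real_,
    raw_fold = NA_character_,
    homolog_name = cat_sorted$homolog_name %||% rep(NA_character_, n),
    accession = cat_sorted$accession %||% rep(NA_character_, n),
    status = ifelse(missing, "not quantified", "ok"),
    stringsAsFactors = FALSE)
  q <- which(!missing)
  if (length(q)) {
    out$rpkm_L[q] <- compute_rpkm(out$reads_L[q], out$length_bp[q],
                                  libs$total_reads_L, config$rpkm_scale)
    out$rpkm_S[q] <- compute_rpkm(out$reads_S[q], out$length_bp[q],
                                  libs$total_reads_S, config$rpkm_scale)
    out$log2_ratio[q] <- log2_fold_change(out$rpkm_L[q], out$rpkm_S[q],
                                          config$zero_substitute)
    out$raw_fold[q] <- mapply(format_raw_fold, out$reads_L[q], out$reads_S[q])
  }
  rownames(out) <- NULL
  out
}
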