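# Shared fixture builders: everything is generated in code or read from
# the plain-text catalogue shipped under inst/extdata.

catalog_path <- function() {
  system.file("extdata", "flowering_catalog.tsv", package = "dgepair",
              mustWork = TRUE)
}

# Published clean-read totals of the two libraries the catalogue belongs to.
CLEAN_TOTALS <- c(L = 25603968, S = 27723240)

load_catalog <- function() read_flowering_catalog(catalog_path())

# Counts TSV derived from the catalogue's printed per-gene reads, with the
# clean-read totals embedded as header comments.
write_catalog_counts <- function(path = tempfile(fileext = ".tsv")) {
  cat_df <- load_catalog()
  counts <- data.frame(gene_id = cat_df$gene_id, length_bp = cat_df$length_bp,
                       reads_L = cat_df$reads_L, reads_S = cat_df$reads_S)
  writeLines(c(sprintf("#total_L=%d", CLEAN_TOTALS[["L"]]),
               sprintf("#total_S=%d", CLEAN_TOTALS[["S"]])), path)
  suppressWarnings(utils::write.table(counts, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  path
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

toy_counts <- function() {
  data.frame(gene_id = c("g1", "g2", "g3", "g4"),
             length_bp = c(500L, 1000L, 2000L, 800L),
             reads_L = c(10L, 0L, 300L, 0L),
             reads_S = c(40L, 25L, 310L, 0L),
             stringsAsFactors = FALSE)
}

toy_annotations <- function() {
  annotation_map(
    gene_id = c("g1", "g1", "g2", "g3", "g4", "g5", "g6"),
    term_id = c("T1", "T2", "T1", "T2", "T1", "T2", "T1"),
    term_name = "term",
    namespace = "biological_process")
}

toy_hits <- function(query, e_value, bit_score = 100, subject = NULL) {
  n <- length(query)
  data.frame(query_id = query,
             subject_id = subject %||% sprintf("REF%03d.1", seq_len(n)),
             percent_identity = 80, alignment_length = 100L, mismatches = 5L,
             gap_opens = 0L, q_start = 1L, q_end = 100L, s_start = 1L,
             s_end = 100L, e_value = e_value,
             bit_score = rep_len(bit_score, n), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
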