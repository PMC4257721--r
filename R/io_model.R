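# Readers/writers for the package's tabular formats plus the small domain
# types they populate. No statistics live here.

GO_NAMESPACES <- c("biological_process", "cellular_component",
                   "molecular_function", "pathway")

#' Library pair: labels and total read counts of the two libraries
#'
#' The two library totals are the conditioning constants of the exact test
#' (often written N1 and N2). They default to clean-read totals; mapped-read
#' totals can be supplied instead when known.
#'
#' @param label_L,label_S Non-empty, distinct labels for the two libraries.
#' @param total_reads_L,total_reads_S Positive integer library totals.
#' @return An object of class `library_pair`.
#' @examples
#' library_pair("L", "S", 25603968, 27723240)
#' @export
library_pair <- function(label_L, label_S, total_reads_L, total_reads_S) {
  if (!is.character(label_L) || !nzchar(label_L) ||
      !is.character(label_S) || !nzchar(label_S))
    domain_error("library labels must be non-empty strings")
  if (identical(label_L, label_S))
    domain_error("library labels must be distinct")
  if (!is_count(total_reads_L, min = 1L) || !is_count(total_reads_S, min = 1L))
    domain_error("library totals must be positive integers")
  structure(list(label_L = label_L, label_S = label_S,
                 total_reads_L = as.double(total_reads_L),
                 total_reads_S = as.double(total_reads_S)),
            class = "library_pair")
}

#' @export
print.library_pair <- function(x, ...) {
  cat(sprintf("library pair: %s (N1 = %s reads) vs %s (N2 = %s reads)\n",
              x$label_L, format(x$total_reads_L, big.mark = ","),
              x$label_S, format(x$total_reads_S, big.mark = ",")))
  invisible(x)
}

# Normalise typographic minus (U+2212) from copy-pasted tables to ASCII.
normalize_minus <- function(x) gsub("−", "-", x)

# Read a TSV allowing leading '#' comment lines; returns the data frame plus
# the comments and the 1-based file line number of each data row.
read_tsv_commented <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  lines <- normalize_minus(readLines(path, encoding = "UTF-8", warn = FALSE))
  is_comment <- startsWith(lines, "#")
  body_idx <- which(!is_comment & nzchar(lines))
  if (length(body_idx) == 0L) parse_error("no header line found")
  df <- utils::read.delim(text = paste(lines[body_idx], collapse = "\n"),
                          header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  list(df = df, comments = lines[is_comment],
       row_lines = body_idx[-1L], header_line = body_idx[1L])
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    parse_error(sprintf("%s: missing column(s): %s", path,
                        paste(missing, collapse = ", ")))
}

# Strict integer column parse; names the first offending file line.
parse_int_column <- function(x, col, row_lines, min = 0L) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != trunc(v) | v < min)
  if (length(bad))
    parse_error(sprintf("column '%s': value '%s' is not an integer >= %d",
                        col, x[bad[1L]], min), line = row_lines[bad[1L]])
  v
}

parse_num_column <- function(x, col, row_lines, min = -Inf) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v < min)
  if (length(bad))
    parse_error(sprintf("column '%s': value '%s' is not a number >= %g",
                        col, x[bad[1L]], min), line = row_lines[bad[1L]])
  v
}

#' Read a two-library per-gene count table
#'
#' The counts TSV has columns `gene_id`, `length_bp`, `reads_L`, `reads_S`.
#' Library totals may be embedded as header comment lines `#total_L=<int>`
#' and `#total_S=<int>`; totals passed as arguments take precedence.
#'
#' @param path Path to the TSV file.
#' @param total_L,total_S Optional library totals overriding the header.
#' @param label_L,label_S Library labels (defaults "L" and "S").
#' @return A list with elements `counts` (data frame, row order preserved)
#'   and `libs` (a [library_pair()]).
#' @export
read_counts <- function(path, total_L = NULL, total_S = NULL,
                        label_L = "L", label_S = "S") {
  parsed <- read_tsv_commented(path)
  df <- parsed$df
  require_columns(df, c("gene_id", "length_bp", "reads_L", "reads_S"), path)

  header_totals <- function(key) {
    hit <- grep(sprintf("^#%s=", key), parsed$comments, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    v <- suppressWarnings(as.numeric(sub(sprintf("^#%s=", key), "", hit[1L])))
    if (is.na(v)) parse_error(sprintf("malformed header comment for %s", key))
    v
  }
  total_L <- total_L %||% header_totals("total_L")
  total_S <- total_S %||% header_totals("total_S")
  if (is.null(total_L) || is.null(total_S))
    parse_error(sprintf("%s: library totals missing (no #total_L=/#total_S= header and no override)", path))

  rl <- parsed$row_lines
  counts <- data.frame(
    gene_id   = df$gene_id,
    length_bp = parse_int_column(df$length_bp, "length_bp", rl, min = 1L),
    reads_L   = parse_int_column(df$reads_L, "reads_L", rl, min = 0L),
    reads_S   = parse_int_column(df$reads_S, "reads_S", rl, min = 0L),
    stringsAsFactors = FALSE)
  dup <- which(duplicated(counts$gene_id))
  if (length(dup))
    parse_error(sprintf("duplicate gene_id '%s'", counts$gene_id[dup[1L]]),
                line = rl[dup[1L]])
  if (any(!nzchar(counts$gene_id)))
    parse_error("empty gene_id", line = rl[which(!nzchar(counts$gene_id))[1L]])

  list(counts = counts,
       libs = library_pair(label_L, label_S, total_L, total_S))
}

#' Write a two-library count table
#'
#' Inverse of [read_counts()]; library totals are stored as header comments.
#'
#' @param counts Count data frame.
#' @param libs A [library_pair()].
#' @param path Output path.
#' @export
write_counts <- function(counts, libs, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("#total_L=%.0f", libs$total_reads_L),
               sprintf("#total_S=%.0f", libs$total_reads_S)), con)
  utils::write.table(counts[, c("gene_id", "length_bp", "reads_L", "reads_S")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' The annotation TSV has columns `gene_id`, `term_id`, `term_name`,
#' `namespace`, with namespace one of `biological_process`,
#' `cellular_component`, `molecular_function`, `pathway`. Duplicate
#' (gene, term) rows collapse to one membership.
#'
#' @param path Path to the TSV file.
#' @return An `annotation_map`: list with `map` (named list, gene id to
#'   character vector of term ids) and `terms` (term metadata data frame).
#' @export
read_annotations <- function(path) {
  parsed <- read_tsv_commented(path)
  df <- parsed$df
  require_columns(df, c("gene_id", "term_id", "term_name", "namespace"), path)
  bad <- which(!df$namespace %in% GO_NAMESPACES)
  if (length(bad))
    parse_error(sprintf("unknown namespace '%s' (expected one of %s)",
                        df$namespace[bad[1L]],
                        paste(GO_NAMESPACES, collapse = ", ")),
                line = parsed$row_lines[bad[1L]])
  annotation_map(df$gene_id, df$term_id, df$term_name, df$namespace)
}

#' Build an annotation map from parallel vectors
#'
#' @param gene_id,term_id,term_name,namespace Parallel character vectors,
#'   one element per (gene, term) membership.
#' @return An `annotation_map` object.
#' @export
annotation_map <- function(gene_id, term_id, term_name, namespace) {
  if (!all(namespace %in% GO_NAMESPACES))
    domain_error("unknown namespace token")
  keep <- !duplicated(paste0(gene_id, "\r", term_id))
  gene_id <- gene_id[keep]; term_id <- term_id[keep]
  terms <- data.frame(term_id = term_id, term_name = term_name[keep],
                      namespace = namespace[keep], stringsAsFactors = FALSE)
  terms <- terms[!duplicated(terms$term_id), , drop = FALSE]
  rownames(terms) <- NULL
  map <- split(term_id, factor(gene_id, levels = unique(gene_id)))
  structure(list(map = map, terms = terms), class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation map: %d genes, %d terms (%s)\n",
              length(x$map), nrow(x$terms),
              paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

#' Write an annotation map as TSV
#' @param annotations An `annotation_map`.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  gene <- rep(names(annotations$map), lengths(annotations$map))
  term <- unlist(annotations$map, use.names = FALSE)
  meta <- annotations$terms[match(term, annotations$terms$term_id), ]
  utils::write.table(
    data.frame(gene_id = gene, term_id = term, term_name = meta$term_name,
               namespace = meta$namespace),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

HITS_COLUMNS <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens",
                  "q_start", "q_end", "s_start", "s_end",
                  "e_value", "bit_score")

#' Read a tabular homology-hit file (12-column BLAST dialect)
#'
#' Expects the ubiquitous headerless 12-column tabular alignment format
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Scientific-notation e-values such as `8E-42` parse.
#'
#' @param path Path to the hits file.
#' @return A data frame with typed columns named per [HITS_COLUMNS].
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  lines <- normalize_minus(readLines(path, encoding = "UTF-8", warn = FALSE))
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0L)
    return(stats::setNames(
      data.frame(character(), character(), numeric(), integer(), integer(),
                 integer(), integer(), integer(), integer(), integer(),
                 numeric(), numeric()), HITS_COLUMNS))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad))
    parse_error(sprintf("expected 12 tab-separated columns, found %d", nf[bad[1L]]),
                line = keep[bad[1L]])
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hits <- data.frame(m[, 1L], m[, 2L],
                     parse_num_column(m[, 3L], "percent_identity", keep, 0),
                     parse_int_column(m[, 4L], "alignment_length", keep),
                     parse_int_column(m[, 5L], "mismatches", keep),
                     parse_int_column(m[, 6L], "gap_opens", keep),
                     parse_int_column(m[, 7L], "q_start", keep),
                     parse_int_column(m[, 8L], "q_end", keep),
                     parse_int_column(m[, 9L], "s_start", keep),
                     parse_int_column(m[, 10L], "s_end", keep),
                     parse_num_column(m[, 11L], "e_value", keep, 0),
                     parse_num_column(m[, 12L], "bit_score", keep),
                     stringsAsFactors = FALSE)
  names(hits) <- HITS_COLUMNS
  if (any(hits$percent_identity > 100))
    parse_error("percent_identity above 100")
  hits
}

#' The six flowering-pathway categories
#'
#' Canonical section order for the flowering-time gene report:
#' circadian clock & photoperiod, vernalization, autonomous, GA,
#' age-related, floral pathway integrators.
#'
#' @return Character vector of the six category names in report order.
#' @export
flowering_categories <- function() {
  c("Circadian clock & Photoperiod pathway",
    "Vernalization pathway",
    "Autonomous pathway",
    "GA pathway",
    "Age-related pathway",
    "Floral pathway integrator genes")
}

#' Read a flowering-time gene catalogue
#'
#' Required columns: `gene_id`, `category`, `homolog_name`, `accession`.
#' `category` must be one of [flowering_categories()]. Extra columns are
#' carried through untouched.
#'
#' @param path Path to the catalogue TSV.
#' @return The catalogue data frame, original row order preserved.
#' @export
read_flowering_catalog <- function(path) {
  parsed <- read_tsv_commented(path)
  df <- parsed$df
  require_columns(df, c("gene_id", "category", "homolog_name", "accession"), path)
  bad <- which(!df$category %in% flowering_categories())
  if (length(bad))
    parse_error(sprintf("unknown flowering category '%s'", df$category[bad[1L]]),
                line = parsed$row_lines[bad[1L]])
  for (col in intersect(c("length_bp", "reads_L", "reads_S"), names(df)))
    df[[col]] <- parse_int_column(df[[col]], col, parsed$row_lines)
  for (col in intersect(c("log2_printed", "e_value", "identity_pct"), names(df)))
    df[[col]] <- parse_num_column(df[[col]], col, parsed$row_lines)
  df
}

# Column rendering rules shared by write_results/read_results: fixed four
# decimals for expression-scale reals (mirrors the catalogue's log2
# precision), four significant digits for probabilities.
FIXED4_COLS <- c("rpkm_L", "rpkm_S", "log2_ratio")
SIG4_COLS <- c("p_value", "fdr", "adjusted_p")

#' Write a results table as TSV
#'
#' Expression-scale reals (`rpkm_L`, `rpkm_S`, `log2_ratio`) are rendered
#' with four decimals; probabilities (`p_value`, `fdr`, `adjusted_p`) with
#' four significant digits. [read_results()] round-trips the rendered
#' values losslessly.
#'
#' @param records A results data frame (e.g. from [call_degs()]).
#' @param path Output path.
#' @export
write_results <- function(records, path) {
  out <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in intersect(FIXED4_COLS, names(out)))
    out[[col]] <- sprintf("%.4f", out[[col]])
  for (col in intersect(SIG4_COLS, names(out)))
    out[[col]] <- formatC(signif(out[[col]], 4L), format = "g", digits = 4L)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(errorCondition(sprintf("cannot write to '%s'", path),
                               class = c("dgepair_io_error", "dgepair_error", "error")))
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path Path to the results TSV.
#' @return Data frame with columns restored to their native types.
#' @export
read_results <- function(path) {
  df <- read_tsv_commented(path)$df
  for (col in intersect(c("length_bp", "reads_L", "reads_S", "m", "n", "M", "N"),
                        names(df)))
    df[[col]] <- as.integer(df[[col]])
  for (col in intersect(c(FIXED4_COLS, SIG4_COLS), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  for (col in intersect(c("is_deg", "enriched"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}
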