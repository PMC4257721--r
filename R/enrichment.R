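# Term (GO/pathway) over-representation of DEGs against an annotated
# background, hypergeometric upper tail with multiple-testing control.

#' Hypergeometric over-representation p-value
#'
#' Probability of observing at least `m` genes carrying a term among `n`
#' drawn DEGs, when `M` of the `N` background genes carry the term:
#' \deqn{P(X \ge m) = \sum_{i=m}^{\min(n,M)}
#'   \binom{M}{i}\binom{N-M}{n-i} \big/ \binom{N}{n}}
#' Computed in log space via `lchoose` with log-sum-exp accumulation.
#'
#' @param m DEGs annotated to the term.
#' @param n DEGs with any annotation.
#' @param M Background genes annotated to the term.
#' @param N Background genes with any annotation.
#' @return Upper-tail probability in \[0, 1\]; exactly 1 when `m = 0`.
#' @examples
#' hypergeom_enrichment_p(3, 5, 4, 10)  # 66/252
#' @export
hypergeom_enrichment_p <- function(m, n, M, N) {
  ints <- c(m, n, M, N)
  if (any(!is.finite(ints)) || any(ints < 0) || any(ints != trunc(ints)))
    domain_error("m, n, M, N must be non-negative integers")
  if (m > min(n, M) || n > N || M > N)
    domain_error("count constraints violated: need m <= min(n, M), n <= N, M <= N")
  if (m == 0) return(1)
  i <- m:min(n, M)
  lp <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  min(1, exp(log_sum_exp(lp)))
}

#' Term over-representation analysis of a DEG set
#'
#' For every term annotated in the background, counts the 2x2 table
#' (`m` DEGs with the term, `n` annotated DEGs, `M` background genes with
#' the term, `N` annotated background genes), computes the upper-tail
#' hypergeometric p-value and applies a multiple-testing correction across
#' terms. A term is called enriched when its adjusted p-value is at or
#' below `alpha`.
#'
#' @param degs Character vector of DEG gene ids (must be a subset of the
#'   background).
#' @param annotations An `annotation_map` (see [read_annotations()]).
#' @param background Character vector of background gene ids; defaults to
#'   every gene with at least one annotation in the selected namespace(s).
#'   Genes without annotation are dropped from the universe.
#' @param namespace Optional namespace filter (e.g. `"pathway"` or
#'   `"biological_process"`); `NULL` keeps all namespaces.
#' @param correction `"bonferroni"` (default, family-wise control as
#'   commonly applied to GO terms) or `"bh"` (Benjamini-Hochberg, the
#'   usual choice for pathways).
#' @param alpha Significance level on the adjusted p-value, default 0.05.
#' @return Data frame of class `enrichment_table` with one row per term,
#'   sorted by `adjusted_p` then `term_id`: columns `term_id`,
#'   `term_name`, `namespace`, `m`, `n`, `M`, `N`, `p_value`,
#'   `adjusted_p`, `enriched`.
#' @export
enrich_terms <- function(degs, annotations, background = NULL,
                         namespace = NULL,
                         correction = c("bonferroni", "bh"), alpha = 0.05) {
  correction <- match.arg(correction)
  if (!inherits(annotations, "annotation_map"))
    domain_error("annotations must be an annotation_map")
  terms <- annotations$terms
  if (!is.null(namespace)) {
    if (!all(namespace %in% GO_NAMESPACES))
      domain_error("unknown namespace filter")
    terms <- terms[terms$namespace %in% namespace, , drop = FALSE]
  }
  map <- lapply(annotations$map, function(t) t[t %in% terms$term_id])
  map <- map[lengths(map) > 0L]
  annotated <- names(map)
  degs <- unique(degs)
  if (!is.null(background) && !all(degs %in% background))
    domain_error("degs must be a subset of the background")
  background <- if (is.null(background)) annotated
                else intersect(background, annotated)
  if (length(background) == 0L)
    domain_error("empty annotated background")
  degs_ann <- intersect(degs, background)

  # per-term membership counts over background and DEG subsets
  bg_terms <- unlist(map[background], use.names = FALSE)
  deg_terms <- unlist(map[degs_ann], use.names = FALSE)
  M_tab <- table(factor(bg_terms, levels = terms$term_id))
  m_tab <- table(factor(deg_terms, levels = terms$term_id))
  present <- M_tab > 0L
  terms <- terms[present, , drop = FALSE]
  M <- as.integer(M_tab[present]); m <- as.integer(m_tab[present])
  N <- length(background); n <- length(degs_ann)

  p <- vapply(seq_along(M), function(i) hypergeom_enrichment_p(m[i], n, M[i], N),
              numeric(1))
  adjusted <- switch(correction,
                     bonferroni = pmin(1, p * length(p)),
                     bh = bh_fdr(p))
  res <- data.frame(term_id = terms$term_id, term_name = terms$term_name,
                    namespace = terms$namespace, m = m, n = n, M = M, N = N,
                    p_value = p, adjusted_p = adjusted,
                    enriched = adjusted <= alpha, stringsAsFactors = FALSE)
  res <- res[order(res$adjusted_p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_table", "data.frame")
  res
}
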