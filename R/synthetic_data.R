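# Two-library count simulator with known ground truth, plus toy
# annotations, homology hits and a flowering catalogue, so every pipeline
# stage is testable without raw read data.

#' Specification of a synthetic two-library experiment
#'
#' Defaults emulate the scale of a typical two-cultivar digital gene
#' expression study: two libraries of roughly 25.6 and 27.7 million reads
#' over tens of thousands of assembled unigenes spanning 200-3000 bp.
#' Baseline expression proportions are log-normal (heavy right tail, as
#' observed across real tag-count tables); a `de_fraction` of genes
#' receives a true log2 effect of magnitude `effect_log2`, split evenly
#' between up- and down-regulation (an odd remainder goes up). Counts are
#' Poisson when `dispersion = 0`, otherwise negative binomial
#' (gamma-mixed Poisson) with `size = 1/dispersion`.
#'
#' @param n_genes Number of genes (positive).
#' @param total_reads_L,total_reads_S Expected library totals.
#' @param de_fraction Fraction of genes with a true effect, in \[0, 1).
#' @param effect_log2 Magnitude of the true log2 effect (positive).
#' @param dispersion Negative-binomial dispersion; 0 means Poisson.
#' @param length_range_bp Integer interval of gene lengths, default
#'   `c(200, 3000)`.
#' @param prop_sdlog Log-normal sdlog of baseline proportions, default 1.5
#'   (expression spread across roughly four orders of magnitude).
#' @param min_mean_count Floor on the per-gene expected count in the
#'   shallower library (0 disables). Power statements about count-based
#'   tests are made for adequately expressed genes; the floor lets a
#'   simulation state "every gene has mean count at least k" exactly.
#' @param n_terms Number of annotation terms to simulate.
#' @param term_size_range Integer interval of term sizes.
#' @param planted_term_size Size of one optionally planted enriched term
#'   (0 disables planting).
#' @param planted_or Odds ratio favouring true-DE genes in the planted
#'   term's membership; 1 means no enrichment.
#' @param hit_fraction Fraction of genes receiving a homology hit.
#' @param n_catalog Number of flowering-catalogue entries to simulate.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 20000,
                           total_reads_L = 25603968,
                           total_reads_S = 27723240,
                           de_fraction = 0.1,
                           effect_log2 = 2,
                           dispersion = 0,
                           length_range_bp = c(200L, 3000L),
                           prop_sdlog = 1.5,
                           min_mean_count = 0,
                           n_terms = 200,
                           term_size_range = c(10L, 60L),
                           planted_term_size = 0,
                           planted_or = 1,
                           hit_fraction = 0.3,
                           n_catalog = 18,
                           seed = 1L) {
  if (!is_count(n_genes, min = 1L)) domain_error("n_genes must be a positive integer")
  if (!is_count(total_reads_L, 1L) || !is_count(total_reads_S, 1L))
    domain_error("library totals must be positive integers")
  if (de_fraction < 0 || de_fraction >= 1)
    domain_error("de_fraction must lie in [0, 1)")
  if (effect_log2 <= 0) domain_error("effect_log2 must be positive")
  if (dispersion < 0) domain_error("dispersion must be non-negative")
  if (length(length_range_bp) != 2L || length_range_bp[1L] < 1 ||
      length_range_bp[2L] < length_range_bp[1L])
    domain_error("length_range_bp must be an increasing positive interval")
  if (prop_sdlog <= 0) domain_error("prop_sdlog must be positive")
  if (min_mean_count < 0) domain_error("min_mean_count must be non-negative")
  if (min_mean_count * n_genes > min(total_reads_L, total_reads_S))
    domain_error("min_mean_count floor exceeds the library depth")
  if (!is_count(n_terms)) domain_error("n_terms must be a non-negative integer")
  if (term_size_range[2L] > n_genes)
    domain_error("term sizes exceed the number of genes available")
  if (planted_term_size > n_genes)
    domain_error("planted term larger than the gene universe")
  if (planted_or < 1) domain_error("planted_or must be >= 1")
  if (hit_fraction < 0 || hit_fraction > 1)
    domain_error("hit_fraction must lie in [0, 1]")
  if (!is_count(seed) && !is_count(-seed)) domain_error("seed must be an integer")
  structure(list(n_genes = n_genes, total_reads_L = total_reads_L,
                 total_reads_S = total_reads_S, de_fraction = de_fraction,
                 effect_log2 = effect_log2, dispersion = dispersion,
                 length_range_bp = as.integer(length_range_bp),
                 prop_sdlog = prop_sdlog,
                 min_mean_count = min_mean_count, n_terms = n_terms,
                 term_size_range = as.integer(term_size_range),
                 planted_term_size = planted_term_size,
                 planted_or = planted_or, hit_fraction = hit_fraction,
                 n_catalog = n_catalog, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Each generator call draws from its own explicitly seeded stream; a fixed
# offset per generator keeps the three streams distinct yet reproducible.
with_stream <- function(spec, offset, code) {
  withr::with_seed((spec$seed + offset) %% .Machine$integer.max, code)
}

#' Simulate a two-library count table with ground truth
#'
#' Baseline proportions are log-normal, normalised to sum to one. True-DE
#' genes have their library-S proportion multiplied by `2^effect` (sign
#' split evenly up/down, odd remainder up) and the S proportions are
#' renormalised, so library totals stay comparable. Counts are Poisson
#' with mean `proportion * total` (negative binomial with
#' `size = 1/dispersion` when `dispersion > 0`).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `counts` (data frame `gene_id`, `length_bp`,
#'   `reads_L`, `reads_S`), `libs` (a [library_pair()]) and `truth`
#'   (data frame `gene_id`, `effect_log2`, `is_de`, `baseline_prop`).
#' @export
generate_counts <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) domain_error("spec must be a synthetic_spec")
  with_stream(spec, 0L, {
    n <- spec$n_genes
    gene_id <- sprintf("SynGene%05d", seq_len(n))
    length_bp <- sample(spec$length_range_bp[1L]:spec$length_range_bp[2L],
                        n, replace = TRUE)
    prop <- stats::rlnorm(n, meanlog = 0, sdlog = spec$prop_sdlog)
    prop <- prop / sum(prop)
    if (spec$min_mean_count > 0) {
      # floor the per-gene mean in the shallower library, keeping sum(prop)=1:
      # clip, rescale the unclipped mass, repeat until stable
      floor_p <- spec$min_mean_count / min(spec$total_reads_L, spec$total_reads_S)
      for (it in 1:20) {
        low <- prop < floor_p
        if (!any(low)) break
        prop[low] <- floor_p
        free <- !low
        prop[free] <- prop[free] * (1 - sum(low) * floor_p) / sum(prop[free])
      }
    }

    n_de <- round(spec$de_fraction * n)
    n_up <- ceiling(n_de / 2)
    de_idx <- sample.int(n, n_de)
    effect <- numeric(n)
    if (n_de > 0)
      effect[de_idx] <- c(rep(spec$effect_log2, n_up),
                          rep(-spec$effect_log2, n_de - n_up))

    prop_S <- prop * 2^effect
    prop_S <- prop_S / sum(prop_S)
    mu_L <- prop * spec$total_reads_L
    mu_S <- prop_S * spec$total_reads_S
    draw <- function(mu) {
      if (spec$dispersion == 0) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / spec$dispersion)
    }
    counts <- data.frame(gene_id = gene_id, length_bp = length_bp,
                         reads_L = draw(mu_L), reads_S = draw(mu_S),
                         stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = gene_id, effect_log2 = effect,
                        is_de = effect != 0, baseline_prop = prop,
                        stringsAsFactors = FALSE)
    list(counts = counts,
         libs = library_pair("L", "S", spec$total_reads_L, spec$total_reads_S),
         truth = truth)
  })
}

#' Simulate gene-to-term annotations with an optional planted enriched term
#'
#' Terms get sizes uniform over `term_size_range` and members drawn
#' uniformly from the gene universe. When `planted_term_size > 0` one
#' extra term (`TERM_PLANTED`) draws its members with sampling weight
#' `planted_or` for true-DE genes versus 1 otherwise, making it genuinely
#' over-represented among DE genes when `planted_or > 1`.
#'
#' @param genes Character vector of gene ids.
#' @param spec A [synthetic_spec()].
#' @param truth Optional ground-truth data frame from [generate_counts()];
#'   required when a planted term is requested.
#' @return List with `annotations` (an `annotation_map`) and `truth`
#'   (data frame `term_id`, `planted`, `odds_ratio`, `enriched`).
#' @export
generate_annotations <- function(genes, spec, truth = NULL) {
  if (length(genes) == 0L) domain_error("genes must be non-empty")
  if (spec$n_terms > 0 && spec$term_size_range[1L] > length(genes))
    domain_error("more term memberships requested than genes available")
  with_stream(spec, 1L, {
    ns_pool <- c("biological_process", "cellular_component",
                 "molecular_function", "pathway")
    gene <- character(0); term <- character(0)
    term_ids <- character(0); term_ns <- character(0)
    if (spec$n_terms > 0) {
      term_ids <- sprintf("TERM%04d", seq_len(spec$n_terms))
      term_ns <- ns_pool[(seq_len(spec$n_terms) - 1L) %% 4L + 1L]
      sizes <- sample(spec$term_size_range[1L]:min(spec$term_size_range[2L],
                                                   length(genes)),
                      spec$n_terms, replace = TRUE)
      for (i in seq_len(spec$n_terms)) {
        members <- sample(genes, sizes[i])
        gene <- c(gene, members)
        term <- c(term, rep(term_ids[i], sizes[i]))
      }
    }
    planted <- spec$planted_term_size > 0
    if (planted) {
      if (is.null(truth)) domain_error("planted term requires ground truth")
      w <- ifelse(truth$is_de[match(genes, truth$gene_id)], spec$planted_or, 1)
      members <- sample(genes, spec$planted_term_size, prob = w)
      gene <- c(gene, members)
      term <- c(term, rep("TERM_PLANTED", spec$planted_term_size))
      term_ids <- c(term_ids, "TERM_PLANTED")
      term_ns <- c(term_ns, "biological_process")
    }
    ann <- annotation_map(gene, term,
                          term_name = paste("synthetic term", term),
                          namespace = term_ns[match(term, term_ids)])
    truth_out <- data.frame(
      term_id = term_ids,
      planted = term_ids == "TERM_PLANTED",
      odds_ratio = ifelse(term_ids == "TERM_PLANTED", spec$planted_or, 1),
      enriched = term_ids == "TERM_PLANTED" & spec$planted_or > 1,
      stringsAsFactors = FALSE)
    list(annotations = ann, truth = truth_out)
  })
}

#' Simulate homology hits and a flowering catalogue
#'
#' A `hit_fraction` subset of genes receives one 12-column tabular hit
#' with e-value log-uniform over \[1e-12, 1e-2\] (straddling the 1e-5
#' screening threshold); `n_catalog` genes are assigned round-robin to the
#' six flowering-pathway categories with synthetic homolog names and
#' accessions.
#'
#' @param genes Character vector of gene ids.
#' @param spec A [synthetic_spec()].
#' @return List with `hits` (12-column data frame as from [read_hits()])
#'   and `catalog` (data frame as from [read_flowering_catalog()]).
#' @export
generate_hits_and_catalog <- function(genes, spec) {
  if (length(genes) == 0L) domain_error("genes must be non-empty")
  with_stream(spec, 2L, {
    n_hit <- round(spec$hit_fraction * length(genes))
    hit_genes <- sample(genes, n_hit)
    if (n_hit > 0) {
      alen <- sample(80:800, n_hit, replace = TRUE)
      hits <- data.frame(
        query_id = hit_genes,
        subject_id = sprintf("REF%05d.1", sample.int(99999L, n_hit, replace = TRUE)),
        percent_identity = round(stats::runif(n_hit, 60, 99), 2),
        alignment_length = alen,
        mismatches = sample(0:40, n_hit, replace = TRUE),
        gap_opens = sample(0:5, n_hit, replace = TRUE),
        q_start = 1L, q_end = alen, s_start = 1L, s_end = alen,
        e_value = 10^stats::runif(n_hit, -12, -2),
        bit_score = round(stats::runif(n_hit, 50, 900), 1),
        stringsAsFactors = FALSE)
    } else {
      hits <- read_hits(tempfile_empty())
    }
    n_cat <- min(spec$n_catalog, length(genes))
    cat_genes <- sample(genes, n_cat)
    catalog <- data.frame(
      gene_id = cat_genes,
      category = flowering_categories()[(seq_len(n_cat) - 1L) %% 6L + 1L],
      homolog_name = sprintf("SYNGENE%d", seq_len(n_cat)),
      accession = sprintf("SYN%06d.1", seq_len(n_cat)),
      stringsAsFactors = FALSE)
    list(hits = hits, catalog = catalog)
  })
}

# Empty file helper so read_hits() supplies a correctly typed empty frame.
tempfile_empty <- function() {
  f <- tempfile(fileext = ".tsv")
  file.create(f)
  f
}
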