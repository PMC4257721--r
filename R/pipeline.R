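# End-to-end pipeline driver: simulate -> quantify/test -> enrich ->
# screen, with a JSON run manifest that fully determines a rerun.

default_config <- function() {
  list(
    test = list(fdr_threshold = 0.001, min_abs_log2 = 1, zero_substitute = 0.01),
    enrich = list(alpha = 0.05, correction = "bonferroni", namespace = NULL),
    screen = list(e_max = 1e-5)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Run the full two-library DGE pipeline
#'
#' Stages run in order: `simulate` (optional; otherwise inputs are read
#' from files), `quantify` (DEG calling), `enrich` (term
#' over-representation of the DEGs, when annotations are available) and
#' `screen` (homology screen plus flowering-time report, when hits and a
#' catalogue are available). Every stage's TSV output is written before
#' the next stage begins; the JSON manifest is written last and records
#' the config snapshot, input checksums, per-stage row counts, package
#' version and seed, so a rerun with the same config and seed reproduces
#' the outputs bit-identically (timestamp aside).
#'
#' @param config A configuration list or a path to a JSON file. Sections:
#'   `simulate` (fields of [synthetic_spec()]) *or* `inputs` (paths
#'   `counts`, optionally `annotations`, `hits`, `catalog`, and totals
#'   `total_L`, `total_S` overriding the counts header); `test`
#'   (`fdr_threshold`, `min_abs_log2`, `zero_substitute`); `enrich`
#'   (`alpha`, `correction`, `namespace`); `screen` (`e_max`).
#' @param out_dir Output directory (created if missing); overrides
#'   `config$out`.
#' @param seed Integer seed overriding `config$seed`/`simulate$seed`.
#' @return Invisibly, the manifest list. Side effect: TSV results and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stage_error("config", sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- merge_config(default_config(), config)
  out_dir <- out_dir %||% config$out
  if (is.null(out_dir)) stage_error("config", "no output directory given")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stage_error("config", sprintf("cannot create output directory '%s'", out_dir))
  if (!is.null(seed)) config$simulate$seed <- seed
  checksums <- list()

  ## stage: simulate or load inputs
  ann <- NULL; hits <- NULL; catalog <- NULL
  if (!is.null(config$simulate)) {
    sim <- tryCatch({
      spec <- do.call(synthetic_spec, config$simulate)
      cc <- generate_counts(spec)
      write_counts(cc$counts, cc$libs, file.path(out_dir, "counts.tsv"))
      utils::write.table(cc$truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      anns <- generate_annotations(cc$counts$gene_id, spec, cc$truth)
      write_annotations(anns$annotations, file.path(out_dir, "annotations.tsv"))
      hc <- generate_hits_and_catalog(cc$counts$gene_id, spec)
      utils::write.table(hc$hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      utils::write.table(hc$catalog, file.path(out_dir, "catalog.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(counts = cc$counts, libs = cc$libs, ann = anns$annotations,
           hits = hc$hits, catalog = hc$catalog, seed = spec$seed)
    }, error = function(e) stage_error("simulate", conditionMessage(e)))
    counts <- sim$counts; libs <- sim$libs
    ann <- sim$ann; hits <- sim$hits; catalog <- sim$catalog
    used_seed <- sim$seed
  } else {
    inp <- config$inputs
    if (is.null(inp$counts) || !file.exists(inp$counts %||% ""))
      stage_error("quantify", "counts file missing")
    loaded <- tryCatch(
      read_counts(inp$counts, total_L = inp$total_L, total_S = inp$total_S),
      error = function(e) stage_error("quantify", conditionMessage(e)))
    counts <- loaded$counts; libs <- loaded$libs
    checksums[["counts"]] <- unname(tools::md5sum(inp$counts))
    if (!is.null(inp$annotations)) {
      ann <- tryCatch(read_annotations(inp$annotations),
                      error = function(e) stage_error("enrich", conditionMessage(e)))
      checksums[["annotations"]] <- unname(tools::md5sum(inp$annotations))
    }
    if (!is.null(inp$hits)) {
      hits <- tryCatch(read_hits(inp$hits),
                       error = function(e) stage_error("screen", conditionMessage(e)))
      checksums[["hits"]] <- unname(tools::md5sum(inp$hits))
    }
    if (!is.null(inp$catalog)) {
      catalog <- tryCatch(read_flowering_catalog(inp$catalog),
                          error = function(e) stage_error("screen", conditionMessage(e)))
      checksums[["catalog"]] <- unname(tools::md5sum(inp$catalog))
    }
    used_seed <- config$simulate$seed %||% NA
  }

  ## stage: quantify + test
  cfg <- tryCatch(
    test_config(fdr_threshold = config$test$fdr_threshold,
                min_abs_log2 = config$test$min_abs_log2,
                zero_substitute = config$test$zero_substitute),
    error = function(e) stage_error("quantify", conditionMessage(e)))
  message(sprintf("[quantify] totals N1=%.0f N2=%.0f, FDR<=%g, |log2|>=%g",
                  libs$total_reads_L, libs$total_reads_S,
                  cfg$fdr_threshold, cfg$min_abs_log2))
  degs <- tryCatch(call_degs(counts, libs, cfg),
                   error = function(e) stage_error("quantify", conditionMessage(e)))
  write_results(degs, file.path(out_dir, "results.tsv"))
  s <- attr(degs, "summary")

  ## stage: enrich
  n_enriched <- NA_integer_
  if (!is.null(ann)) {
    enr <- tryCatch(
      enrich_terms(degs$gene_id[degs$is_deg], ann,
                   namespace = config$enrich$namespace,
                   correction = config$enrich$correction,
                   alpha = config$enrich$alpha),
      error = function(e) stage_error("enrich", conditionMessage(e)))
    write_results(enr, file.path(out_dir, "enrichment.tsv"))
    n_enriched <- sum(enr$enriched)
  }

  ## stage: screen
  n_candidates <- NA_integer_
  if (!is.null(hits)) {
    cand <- tryCatch(
      screen_flowering_related(degs, hits, e_max = config$screen$e_max),
      error = function(e) stage_error("screen", conditionMessage(e)))
    write_results(cand, file.path(out_dir, "candidates.tsv"))
    n_candidates <- nrow(cand)
  }
  if (!is.null(catalog)) {
    rep <- tryCatch(
      flowering_time_report(catalog, counts, libs, cfg),
      error = function(e) stage_error("screen", conditionMessage(e)))
    write_results(rep, file.path(out_dir, "flowering_report.tsv"))
  }

  manifest <- list(
    tool = "dgepair",
    version = as.character(utils::packageVersion("dgepair")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = used_seed,
    config = config,
    input_checksums = checksums,
    stage_counts = list(
      genes_tested = unname(s["genes_tested"]),
      untestable = unname(s["untestable"]),
      degs_up = unname(s["degs_up"]),
      degs_down = unname(s["degs_down"]),
      enriched_terms = n_enriched,
      candidates = n_candidates))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
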