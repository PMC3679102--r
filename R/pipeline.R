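# End-to-end orchestration: QC -> orthology -> codon alignment ->
# Ka/Ks -> Ks filter -> classification -> GO enrichment -> expression.
# Every stage writes a TSV into the run directory; a machine-readable
# summary.json and a per-stage log close the run. Reruns with the same
# configuration and seed are byte-identical.

#' Build a pipeline configuration
#'
#' @param fasta_a,fasta_b paths to the two species' FASTA files
#' @param out_dir run directory (created if needed)
#' @param annotations optional gene-to-GO TSV (keyed on species-A ids)
#' @param reads_control_a,reads_stress_a,reads_control_b,reads_stress_b
#'   optional FASTQ paths for expression quantification
#' @param extract_orf scan unigenes for the longest ORF (`TRUE`) or
#'   treat inputs as in-frame CDS (`FALSE`)
#' @param min_orf_nt minimum ORF length when `extract_orf` is `TRUE`
#' @param min_score BBH raw-score threshold
#' @param min_overlap_nt,min_coverage,max_gap_col_frac orthology filter
#'   thresholds
#' @param ks_max Ks paralog-filter threshold
#' @param method Ka/Ks estimator, `"yn"` or `"ng"`
#' @param alpha enrichment significance threshold
#' @param log2_threshold,pseudo expression regulation parameters
#' @param max_mismatch read-mapping mismatch cap
#' @param max_n,qual_floor,max_lowq_frac,adapter read-QC parameters
#' @param seed integer seed echoed into the run log
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(fasta_a, fasta_b, out_dir,
                            annotations = NULL,
                            reads_control_a = NULL, reads_stress_a = NULL,
                            reads_control_b = NULL, reads_stress_b = NULL,
                            extract_orf = TRUE, min_orf_nt = 150,
                            min_score = 100,
                            min_overlap_nt = 150, min_coverage = 0.9,
                            max_gap_col_frac = 0.2, ks_max = 0.1,
                            method = c("yn", "ng"), alpha = 0.05,
                            log2_threshold = 1, pseudo = 0.1,
                            max_mismatch = 3,
                            max_n = 8, qual_floor = 5, max_lowq_frac = 0.5,
                            adapter = "", seed = 1) {
  method <- match.arg(method)
  stopifnot(min_overlap_nt >= 0, min_coverage >= 0, min_coverage <= 1,
            ks_max > 0, log2_threshold > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Percentages of category counts, to one decimal
#'
#' The summary convention used throughout run reports:
#' `round(count / total * 100, 1)`.
#'
#' @param counts named numeric vector of counts
#' @param total denominator (defaults to `sum(counts)`)
#' @return named numeric vector of percentages
#' @export
category_percentages <- function(counts, total = sum(counts)) {
  if (total <= 0) return(setNames(rep(NA_real_, length(counts)),
                                  names(counts)))
  round(counts / total * 100, 1)
}

#' Tabulate selection categories of retained pairs
#'
#' @param categories character vector of per-pair categories
#' @return data frame with `category`, `count`, `pct` (one decimal, of
#'   the retained total) in a fixed category order
#' @export
summarize_kaks_categories <- function(categories) {
  levels <- c("positive", "weak_purifying", "purifying", "ka_only",
              "ks_only", "incalculable")
  counts <- table(factor(categories, levels = levels))
  data.frame(
    category = levels,
    count = as.integer(counts),
    pct = unname(category_percentages(as.numeric(counts),
                                      max(length(categories), 1))),
    stringsAsFactors = FALSE
  )
}

.log_line <- function(log, ...) {
  c(log, paste0(...))
}

#' Run the full ortholog / Ka/Ks / enrichment / expression pipeline
#'
#' Stages run in a fixed order; every stage writes its table under the
#' run directory and appends an input/output line to `run.log`. The run
#' ends with `summary.json` carrying category counts and percentages,
#' per-filter exclusion tallies, the enrichment table and the
#' concordance calls.
#'
#' @param config a [pipeline_config()] object
#' @return the summary list, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  log <- .log_line(log, "config: method=", config$method,
                   " ks_max=", config$ks_max,
                   " min_overlap_nt=", config$min_overlap_nt,
                   " min_coverage=", config$min_coverage,
                   " max_gap_col_frac=", config$max_gap_col_frac,
                   " min_score=", config$min_score,
                   " log2_threshold=", config$log2_threshold,
                   " alpha=", config$alpha,
                   " max_n=", config$max_n,
                   " qual_floor=", config$qual_floor,
                   " max_lowq_frac=", config$max_lowq_frac,
                   " seed=", config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- inputs ----
  recs_a <- stage("input", read_fasta(config$fasta_a))
  recs_b <- stage("input", read_fasta(config$fasta_b))
  log <- .log_line(log, "input: ", nrow(recs_a), " sequences (A), ",
                   nrow(recs_b), " sequences (B)")

  # ---- coding regions ----
  cds_a <- stage("cds", if (config$extract_orf) {
    extract_cds_set(recs_a, config$min_orf_nt, species = "a")
  } else as_cds_set(recs_a, species = "a"))
  cds_b <- stage("cds", if (config$extract_orf) {
    extract_cds_set(recs_b, config$min_orf_nt, species = "b")
  } else as_cds_set(recs_b, species = "b"))
  log <- .log_line(log, "cds: ", length(cds_a), " (A), ", length(cds_b),
                   " (B)")

  # ---- BBH + filters i-iii ----
  empty <- length(cds_a) == 0 || length(cds_b) == 0
  pairs <- if (empty) {
    data.frame(id_a = character(0), id_b = character(0),
               score = numeric(0), overlap_nt = numeric(0),
               coverage_a = numeric(0), coverage_b = numeric(0))
  } else {
    stage("bbh", find_bbh(cds_a, cds_b, min_score = config$min_score))
  }
  log <- .log_line(log, "bbh: ", nrow(pairs), " candidate pairs")
  alns <- stage("align", attach_codon_alignments(pairs, cds_a, cds_b))
  filt <- stage("filter", filter_ortholog_pairs(
    pairs, alns, min_overlap_nt = config$min_overlap_nt,
    min_coverage = config$min_coverage,
    max_gap_col_frac = config$max_gap_col_frac))
  log <- .log_line(log, "filter: retained ", nrow(filt$retained),
                   ", excluded ", nrow(filt$excluded),
                   " (overlap=", filt$counts["overlap"],
                   ", coverage=", filt$counts["coverage"],
                   ", stop_or_ambiguous=", filt$counts["stop_or_ambiguous"],
                   ")")
  write.table(filt$retained, file.path(config$out_dir, "pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  excl <- filt$excluded
  write.table(excl, file.path(config$out_dir, "pairs_excluded.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- Ka/Ks + Ks filter (iv) ----
  est <- if (config$method == "yn") yn00 else ng86
  keys <- paste0(filt$retained$id_a, "|", filt$retained$id_b)
  results <- stage("kaks", lapply(keys, function(k) est(alns[[k]])))
  ksf <- apply_ks_filter(results, ks_max = config$ks_max)
  log <- .log_line(log, "kaks: ", length(results), " pairs estimated, ",
                   length(ksf$excluded), " excluded by Ks > ",
                   config$ks_max)
  ktab <- kaks_table(ksf$retained)
  write_results_table(ktab, file.path(config$out_dir, "kaks.tsv"),
                      schema = "kaks")
  write_results_table(kaks_table(ksf$excluded),
                      file.path(config$out_dir, "kaks_excluded.tsv"),
                      schema = "kaks")

  cat_summary <- summarize_kaks_categories(ktab$category)

  # ---- GO enrichment ----
  enr <- NULL
  if (!is.null(config$annotations) && nrow(ktab) > 0) {
    anno <- stage("enrich", read_annotation(config$annotations))
    bg <- sub("\\|.*$", "", ktab$pair_id)
    psg <- bg[ktab$category == "positive"]
    enr <- stage("enrich", go_enrichment(anno, psg, bg,
                                         alpha = config$alpha))
    write_results_table(enr, file.path(config$out_dir, "enrichment.tsv"),
                        schema = "enrichment")
    log <- .log_line(log, "enrich: ", nrow(enr), " categories tested, ",
                     sum(enr$significant), " at p <= ", config$alpha)
  }

  # ---- expression ----
  expr_tab <- NULL
  conc <- NULL
  have_reads <- !is.null(config$reads_control_a) &&
    !is.null(config$reads_stress_a) &&
    !is.null(config$reads_control_b) && !is.null(config$reads_stress_b)
  if (have_reads && nrow(ktab) > 0) {
    ids_a <- sub("\\|.*$", "", ktab$pair_id)
    ids_b <- sub("^.*\\|", "", ktab$pair_id)
    genes_a <- recs_a[match(ids_a, recs_a$id), ]
    genes_b <- recs_b[match(ids_b, recs_b$id), ]
    ex_a <- stage("express", expression_records(
      genes_a, read_fastq(config$reads_control_a),
      read_fastq(config$reads_stress_a), species = "a",
      max_mismatch = config$max_mismatch,
      log2_threshold = config$log2_threshold, pseudo = config$pseudo))
    ex_b <- stage("express", expression_records(
      genes_b, read_fastq(config$reads_control_b),
      read_fastq(config$reads_stress_b), species = "b",
      max_mismatch = config$max_mismatch,
      log2_threshold = config$log2_threshold, pseudo = config$pseudo))
    ex_a$pair_id <- ktab$pair_id
    ex_b$pair_id <- ktab$pair_id
    expr_tab <- rbind(ex_a, ex_b)
    write_results_table(expr_tab,
                        file.path(config$out_dir, "expression.tsv"),
                        schema = "expression")
    conc <- concordance(expr_tab)
    write.table(conc, file.path(config$out_dir, "concordance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log <- .log_line(log, "express: ", nrow(expr_tab), " records, ",
                     sum(conc$call == "up_both"), " up in both species")
  }

  summary <- list(
    n_input_a = nrow(recs_a), n_input_b = nrow(recs_b),
    n_cds_a = length(cds_a), n_cds_b = length(cds_b),
    n_candidate_pairs = nrow(pairs),
    filter_exclusions = as.list(c(filt$counts,
                                  ks_excess = length(ksf$excluded))),
    n_retained = nrow(ktab),
    categories = cat_summary,
    enrichment = if (!is.null(enr)) enr else NULL,
    concordance = if (!is.null(conc)) {
      as.list(table(factor(conc$call, levels = c(
        "up_both", "up_species_a_only", "up_species_b_only", "other"))))
    } else NULL,
    seed = config$seed,
    method = config$method
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  writeLines(log, file.path(config$out_dir, "run.log"))
  invisible(summary)
}
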