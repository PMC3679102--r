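# Raw-read cleaning: exact duplicates (both orientations), adapter
# trimming, and removal of reads with too many Ns, too many low-quality
# bases, or low sequence complexity. Filters run in a fixed order so the
# report is reproducible: duplicates -> adapter trim -> N -> quality ->
# complexity.

# trim an exact adapter match: full internal occurrence, or a >= min_match
# suffix of the read matching a prefix of the adapter (3' contamination),
# or a >= min_match prefix matching an adapter suffix (5')
.trim_adapter <- function(seq, qual, adapter, min_match = 8) {
  n <- nchar(seq)
  na <- nchar(adapter)
  hit <- regexpr(adapter, seq, fixed = TRUE)
  if (hit > 0) {
    cut <- as.integer(hit) - 1L
    return(list(seq = substring(seq, 1, cut), qual = qual[seq_len(cut)],
                trimmed = TRUE))
  }
  for (k in seq(min(na - 1, n), min_match)) {
    if (k < min_match) break
    if (substring(seq, n - k + 1, n) == substring(adapter, 1, k)) {
      cut <- n - k
      return(list(seq = substring(seq, 1, cut), qual = qual[seq_len(cut)],
                  trimmed = TRUE))
    }
  }
  for (k in seq(min(na - 1, n), min_match)) {
    if (k < min_match) break
    if (substring(seq, 1, k) == substring(adapter, na - k + 1, na)) {
      return(list(seq = substring(seq, k + 1, n), qual = qual[-seq_len(k)],
                  trimmed = TRUE))
    }
  }
  list(seq = seq, qual = qual, trimmed = FALSE)
}

#' Clean raw sequencing reads
#'
#' Applies, in order: removal of exact duplicates (a read identical to an
#' already retained read, or to its reverse complement, is dropped;
#' first-seen wins), adapter trimming, removal of reads with more than
#' `max_n` unknown bases, removal of reads where more than
#' `max_lowq_frac` of bases have quality at or below `qual_floor`, and
#' removal of low-complexity reads in which one nucleotide makes up more
#' than `complexity_max_frac` of the read.
#'
#' @param reads read data frame (`id`, `seq`, `qual`), as from
#'   [read_fastq()]
#' @param adapter adapter sequence to trim; `""` disables trimming
#' @param max_n maximum tolerated number of N calls (strictly more are
#'   removed)
#' @param qual_floor Phred score at or below which a base counts as
#'   low-quality
#' @param max_lowq_frac maximum tolerated fraction of low-quality bases
#'   (strictly more is removed)
#' @param complexity_max_frac maximum tolerated fraction of the read made
#'   up by its most frequent nucleotide
#' @return list with `reads` (the retained, possibly trimmed reads) and
#'   `report` (a one-row data frame of QC counters that reconciles
#'   exactly: `n_output = n_input - removals`)
#' @export
clean_reads <- function(reads, adapter = "", max_n = 8, qual_floor = 5,
                        max_lowq_frac = 0.5, complexity_max_frac = 0.8) {
  if (max_n < 0 || qual_floor < 0 || max_lowq_frac < 0 ||
      complexity_max_frac < 0) {
    stop("thresholds must be non-negative")
  }
  n_input <- nrow(reads)

  # 1. exact duplicates, both orientations, first-seen retained
  seen <- new.env(parent = emptyenv(), size = max(2L * n_input, 16L))
  keep <- logical(n_input)
  for (i in seq_len(n_input)) {
    s <- reads$seq[i]
    if (is.null(seen[[s]])) {
      keep[i] <- TRUE
      seen[[s]] <- TRUE
      seen[[revcomp(s)]] <- TRUE
    }
  }
  n_dup <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]

  # 2. adapter trimming
  n_trim <- 0L
  if (nzchar(adapter)) {
    for (i in seq_len(nrow(reads))) {
      tr <- .trim_adapter(reads$seq[i], reads$qual[[i]], adapter)
      if (tr$trimmed) {
        n_trim <- n_trim + 1L
        reads$seq[i] <- tr$seq
        reads$qual[[i]] <- tr$qual
      }
    }
  }

  # 3. too many unknown bases
  n_count <- vapply(strsplit(reads$seq, ""), function(x) sum(x == "N"),
                    numeric(1))
  rm_n <- n_count > max_n
  n_removed_n <- sum(rm_n)
  reads <- reads[!rm_n, , drop = FALSE]

  # 4. low-quality bases
  lowq <- vapply(reads$qual, function(q) {
    if (length(q) == 0) return(0)
    mean(q <= qual_floor)
  }, numeric(1))
  rm_q <- lowq > max_lowq_frac
  n_removed_quality <- sum(rm_q)
  reads <- reads[!rm_q, , drop = FALSE]

  # 5. low complexity
  comp <- vapply(strsplit(reads$seq, ""), function(x) {
    if (length(x) == 0) return(1)
    max(table(factor(x, levels = c(NUCS, "N")))) / length(x)
  }, numeric(1))
  rm_c <- comp > complexity_max_frac
  n_removed_complexity <- sum(rm_c)
  reads <- reads[!rm_c, , drop = FALSE]

  report <- data.frame(
    n_input = n_input,
    n_duplicates_removed = n_dup,
    n_adapter_trimmed = n_trim,
    n_removed_n = n_removed_n,
    n_removed_quality = n_removed_quality,
    n_removed_complexity = n_removed_complexity,
    n_output = nrow(reads)
  )
  stopifnot(report$n_output == reconcile_counts(
    n_input, n_dup + n_removed_n + n_removed_quality + n_removed_complexity))
  rownames(reads) <- NULL
  list(reads = reads, report = report)
}

#' Sequences retained after exclusions
#'
#' Bookkeeping used by the QC report and run summaries: the number of
#' records kept once removals are accounted for.
#'
#' @param n_input number of input records
#' @param n_excluded total number excluded
#' @return `n_input - n_excluded`
#' @export
reconcile_counts <- function(n_input, n_excluded) {
  if (n_excluded > n_input) stop("more exclusions than inputs")
  n_input - n_excluded
}
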