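# Coding-region extraction, reciprocal-best-hit ortholog candidates, and
# the strict paralog filters (overlap, coverage, stop/ambiguous).
#
# Protein scoring uses exact Smith-Waterman / Needleman-Wunsch with
# BLOSUM62 and affine gaps (via Biostrings::pairwiseAlignment), in place
# of heuristic database search: at the scale this package targets the
# exact score is affordable and removes score-statistics guesswork. The
# default `min_score` below plays the role of a bit-score cut-off: raw
# score 100 is far above what unrelated protein pairs of this length
# attain under BLOSUM62, while genuine cross-species orthologs score in
# the hundreds.

.blosum62 <- function() {
  m <- .kaksflow_cache$BLOSUM62
  if (is.null(m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    .kaksflow_cache$BLOSUM62 <- m
  }
  m
}

#' Extract the longest ATG-initiated open reading frame
#'
#' Scans all six frames of a unigene for open reading frames that start
#' at ATG and run stop-free to the first stop codon (or the frame end);
#' the longest one is returned. Ties are broken by frame order (+1, +2,
#' +3, -1, -2, -3) and then by leftmost start.
#'
#' @param unigene one sequence record (a list or one-row data frame with
#'   `id` and `seq`)
#' @param min_orf_nt minimum ORF length in nucleotides (multiple of 3,
#'   default 150)
#' @param species optional species label carried on the result
#' @return a `coding_sequence` list (`id`, `species`, `nt`, `protein`,
#'   `span` with 0-based half-open coordinates on the parent and strand),
#'   or `NULL` if no qualifying ORF exists
#' @export
extract_cds <- function(unigene, min_orf_nt = 150, species = NA_character_) {
  if (min_orf_nt < 3 || min_orf_nt %% 3 != 0) {
    stop("min_orf_nt must be >= 3 and divisible by 3")
  }
  seq <- toupper(unigene$seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("non-nucleotide characters in ", unigene$id)
  }
  n <- nchar(seq)
  best <- NULL
  frames <- list(
    list(strand = "+", off = 0), list(strand = "+", off = 1),
    list(strand = "+", off = 2), list(strand = "-", off = 0),
    list(strand = "-", off = 1), list(strand = "-", off = 2)
  )
  rc <- revcomp(seq)
  for (fr in frames) {
    s <- if (fr$strand == "+") seq else rc
    usable <- n - fr$off
    usable <- usable - usable %% 3
    if (usable < min_orf_nt) next
    codons <- split_codons(substring(s, fr$off + 1, fr$off + usable))
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    # segment the frame at stop codons; ORF = first ATG of a segment to
    # the segment end
    seg <- cumsum(c(TRUE, is_stop[-length(is_stop)]))
    for (g in split(seq_along(codons), seg)) {
      g <- g[!is_stop[g]]
      if (length(g) == 0) next
      atg <- g[is_atg[g]]
      if (length(atg) == 0) next
      start_cod <- atg[1]
      len_cod <- g[length(g)] - start_cod + 1
      if (3 * len_cod < min_orf_nt) next
      if (!is.null(best) && 3 * len_cod <= best$len_nt) next
      # coordinates on the oriented strand
      s0 <- fr$off + 3 * (start_cod - 1)       # 0-based start
      e0 <- s0 + 3 * len_cod                   # 0-based end (half-open)
      if (fr$strand == "+") {
        span <- c(start = s0, end = e0)
      } else {
        span <- c(start = n - e0, end = n - s0)
      }
      nt <- substring(s, s0 + 1, e0)
      best <- list(
        len_nt = 3 * len_cod, nt = nt,
        span = span, strand = fr$strand
      )
    }
  }
  if (is.null(best)) return(NULL)
  structure(
    list(
      id = unigene$id, species = species, nt = best$nt,
      protein = translate_cds(best$nt),
      span = list(start = unname(best$span["start"]),
                  end = unname(best$span["end"]),
                  strand = best$strand)
    ),
    class = "coding_sequence"
  )
}

#' Extract coding sequences for a whole FASTA
#'
#' @param records sequence-record data frame
#' @param min_orf_nt minimum ORF length (nt)
#' @param species species label
#' @return named list of `coding_sequence` objects (records without a
#'   qualifying ORF are dropped)
#' @export
extract_cds_set <- function(records, min_orf_nt = 150,
                            species = NA_character_) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    cds <- extract_cds(records[i, ], min_orf_nt = min_orf_nt,
                       species = species)
    if (!is.null(cds)) out[[cds$id]] <- cds
  }
  out
}

#' Treat in-frame sequences as coding sequences without ORF scanning
#'
#' For inputs that are already in-frame CDS (e.g. simulator output),
#' wraps each record directly; internal stop codons are tolerated here so
#' that the downstream stop filter can flag them.
#'
#' @inheritParams extract_cds_set
#' @return named list of `coding_sequence` objects
#' @export
as_cds_set <- function(records, species = NA_character_) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    nt <- toupper(records$seq[i])
    nt <- substring(nt, 1, nchar(nt) - nchar(nt) %% 3)
    out[[records$id[i]]] <- structure(
      list(
        id = records$id[i], species = species, nt = nt,
        protein = translate_cds(nt),
        span = list(start = 0, end = nchar(nt), strand = "+")
      ),
      class = "coding_sequence"
    )
  }
  out
}

#' Align two proteins with BLOSUM62 and affine gaps
#'
#' @param a,b amino-acid strings
#' @param gap_open,gap_extend affine gap penalties (defaults 11/1, the
#'   conventional BLOSUM62 pairing)
#' @param mode `"local"` (Smith-Waterman) or `"global"`
#'   (Needleman-Wunsch)
#' @return list with `score`, `aligned_a`, `aligned_b` (gapped strings),
#'   `overlap_nt` (3 x aligned residue-pair columns), and `coverage_a`,
#'   `coverage_b` (fraction of each input spanned by the alignment)
#' @export
align_proteins <- function(a, b, gap_open = 11, gap_extend = 1,
                           mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = mode, substitutionMatrix = .blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  both <- sum(ca != "-" & cb != "-")
  list(
    score = BiocGenerics::score(aln),
    aligned_a = pa, aligned_b = pb,
    overlap_nt = 3L * both,
    coverage_a = sum(ca != "-") / nchar(a),
    coverage_b = sum(cb != "-") / nchar(b)
  )
}

# score matrix A x B via vectorised pairwiseAlignment calls
.score_matrix <- function(prots_a, prots_b, gap_open, gap_extend) {
  pa <- Biostrings::AAStringSet(prots_a)
  m <- matrix(0, length(prots_a), length(prots_b),
              dimnames = list(names(prots_a), names(prots_b)))
  for (j in seq_along(prots_b)) {
    m[, j] <- Biostrings::pairwiseAlignment(
      pa, Biostrings::AAString(prots_b[[j]]), type = "local",
      substitutionMatrix = .blosum62(),
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
  }
  m
}

# pick the best hit index with the declared tie-breaks: max score, then
# larger overlap_nt, then lexicographically smaller id
.best_hit <- function(scores, my_prot, other_prots, gap_open, gap_extend) {
  top <- max(scores)
  cand <- which(scores == top)
  if (length(cand) > 1) {
    ov <- vapply(cand, function(j) {
      align_proteins(my_prot, other_prots[[j]], gap_open, gap_extend,
                     mode = "local")$overlap_nt
    }, numeric(1))
    cand <- cand[ov == max(ov)]
    if (length(cand) > 1) {
      cand <- cand[order(names(other_prots)[cand])[1]]
    }
  }
  cand[1]
}

#' Reciprocal-best-hit ortholog candidates between two CDS sets
#'
#' A pair (a, b) is reported when b is a's highest-scoring hit among
#' species B and a is b's highest-scoring hit among species A, with raw
#' local-alignment score above `min_score`. Score ties are broken by
#' larger aligned overlap and then lexicographic id, so the output is
#' deterministic.
#'
#' @param cds_a,cds_b named lists of `coding_sequence` objects (one per
#'   species), as from [extract_cds_set()] or [as_cds_set()]
#' @param min_score minimum raw alignment score (default 100; see note
#'   in the package vignette on calibration)
#' @param gap_open,gap_extend affine gap penalties
#' @return data frame of candidate pairs with columns `id_a`, `id_b`,
#'   `score`, `overlap_nt`, `coverage_a`, `coverage_b`
#' @export
find_bbh <- function(cds_a, cds_b, min_score = 100, gap_open = 11,
                     gap_extend = 1) {
  if (length(cds_a) == 0 || length(cds_b) == 0) {
    stop("both CDS sets must be non-empty")
  }
  if (min_score < 0) stop("min_score must be >= 0")
  prots_a <- vapply(cds_a, `[[`, character(1), "protein")
  prots_b <- vapply(cds_b, `[[`, character(1), "protein")
  m <- .score_matrix(prots_a, prots_b, gap_open, gap_extend)

  best_in_b <- vapply(seq_along(prots_a), function(i) {
    .best_hit(m[i, ], prots_a[[i]], prots_b, gap_open, gap_extend)
  }, integer(1))
  best_in_a <- vapply(seq_along(prots_b), function(j) {
    .best_hit(m[, j], prots_b[[j]], prots_a, gap_open, gap_extend)
  }, integer(1))

  rows <- list()
  for (i in seq_along(prots_a)) {
    j <- best_in_b[i]
    if (best_in_a[j] == i && m[i, j] > min_score) {
      hit <- align_proteins(prots_a[[i]], prots_b[[j]], gap_open,
                            gap_extend, mode = "local")
      rows[[length(rows) + 1]] <- data.frame(
        id_a = names(prots_a)[i], id_b = names(prots_b)[j],
        score = hit$score, overlap_nt = hit$overlap_nt,
        coverage_a = hit$coverage_a, coverage_b = hit$coverage_b,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), overlap_nt = numeric(0),
                      coverage_a = numeric(0), coverage_b = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$id_a), , drop = FALSE]
}

#' Attach codon alignments to candidate pairs
#'
#' Produces a protein-guided codon alignment for every pair (stops
#' tolerated at this stage so that the stop filter can act on them).
#'
#' @param pairs data frame from [find_bbh()]
#' @param cds_a,cds_b the CDS sets used to build the pairs
#' @param gap_open,gap_extend gap penalties for the guide alignment
#' @return list of `codon_alignment` objects, one per pair, named by
#'   `id_a|id_b`
#' @export
attach_codon_alignments <- function(pairs, cds_a, cds_b, gap_open = 11,
                                    gap_extend = 1) {
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ca <- cds_a[[pairs$id_a[k]]]
    cb <- cds_b[[pairs$id_b[k]]]
    out[[k]] <- codon_align(ca$nt, cb$nt,
                            pair_id = paste0(pairs$id_a[k], "|", pairs$id_b[k]),
                            gap_open = gap_open, gap_extend = gap_extend,
                            check_stops = FALSE)
  }
  names(out) <- paste0(pairs$id_a, "|", pairs$id_b)
  out
}

#' Apply the overlap / coverage / stop-or-ambiguous filters
#'
#' Flags a pair `overlap` when the aligned overlap is 150 bp or less
#' (the retention rule is strictly greater than 150 bp), `coverage` when
#' either sequence is covered below `min_coverage` (boundary inclusive),
#' and `stop_or_ambiguous` when an internal stop codon appears in either
#' aligned CDS or the gap-column fraction of the codon alignment exceeds
#' `max_gap_col_frac`. The Ks filter is applied downstream, after Ka/Ks
#' estimation (see [apply_ks_filter()]).
#'
#' @param pairs data frame from [find_bbh()]
#' @param alignments codon alignments from [attach_codon_alignments()]
#' @param min_overlap_nt overlap threshold in nt (retained iff strictly
#'   greater)
#' @param min_coverage minimum aligned fraction required of both
#'   sequences
#' @param max_gap_col_frac maximum tolerated fraction of gap columns
#' @return list with `retained` (pair data frame), `excluded` (pair data
#'   frame with a `reasons` column, comma-separated) and `counts` (named
#'   exclusion tally per filter)
#' @export
filter_ortholog_pairs <- function(pairs, alignments, min_overlap_nt = 150,
                                  min_coverage = 0.9,
                                  max_gap_col_frac = 0.2) {
  reasons <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    fl <- character(0)
    if (pairs$overlap_nt[k] <= min_overlap_nt) fl <- c(fl, "overlap")
    if (min(pairs$coverage_a[k], pairs$coverage_b[k]) < min_coverage) {
      fl <- c(fl, "coverage")
    }
    aln <- alignments[[k]]
    has_stop <- any(aln$codons_a %in% STOP_CODONS) ||
      any(aln$codons_b %in% STOP_CODONS)
    gap_frac <- mean(aln$codons_a == "---" | aln$codons_b == "---")
    if (has_stop || gap_frac > max_gap_col_frac) {
      fl <- c(fl, "stop_or_ambiguous")
    }
    reasons[[k]] <- fl
  }
  flagged <- lengths(reasons) > 0
  excluded <- pairs[flagged, , drop = FALSE]
  excluded$reasons <- vapply(reasons[flagged], paste, character(1),
                             collapse = ",")
  counts <- c(
    overlap = sum(vapply(reasons, function(r) "overlap" %in% r, logical(1))),
    coverage = sum(vapply(reasons, function(r) "coverage" %in% r, logical(1))),
    stop_or_ambiguous = sum(vapply(reasons, function(r)
      "stop_or_ambiguous" %in% r, logical(1)))
  )
  list(
    retained = pairs[!flagged, , drop = FALSE],
    excluded = excluded,
    counts = counts
  )
}
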