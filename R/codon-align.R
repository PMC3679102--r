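# Protein-guided codon alignment: the two CDSs are translated, the
# proteins aligned globally, and the protein alignment back-translated
# so that every protein gap becomes a whole-codon gap. This preserves
# codon structure by construction and suits the low-divergence pairs the
# Ks <= 0.1 regime keeps.

#' Codon-aware alignment of two coding sequences
#'
#' @param nt_a,nt_b in-frame nucleotide sequences (length divisible by 3)
#' @param pair_id identifier carried on the result
#' @param gap_open,gap_extend affine gap penalties for the protein guide
#'   alignment
#' @param check_stops when `TRUE` (default) an internal stop codon in
#'   either CDS is a validation error; the orthology filter path sets
#'   `FALSE` so that planted stops reach the stop filter
#' @return a `codon_alignment` list: `pair_id`, `codons_a`, `codons_b`
#'   (equal-length codon vectors with `"---"` gaps) and
#'   `gapless_len_nt` (3 x columns ungapped in both sequences, stop
#'   columns excluded)
#' @export
codon_align <- function(nt_a, nt_b, pair_id = NA_character_,
                        gap_open = 11, gap_extend = 1,
                        check_stops = TRUE) {
  cod_a <- split_codons(toupper(nt_a))
  cod_b <- split_codons(toupper(nt_b))
  if (check_stops) {
    if (any(cod_a %in% STOP_CODONS) || any(cod_b %in% STOP_CODONS)) {
      stop("internal stop codon in CDS for pair ", pair_id)
    }
  }
  prot_a <- translate_cds(paste(cod_a, collapse = ""))
  prot_b <- translate_cds(paste(cod_b, collapse = ""))
  if (identical(prot_a, prot_b)) {
    # identical proteins need no guide alignment
    aligned_a <- cod_a
    aligned_b <- cod_b
  } else {
    aln <- align_proteins(prot_a, prot_b, gap_open = gap_open,
                          gap_extend = gap_extend, mode = "global")
    ga <- strsplit(aln$aligned_a, "")[[1]]
    gb <- strsplit(aln$aligned_b, "")[[1]]
    aligned_a <- character(length(ga))
    aligned_b <- character(length(gb))
    ia <- 0; ib <- 0
    for (k in seq_along(ga)) {
      if (ga[k] == "-") {
        aligned_a[k] <- "---"
      } else {
        ia <- ia + 1
        aligned_a[k] <- cod_a[ia]
      }
      if (gb[k] == "-") {
        aligned_b[k] <- "---"
      } else {
        ib <- ib + 1
        aligned_b[k] <- cod_b[ib]
      }
    }
  }
  structure(
    list(
      pair_id = pair_id,
      codons_a = aligned_a,
      codons_b = aligned_b,
      gapless_len_nt = 3L * sum(
        aligned_a != "---" & aligned_b != "---" &
          !(aligned_a %in% STOP_CODONS) & !(aligned_b %in% STOP_CODONS)
      )
    ),
    class = "codon_alignment"
  )
}

#' Build a codon alignment directly from an already-aligned pair
#'
#' Simulated ortholog pairs are gap-free and in frame, so no guide
#' alignment is needed.
#'
#' @param nt_a,nt_b equal-length in-frame nucleotide sequences
#' @param pair_id identifier carried on the result
#' @return a `codon_alignment` object
#' @export
codon_alignment_from_cds <- function(nt_a, nt_b, pair_id = NA_character_) {
  if (nchar(nt_a) != nchar(nt_b)) {
    stop("sequences differ in length; use codon_align()")
  }
  cod_a <- split_codons(toupper(nt_a))
  cod_b <- split_codons(toupper(nt_b))
  structure(
    list(
      pair_id = pair_id, codons_a = cod_a, codons_b = cod_b,
      gapless_len_nt = 3L * sum(
        !(cod_a %in% STOP_CODONS) & !(cod_b %in% STOP_CODONS)
      )
    ),
    class = "codon_alignment"
  )
}

# ungapped, stop-free codon columns of an alignment
.ungapped_columns <- function(alignment) {
  keep <- alignment$codons_a != "---" & alignment$codons_b != "---" &
    !(alignment$codons_a %in% STOP_CODONS) &
    !(alignment$codons_b %in% STOP_CODONS)
  list(a = alignment$codons_a[keep], b = alignment$codons_b[keep])
}

#' Descriptive statistics of a codon alignment
#'
#' GC content is computed jointly over both sequences' ungapped columns;
#' the gapless length counts columns ungapped in both sequences (stop
#' codons excluded), in nucleotides.
#'
#' @param alignment a `codon_alignment` object
#' @return list with `gc`, `gapless_len_nt`, `n_codon_diffs` (differing
#'   ungapped codon columns) and `n_nt_diffs` (nucleotide differences in
#'   those columns)
#' @export
pair_stats <- function(alignment) {
  cols <- .ungapped_columns(alignment)
  nt <- paste0(paste(cols$a, collapse = ""), paste(cols$b, collapse = ""))
  chars <- strsplit(nt, "")[[1]]
  gc <- if (length(chars) == 0) NA_real_ else mean(chars %in% c("G", "C"))
  diffs <- cols$a != cols$b
  n_nt <- 0L
  if (any(diffs)) {
    n_nt <- sum(vapply(which(diffs), function(i) {
      sum(strsplit(cols$a[i], "")[[1]] != strsplit(cols$b[i], "")[[1]])
    }, numeric(1)))
  }
  list(
    gc = gc,
    gapless_len_nt = alignment$gapless_len_nt,
    n_codon_diffs = sum(diffs),
    n_nt_diffs = as.integer(n_nt)
  )
}
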