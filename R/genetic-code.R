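# Codon-level machinery shared by the simulator and the Ka/Ks estimators.
#
# Everything here is derived once from the universal genetic code at load
# time and cached: the 61 sense codons, the single-nucleotide neighbour
# graph with synonymous/transition annotations, and the NG86 per-codon
# synonymous-site fractions.

NUCS <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Is a single-nucleotide change a transition?
#'
#' Transitions are A<->G and C<->T; all other changes are transversions.
#' @param from,to single upper-case nucleotide characters
#' @return logical
#' @keywords internal
is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

.genetic_code <- function() {
  gc <- .kaksflow_cache$genetic_code
  if (is.null(gc)) {
    gc <- Biostrings::GENETIC_CODE
    .kaksflow_cache$genetic_code <- gc
  }
  gc
}

.build_codon_tables <- function() {
  if (!is.null(.kaksflow_cache$codon_tables)) {
    return(invisible(.kaksflow_cache$codon_tables))
  }
  gc <- .genetic_code()
  codons64 <- names(gc)
  sense <- codons64[gc != "*"]
  aa <- gc[sense]

  # neighbour table: for each sense codon all 9 single-nucleotide changes
  neighbors <- vector("list", length(sense))
  names(neighbors) <- sense
  for (c1 in sense) {
    nt <- strsplit(c1, "")[[1]]
    tgt <- character(0); pos <- integer(0); to_nt <- character(0)
    for (p in 1:3) {
      for (x in setdiff(NUCS, nt[p])) {
        c2 <- nt
        c2[p] <- x
        tgt <- c(tgt, paste(c2, collapse = ""))
        pos <- c(pos, p)
        to_nt <- c(to_nt, x)
      }
    }
    is_stop <- tgt %in% STOP_CODONS
    syn <- !is_stop & gc[tgt] == gc[c1]
    ts <- is_transition(substring(c1, pos, pos), to_nt)
    neighbors[[c1]] <- data.frame(
      target = tgt, pos = pos, to_nt = to_nt,
      is_stop = is_stop, is_syn = unname(syn), is_ts = unname(ts),
      stringsAsFactors = FALSE
    )
  }

  # NG86 synonymous-site fraction per codon: among the single-nucleotide
  # changes that do not create a stop, the fraction that is synonymous,
  # scaled to 3 sites per codon.
  fS <- vapply(sense, function(c1) {
    nb <- neighbors[[c1]]
    nb <- nb[!nb$is_stop, ]
    3 * sum(nb$is_syn) / nrow(nb)
  }, numeric(1))

  # degeneracy class per codon position: number of the 3 alternative
  # nucleotides that keep the amino acid (stop targets never count)
  degeneracy <- t(vapply(sense, function(c1) {
    nb <- neighbors[[c1]]
    vapply(1:3, function(p) sum(nb$is_syn[nb$pos == p]), numeric(1))
  }, numeric(3)))

  tables <- list(
    sense = sense, aa = aa, neighbors = neighbors,
    fS = fS, degeneracy = degeneracy
  )
  .kaksflow_cache$codon_tables <- tables
  .kaksflow_cache$path_memo <- new.env(parent = emptyenv())
  invisible(tables)
}

.codon_tables <- function() {
  tbl <- .kaksflow_cache$codon_tables
  if (is.null(tbl)) tbl <- .build_codon_tables()
  tbl
}

#' Sense codons of the universal genetic code
#' @return character vector of the 61 codons that encode an amino acid
#' @export
sense_codons <- function() .codon_tables()$sense

#' NG86 synonymous site count of a codon
#'
#' Enumerates all nine single-nucleotide changes of the codon; changes
#' that would create a stop codon are excluded from the denominator. The
#' returned value is the expected number of synonymous sites (out of 3).
#'
#' @param codon character vector of sense codons
#' @return numeric vector of synonymous site counts in `[0, 3]`
#' @examples
#' ng86_syn_sites("TTT") # 1/3: only TTT->TTC is synonymous
#' @export
ng86_syn_sites <- function(codon) {
  tbl <- .codon_tables()
  codon <- toupper(codon)
  bad <- !codon %in% tbl$sense
  if (any(bad)) {
    stop("not a sense codon: ", paste(unique(codon[bad]), collapse = ", "))
  }
  unname(tbl$fS[codon])
}

#' Translate an in-frame coding sequence
#'
#' @param nt nucleotide string with length divisible by 3
#' @return amino-acid string; stop codons become `*`, codons containing
#'   `N` become `X`
#' @export
translate_cds <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) %% 3 != 0) stop("sequence length not divisible by 3")
  if (nchar(nt) == 0) return("")
  codons <- split_codons(nt)
  gc <- .genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Split an in-frame sequence into codons
#' @param nt nucleotide string, length divisible by 3
#' @return character vector of codons
#' @export
split_codons <- function(nt) {
  n <- nchar(nt)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  if (n == 0) return(character(0))
  substring(nt, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Reverse complement of a nucleotide string
#' @param nt nucleotide string over A,C,G,T,N
#' @return reverse-complemented string
#' @export
revcomp <- function(nt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  x <- rev(strsplit(toupper(nt), "")[[1]])
  paste(comp[x], collapse = "")
}

# ---- minimal substitution paths between two codons -------------------------
#
# For a codon pair differing at k positions there are k! orderings of the
# single-nucleotide steps. Paths passing through a stop codon are dropped
# (unless every path does, in which case all are kept so the pair still
# contributes). Each step is annotated synonymous/nonsynonymous and
# transition/transversion; estimators weight the paths.

.codon_paths <- function(c1, c2) {
  key <- paste0(c1, c2)
  memo <- .kaksflow_cache$path_memo
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)

  gc <- .genetic_code()
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(n1 != n2)
  k <- length(diff_pos)
  if (k == 0) {
    out <- list()
  } else {
    orders <- if (k == 1) list(diff_pos) else {
      perms <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v)) {
          for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
        }
        out
      }
      perms(diff_pos)
    }
    build <- function(ord) {
      cur <- n1
      steps <- vector("list", length(ord))
      via_stop <- FALSE
      for (i in seq_along(ord)) {
        p <- ord[i]
        nxt <- cur
        nxt[p] <- n2[p]
        from_cod <- paste(cur, collapse = "")
        to_cod <- paste(nxt, collapse = "")
        to_stop <- to_cod %in% STOP_CODONS
        from_stop <- from_cod %in% STOP_CODONS
        if (to_stop && i < length(ord)) via_stop <- TRUE
        syn <- !to_stop && !from_stop && gc[from_cod] == gc[to_cod]
        steps[[i]] <- list(
          pos = p, to_nt = n2[p],
          is_syn = unname(syn),
          is_ts = is_transition(cur[p], n2[p]),
          to_stop = to_stop || from_stop
        )
        cur <- nxt
      }
      list(steps = steps, via_stop = via_stop || to_cod %in% STOP_CODONS)
    }
    paths <- lapply(orders, build)
    ok <- !vapply(paths, `[[`, logical(1), "via_stop")
    if (any(ok)) paths <- paths[ok]
    out <- lapply(paths, `[[`, "steps")
  }
  memo[[key]] <- out
  out
}
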