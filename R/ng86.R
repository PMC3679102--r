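# Nei-Gojobori (1986) counting estimator with Jukes-Cantor correction.
# Serves as the transparent counting oracle against which the
# Yang-Nielsen approximate-ML estimator is cross-checked.

# expected substitution counts between the two sequences, resolved over
# minimal single-nucleotide paths. `path_weight` maps a path (list of
# steps) to a non-negative weight; weights are normalised per codon pair.
# Returns syn/nonsyn x ts/tv expected counts.
.count_substitutions <- function(cols_a, cols_b, path_weight) {
  acc <- c(syn_ts = 0, syn_tv = 0, nonsyn_ts = 0, nonsyn_tv = 0)
  diff <- which(cols_a != cols_b)
  for (i in diff) {
    paths <- .codon_paths(cols_a[i], cols_b[i])
    w <- vapply(paths, path_weight, numeric(1))
    if (all(w <= 0)) w <- rep(1, length(w))
    w <- w / sum(w)
    for (p in seq_along(paths)) {
      for (st in paths[[p]]) {
        key <- if (st$is_syn) {
          if (st$is_ts) "syn_ts" else "syn_tv"
        } else {
          if (st$is_ts) "nonsyn_ts" else "nonsyn_tv"
        }
        acc[key] <- acc[key] + w[p]
      }
    }
  }
  acc
}

# Jukes-Cantor multiple-hit correction of a raw proportion
.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  arg <- 1 - 4 * p / 3
  if (arg <= 0) return(NA_real_)
  -3 / 4 * log(arg)
}

.kaks_result <- function(pair_id, S, N, Sd, Nd, Ka, Ks, kappa, gc,
                         gapless_len_nt, method) {
  S <- unname(S); N <- unname(N); Sd <- unname(Sd); Nd <- unname(Nd)
  Ka <- unname(Ka); Ks <- unname(Ks)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  p <- fisher_validity(S, N, Sd, Nd)
  res <- list(
    pair_id = pair_id, method = method,
    S = S, N = N, Sd = Sd, Nd = Nd,
    Ka = Ka, Ks = Ks, ratio = ratio, kappa = kappa,
    gc = gc, gapless_len_nt = gapless_len_nt,
    p_fisher = p, category = NA_character_
  )
  res$category <- classify_pair(res)
  structure(res, class = "kaks_result")
}

#' Ka/Ks by Nei-Gojobori counting
#'
#' Synonymous and nonsynonymous site counts come from enumerating all
#' nine single-nucleotide changes of every ungapped codon (changes to
#' stop codons are excluded from the denominator); substitution counts
#' average equally over all minimal substitution paths through sense
#' codons; distances apply the Jukes-Cantor correction
#' `d = -3/4 ln(1 - 4p/3)`, undefined when the log argument is
#' non-positive.
#'
#' @param alignment a `codon_alignment` object
#' @return a `kaks_result` list with sites (`S`, `N`), substitutions
#'   (`Sd`, `Nd`), rates (`Ka`, `Ks`, `ratio`), `gc`, `gapless_len_nt`,
#'   the Fisher validity p-value and the selection category
#' @export
ng86 <- function(alignment) {
  cols <- .ungapped_columns(alignment)
  L <- length(cols$a)
  if (L == 0) stop("no ungapped codon columns")
  fS_a <- sum(ng86_syn_sites(cols$a))
  fS_b <- sum(ng86_syn_sites(cols$b))
  S <- (fS_a + fS_b) / 2
  N <- 3 * L - S
  counts <- .count_substitutions(cols$a, cols$b, function(p) 1)
  Sd <- counts["syn_ts"] + counts["syn_tv"]
  Nd <- counts["nonsyn_ts"] + counts["nonsyn_tv"]
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  Ks <- .jc_correct(ps)
  Kn <- .jc_correct(pn)
  st <- pair_stats(alignment)
  .kaks_result(
    pair_id = alignment$pair_id,
    S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
    Ka = Kn, Ks = Ks, kappa = NA_real_,
    gc = st$gc, gapless_len_nt = st$gapless_len_nt, method = "ng"
  )
}
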