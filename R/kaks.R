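# Validity testing, the Ks paralog filter, selection-category
# classification, and replicate-level omega recovery summaries.

#' Fisher exact validity test of a Ka/Ks estimate
#'
#' Tests the association between site class and substitution status on
#' the 2x2 table `[[Sd, S-Sd], [Nd, N-Nd]]` (two-sided). Fractional
#' counts are rounded half away from zero before tabulation.
#'
#' @param S,N synonymous/nonsynonymous site counts (>= 0)
#' @param Sd,Nd synonymous/nonsynonymous substitution counts
#'   (`Sd <= S`, `Nd <= N`)
#' @return two-sided p-value
#' @export
fisher_validity <- function(S, N, Sd, Nd) {
  if (any(c(S, N, Sd, Nd) < 0)) stop("all inputs must be >= 0")
  if (Sd > S || Nd > N) stop("substitutions exceed sites")
  r <- function(x) sign(x) * floor(abs(x) + 0.5)  # half away from zero
  tab <- matrix(c(r(Sd), r(S - Sd), r(Nd), r(N - Nd)), nrow = 2,
                byrow = TRUE)
  if (any(tab < 0)) tab[tab < 0] <- 0
  if (sum(tab) == 0) return(1)
  fisher.test(tab)$p.value
}

#' Exclude candidate orthologs with excessive synonymous divergence
#'
#' A pair is excluded iff its Ks is defined and strictly greater than
#' `ks_max`; pairs with undefined Ks are retained and handled by the
#' category classification.
#'
#' @param results list of `kaks_result` objects
#' @param ks_max Ks threshold (default 0.1)
#' @return list with `retained` and `excluded` (both lists of
#'   `kaks_result`)
#' @export
apply_ks_filter <- function(results, ks_max = 0.1) {
  ks <- vapply(results, function(r) {
    if (is.na(r$Ks)) -Inf else r$Ks
  }, numeric(1))
  drop <- ks > ks_max
  list(retained = results[!drop], excluded = results[drop])
}

#' Selection category of a Ka/Ks result
#'
#' `positive` when both rates are defined, Ks > 0 and Ka/Ks > 1;
#' `weak_purifying` for a ratio in (0.5, 1]; `purifying` for (0, 0.5];
#' `ka_only` when Ka is defined and positive but Ks is undefined or 0
#' (the ratio is reported as undefined rather than infinite);
#' `ks_only` symmetrically; `incalculable` otherwise.
#'
#' @param result a `kaks_result` (or any list with `Ka`, `Ks`, `ratio`)
#' @return category string
#' @export
classify_pair <- function(result) {
  ka <- result$Ka
  ks <- result$Ks
  ka_def <- !is.na(ka)
  ks_def <- !is.na(ks)
  if (ka_def && ks_def && ks > 0) {
    ratio <- ka / ks
    if (ratio > 1) return("positive")
    if (ratio > 0.5) return("weak_purifying")
    if (ratio > 0) return("purifying")
    # Ka == 0 with usable Ks: only the synonymous rate is informative
    return("ks_only")
  }
  if (ka_def && ka > 0 && (!ks_def || ks == 0)) return("ka_only")
  if (ks_def && ks > 0 && (!ka_def || ka == 0)) return("ks_only")
  "incalculable"
}

#' Convert a list of `kaks_result` objects to a data frame
#'
#' @param results list of `kaks_result` objects
#' @return data frame in the `kaks` results-table schema
#' @export
kaks_table <- function(results) {
  if (length(results) == 0) {
    return(data.frame(
      pair_id = character(0), S = numeric(0), N = numeric(0),
      Sd = numeric(0), Nd = numeric(0), Ka = numeric(0), Ks = numeric(0),
      ratio = numeric(0), kappa = numeric(0), gc = numeric(0),
      gapless_len_nt = integer(0), p_fisher = numeric(0),
      category = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      pair_id = r$pair_id, S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
      Ka = r$Ka, Ks = r$Ks, ratio = r$ratio, kappa = r$kappa, gc = r$gc,
      gapless_len_nt = r$gapless_len_nt, p_fisher = r$p_fisher,
      category = r$category, stringsAsFactors = FALSE
    )
  }))
}

#' Simulate replicate ortholog pairs and estimate Ka/Ks on each
#'
#' Workhorse for parameter-recovery and false-positive-control studies:
#' simulates `n_reps` pairs under one omega and runs the chosen
#' estimator on each.
#'
#' @param omega planted nonsynonymous/synonymous rate ratio
#' @param n_reps number of replicate pairs
#' @param n_codons codons per pair
#' @param t divergence (expected substitutions per codon, whole path)
#' @param kappa transition/transversion ratio of the generating model
#' @param seed integer seed (required)
#' @param method `"yn"` or `"ng"`
#' @return data frame of per-replicate results (kaks schema) with an
#'   attribute `omega_pooled`: the aggregate estimate
#'   `mean(Ka)/mean(Ks)` over replicates with both rates defined
#' @export
simulate_kaks_replicates <- function(omega, n_reps, n_codons = 300,
                                     t = 0.1, kappa = 2, seed,
                                     method = c("yn", "ng")) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  method <- match.arg(method)
  est <- if (method == "yn") yn00 else ng86
  params <- codon_model_params(kappa = kappa, omega = omega)
  set.seed(as.integer(seed))
  child_seeds <- sample.int(2^31 - 2, n_reps)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_codon_pair(n_codons, params, t, seed = child_seeds[r])
    aln <- codon_alignment_from_cds(sim$seq_a, sim$seq_b,
                                    pair_id = sprintf("rep%04d", r))
    rows[[r]] <- est(aln)
  }
  out <- kaks_table(rows)
  both <- !is.na(out$Ka) & !is.na(out$Ks)
  attr(out, "omega_pooled") <- if (any(both) && mean(out$Ks[both]) > 0) {
    mean(out$Ka[both]) / mean(out$Ks[both])
  } else NA_real_
  out
}
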