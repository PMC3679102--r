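# Yang-Nielsen (2000) approximate method: kappa is estimated from
# nucleotide differences at fourfold-degenerate and nondegenerate codon
# positions; synonymous/nonsynonymous site counts are weighted by the
# transition/transversion ratio and F3x4 codon-position nucleotide
# frequencies; substitution counts weight minimal paths by the codon
# model (kappa, omega, target-nucleotide frequency); distances use the
# Kimura two-parameter correction applied separately to the synonymous
# and nonsynonymous site classes; the omega used in path weighting is
# iterated to a fixed point.

# K80 correction from transition (P) and transversion (Q) proportions:
# returns total distance d plus the transition/transversion components
.k80 <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    return(list(d = NA_real_, ts = NA_real_, tv = NA_real_))
  }
  ts <- -0.5 * log(a1) + 0.25 * log(a2)
  tv <- -0.5 * log(a2)
  list(d = ts + tv, ts = ts, tv = tv)
}

# F3x4: nucleotide frequencies per codon position, pooled over both
# sequences' ungapped codons
.f3x4 <- function(cols_a, cols_b) {
  m <- matrix(0, 3, 4, dimnames = list(NULL, NUCS))
  all_cod <- c(cols_a, cols_b)
  for (p in 1:3) {
    nt <- substring(all_cod, p, p)
    tab <- table(factor(nt, levels = NUCS))
    m[p, ] <- (tab + 1e-9) / sum(tab + 4e-9)  # tiny prior avoids zeros
  }
  m
}

# kappa from fourfold-degenerate and nondegenerate positions: K80
# applied per class, combined with site-count weights
.estimate_kappa <- function(cols_a, cols_b) {
  tbl <- .codon_tables()
  deg <- tbl$degeneracy
  L <- c(four = 0, zero = 0)
  ts_cnt <- c(four = 0, zero = 0)
  tv_cnt <- c(four = 0, zero = 0)
  for (i in seq_along(cols_a)) {
    da <- deg[cols_a[i], ]
    db <- deg[cols_b[i], ]
    for (p in 1:3) {
      cls <- if (da[p] == 3 && db[p] == 3) "four"
             else if (da[p] == 0 && db[p] == 0) "zero"
             else next
      L[cls] <- L[cls] + 1
      na <- substring(cols_a[i], p, p)
      nb <- substring(cols_b[i], p, p)
      if (na != nb) {
        if (is_transition(na, nb)) ts_cnt[cls] <- ts_cnt[cls] + 1
        else tv_cnt[cls] <- tv_cnt[cls] + 1
      }
    }
  }
  kap <- c(four = NA_real_, zero = NA_real_)
  for (cls in c("four", "zero")) {
    if (L[cls] == 0) next
    k <- .k80(ts_cnt[cls] / L[cls], tv_cnt[cls] / L[cls])
    if (!is.na(k$ts) && k$tv > 0 && k$ts > 0) {
      kap[cls] <- (k$ts / k$tv)  # alpha*t / beta*t = kappa / 2 * 2 -> see note
    }
  }
  # ts component equals (kappa/2) x tv component under K80 with two
  # transversion types, so the rate ratio is 2 x (ts/tv distance ratio)
  kap <- 2 * kap
  ok <- !is.na(kap)
  if (!any(ok)) return(list(kappa = 1, estimated = FALSE))
  list(kappa = sum(kap[ok] * L[ok]) / sum(L[ok]), estimated = TRUE)
}

# per-codon synonymous site fraction under the mutation model (kappa,
# F3x4 target-nucleotide weights); stop targets excluded
.yn_syn_sites <- function(codon, kappa, f3x4) {
  tbl <- .codon_tables()
  nb <- tbl$neighbors[[codon]]
  nb <- nb[!nb$is_stop, ]
  w <- f3x4[cbind(nb$pos, match(nb$to_nt, NUCS))] *
    ifelse(nb$is_ts, kappa, 1)
  tot <- sum(w)
  if (tot <= 0) return(0)
  3 * sum(w[nb$is_syn]) / tot
}

#' Ka/Ks by the Yang-Nielsen approximate maximum-likelihood method
#'
#' @param alignment a `codon_alignment` object
#' @param tol convergence tolerance on omega (default 1e-6)
#' @param max_iter iteration cap (default 100); non-convergence is
#'   reported via the `converged` flag, not an error
#' @return a `kaks_result` list (see [ng86()]) with additional fields
#'   `converged` and `kappa_estimated`
#' @export
yn00 <- function(alignment, tol = 1e-6, max_iter = 100) {
  cols <- .ungapped_columns(alignment)
  L <- length(cols$a)
  if (L == 0) stop("no ungapped codon columns")
  f3 <- .f3x4(cols$a, cols$b)
  kp <- .estimate_kappa(cols$a, cols$b)
  kappa <- kp$kappa

  site_tab <- new.env(parent = emptyenv())
  syn_sites <- function(codon) {
    v <- site_tab[[codon]]
    if (is.null(v)) {
      v <- .yn_syn_sites(codon, kappa, f3)
      site_tab[[codon]] <- v
    }
    v
  }
  S_a <- sum(vapply(cols$a, syn_sites, numeric(1)))
  S_b <- sum(vapply(cols$b, syn_sites, numeric(1)))
  S <- (S_a + S_b) / 2
  N <- 3 * L - S

  omega <- 1
  converged <- FALSE
  Ka <- NA_real_; Ks <- NA_real_
  counts <- NULL
  for (it in seq_len(max_iter)) {
    path_weight <- function(steps) {
      w <- 1
      for (st in steps) {
        w <- w * f3[st$pos, st$to_nt] *
          (if (st$is_ts) kappa else 1) *
          (if (st$is_syn) 1 else omega)
      }
      w
    }
    counts <- .count_substitutions(cols$a, cols$b, path_weight)
    ks_fit <- .k80(counts["syn_ts"] / S, counts["syn_tv"] / S)
    ka_fit <- .k80(counts["nonsyn_ts"] / N, counts["nonsyn_tv"] / N)
    Ks <- ks_fit$d
    Ka <- ka_fit$d
    if (is.na(Ka) || is.na(Ks) || Ks <= 0 || Ka <= 0) {
      # omega not iterable; counts from the current weighting stand
      converged <- TRUE
      break
    }
    new_omega <- Ka / Ks
    if (abs(new_omega - omega) < tol) {
      omega <- new_omega
      converged <- TRUE
      break
    }
    omega <- new_omega
  }

  st <- pair_stats(alignment)
  res <- .kaks_result(
    pair_id = alignment$pair_id,
    S = unname(S), N = unname(N),
    Sd = unname(counts["syn_ts"] + counts["syn_tv"]),
    Nd = unname(counts["nonsyn_ts"] + counts["nonsyn_tv"]),
    Ka = Ka, Ks = Ks, kappa = kappa,
    gc = st$gc, gapless_len_nt = st$gapless_len_nt, method = "yn"
  )
  res$converged <- converged
  res$kappa_estimated <- kp$estimated
  res
}
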