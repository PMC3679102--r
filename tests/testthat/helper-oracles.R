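# Independent oracles built directly from the genetic code, used to
# cross-check the package's codon tables and estimators.

oracle_code <- Biostrings::GENETIC_CODE
oracle_sense <- names(oracle_code)[oracle_code != "*"]
oracle_stops <- names(oracle_code)[oracle_code == "*"]

# all nine single-nucleotide neighbours of a codon
oracle_neighbors <- function(codon) {
  nt <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) {
    for (x in setdiff(c("A", "C", "G", "T"), nt[p])) {
      alt <- nt
      alt[p] <- x
      out <- c(out, paste(alt, collapse = ""))
    }
  }
  out
}

# NG86 synonymous sites of a codon by direct enumeration
oracle_syn_sites <- function(codon) {
  nb <- oracle_neighbors(codon)
  nb <- nb[!nb %in% oracle_stops]
  3 * sum(oracle_code[nb] == oracle_code[codon]) / length(nb)
}

# expected fraction of realized substitutions that are synonymous under
# kappa = 1, omega = 1, uniform codon frequencies: flux ratio over the
# uniform stationary distribution
oracle_syn_flux_share <- function() {
  syn <- 0
  tot <- 0
  for (c1 in oracle_sense) {
    nb <- oracle_neighbors(c1)
    nb <- nb[!nb %in% oracle_stops]
    syn <- syn + sum(oracle_code[nb] == oracle_code[c1])
    tot <- tot + length(nb)
  }
  syn / tot
}

# one-sided hypergeometric tail P(X >= a) for the 2x2 table
# [[a, b], [c, d]] by direct enumeration
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b      # white balls (in category)
  n <- c + d      # black balls
  k <- a + c      # draws (PSG size)
  xs <- max(0, k - n):min(m, k)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= a])
}

# tiny in-memory fixture for read-generation tests
toy_fixture <- function(seqs, abund_control, abund_stress) {
  n <- length(seqs)
  ids <- sprintf("g%02d", seq_len(n))
  list(
    fasta_a = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
    fasta_b = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
    truth = data.frame(
      pair_id = ids, id_a = ids, id_b = ids,
      abund_control_a = abund_control, abund_stress_a = abund_stress,
      abund_control_b = abund_control, abund_stress_b = abund_stress,
      stringsAsFactors = FALSE
    )
  )
}

# deterministic random in-frame stop-free CDS for alignment tests
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  paste(sample(oracle_sense, n_codons, replace = TRUE), collapse = "")
}
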