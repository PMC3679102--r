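# Codon-substitution simulator and fixture generator.
#
# The generating model is GY94-style: a continuous-time Markov chain on
# the 61 sense codons in which only single-nucleotide changes have
# positive rate,
#
#   q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous],
#
# changes into stop codons are forbidden, and the chain is scaled so that
# one unit of t equals one expected substitution per codon at
# stationarity. An ortholog pair is produced by drawing an ancestor from
# `codon_freqs` and evolving each lineage independently for t/2.

#' Parameters of the codon substitution model
#'
#' @param kappa transition/transversion rate ratio (> 0)
#' @param omega nonsynonymous/synonymous rate ratio (>= 0)
#' @param codon_freqs probability vector over the 61 sense codons (in the
#'   order of [sense_codons()]); default uniform. Must sum to 1.
#' @return object of class `codon_model_params`
#' @export
codon_model_params <- function(kappa = 2, omega = 0.2, codon_freqs = NULL) {
  sense <- sense_codons()
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) stop("omega must be >= 0")
  if (is.null(codon_freqs)) {
    codon_freqs <- rep(1 / length(sense), length(sense))
  }
  if (length(codon_freqs) != length(sense)) {
    stop("codon_freqs must have ", length(sense), " entries")
  }
  if (any(codon_freqs < 0) || abs(sum(codon_freqs) - 1) > 1e-9) {
    stop("codon_freqs must be non-negative and sum to 1")
  }
  structure(
    list(kappa = kappa, omega = omega,
         codon_freqs = setNames(codon_freqs, sense)),
    class = "codon_model_params"
  )
}

# rate structure: per sense codon, target indices, per-target rates, and
# step annotations; scaled to 1 expected substitution/codon/unit time
.build_rates <- function(params) {
  tbl <- .codon_tables()
  sense <- tbl$sense
  pi <- params$codon_freqs
  targets <- vector("list", length(sense))
  rates <- vector("list", length(sense))
  syn <- vector("list", length(sense))
  ts <- vector("list", length(sense))
  total <- numeric(length(sense))
  for (i in seq_along(sense)) {
    nb <- tbl$neighbors[[sense[i]]]
    nb <- nb[!nb$is_stop, ]
    r <- pi[nb$target] *
      ifelse(nb$is_ts, params$kappa, 1) *
      ifelse(nb$is_syn, 1, params$omega)
    targets[[i]] <- match(nb$target, sense)
    rates[[i]] <- unname(r)
    syn[[i]] <- nb$is_syn
    ts[[i]] <- nb$is_ts
    total[i] <- sum(r)
  }
  scale <- sum(pi * total)
  if (scale <= 0) stop("degenerate model: total substitution rate is zero")
  list(
    targets = targets, rates = lapply(rates, function(r) r / scale),
    syn = syn, ts = ts, total = total / scale
  )
}

# evolve one codon (index into sense_codons()) for time tau; returns the
# final state plus realized event counts
.evolve_codon <- function(i, tau, rt) {
  n_events <- 0L
  counts <- c(syn_ts = 0L, syn_tv = 0L, nonsyn_ts = 0L, nonsyn_tv = 0L)
  repeat {
    rate <- rt$total[i]
    if (rate <= 0) break
    w <- rexp(1, rate)
    if (w > tau) break
    tau <- tau - w
    k <- sample.int(length(rt$rates[[i]]), 1, prob = rt$rates[[i]])
    key <- if (rt$syn[[i]][k]) {
      if (rt$ts[[i]][k]) "syn_ts" else "syn_tv"
    } else {
      if (rt$ts[[i]][k]) "nonsyn_ts" else "nonsyn_tv"
    }
    counts[key] <- counts[key] + 1L
    i <- rt$targets[[i]][k]
    n_events <- n_events + 1L
  }
  list(state = i, counts = counts, n_events = n_events)
}

#' Simulate a diverged ortholog codon-sequence pair
#'
#' Draws an ancestral sequence from the model's codon frequencies and
#' evolves two lineages independently for `t/2` each, so the pair is
#' separated by an expected `t` substitutions per codon.
#'
#' @param n_codons number of codons (>= 1)
#' @param params a [codon_model_params()] object
#' @param t expected substitutions per codon along the whole pair-path
#'   (>= 0)
#' @param seed integer seed; required (the simulator keeps no implicit
#'   RNG state)
#' @return list with `seq_a`, `seq_b` (nucleotide strings, stop-free,
#'   length `3 * n_codons`), `counts` (realized substitution counts split
#'   by synonymous/nonsynonymous and transition/transversion, summed over
#'   both lineages) and `events_per_codon` (integer vector)
#' @export
simulate_codon_pair <- function(n_codons, params, t, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (!is.numeric(n_codons) || n_codons < 1) stop("n_codons must be >= 1")
  if (!is.numeric(t) || t < 0) stop("t must be >= 0")
  stopifnot(inherits(params, "codon_model_params"))
  set.seed(as.integer(seed))
  sense <- sense_codons()
  rt <- .build_rates(params)
  anc <- sample.int(length(sense), n_codons, replace = TRUE,
                    prob = params$codon_freqs)
  counts <- c(syn_ts = 0L, syn_tv = 0L, nonsyn_ts = 0L, nonsyn_tv = 0L)
  events <- integer(n_codons)
  a <- integer(n_codons)
  b <- integer(n_codons)
  for (j in seq_len(n_codons)) {
    ra <- .evolve_codon(anc[j], t / 2, rt)
    rb <- .evolve_codon(anc[j], t / 2, rt)
    a[j] <- ra$state
    b[j] <- rb$state
    counts <- counts + ra$counts + rb$counts
    events[j] <- ra$n_events + rb$n_events
  }
  list(
    seq_a = paste(sense[a], collapse = ""),
    seq_b = paste(sense[b], collapse = ""),
    counts = counts,
    events_per_codon = events
  )
}

#' Generate a two-species transcriptome fixture with planted truth
#'
#' Builds paired coding sequences for two artificial species:
#' `ortholog` pairs diverged under known omega (cycled from
#' `omega_grid`), `paralog_decoy` pairs diverged deeply enough that the
#' expected Ks exceeds 0.1, `stop_contaminant` pairs carrying a planted
#' internal stop codon, `short_overlap` pairs whose second copy is
#' truncated so the alignable overlap is at most 150 bp, and
#' `low_coverage` pairs truncated to under 90% mutual coverage. GO labels
#' are attached so that `enriched_go` is over-represented among pairs
#' with planted omega > 1, and every pair receives per-species
#' control/stress relative abundances (a subset planted as
#' stress-induced).
#'
#' @param n_orthologs,n_decoys,n_contaminants,n_short_overlap,n_low_coverage
#'   non-negative counts of pairs per role
#' @param omega_grid non-empty numeric vector of omega values cycled over
#'   the ortholog pairs
#' @param seed integer seed (required)
#' @param n_codons_range inclusive range of pair lengths in codons
#' @param t divergence of ortholog-like pairs (expected substitutions per
#'   codon); decoys use `t_decoy`
#' @param kappa transition/transversion ratio of the generating model
#' @param t_decoy divergence of paralog decoys (must push Ks above 0.1)
#' @param enriched_go GO id planted as enriched among omega > 1 pairs
#' @param stress_fold fold-change planted for stress-induced genes
#' @param up_both_frac,up_a_frac,up_b_frac fractions of ortholog pairs
#'   planted as stress-induced in both species / species A only / B only
#' @return list with `fasta_a`, `fasta_b` (sequence-record data frames),
#'   `annotations` (gene_id/go_id data frame keyed on species-A ids) and
#'   `truth` (one row per pair: ids, role, true omega and t, GO ids,
#'   per-species control/stress abundances)
#' @export
generate_transcriptome_fixture <- function(n_orthologs,
                                           n_decoys = 0,
                                           n_contaminants = 0,
                                           omega_grid = c(0.2),
                                           seed,
                                           n_short_overlap = 0,
                                           n_low_coverage = 0,
                                           n_codons_range = c(280, 380),
                                           t = 0.05,
                                           kappa = 2,
                                           t_decoy = 1.0,
                                           enriched_go = "GO:0006950",
                                           stress_fold = 4,
                                           up_both_frac = 0.1,
                                           up_a_frac = 0.1,
                                           up_b_frac = 0.1) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  counts <- c(n_orthologs, n_decoys, n_contaminants, n_short_overlap,
              n_low_coverage)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (length(omega_grid) == 0) stop("omega_grid must be non-empty")
  set.seed(as.integer(seed))

  roles <- c(
    rep("ortholog", n_orthologs),
    rep("paralog_decoy", n_decoys),
    rep("stop_contaminant", n_contaminants),
    rep("short_overlap", n_short_overlap),
    rep("low_coverage", n_low_coverage)
  )
  n_pairs <- length(roles)
  omega_cycle <- rep_len(omega_grid, max(n_orthologs, 1))

  truth <- data.frame(
    pair_id = sprintf("pair%04d", seq_len(n_pairs)),
    id_a = sprintf("UnigeneA%04d_All", seq_len(n_pairs)),
    id_b = sprintf("UnigeneB%04d_All", seq_len(n_pairs)),
    role = roles,
    true_omega = rep(NA_real_, n_pairs),
    true_t = rep(NA_real_, n_pairs),
    go_ids = rep("", n_pairs),
    stringsAsFactors = FALSE
  )

  seq_a <- character(n_pairs)
  seq_b <- character(n_pairs)
  child_seeds <- if (n_pairs > 0) sample.int(2^31 - 2, n_pairs) else integer(0)
  ortho_i <- 0
  for (i in seq_len(n_pairs)) {
    role <- roles[i]
    n_cod <- sample(seq(n_codons_range[1], n_codons_range[2]), 1)
    if (role == "ortholog") {
      ortho_i <- ortho_i + 1
      om <- omega_cycle[ortho_i]
      tt <- t
    } else if (role == "paralog_decoy") {
      om <- 0.3
      tt <- t_decoy
    } else {
      om <- 0.2
      tt <- t
    }
    pp <- codon_model_params(kappa = kappa, omega = om)
    sim <- simulate_codon_pair(n_cod, pp, tt, seed = child_seeds[i])
    sa <- sim$seq_a
    sb <- sim$seq_b
    if (role == "stop_contaminant") {
      # plant an internal stop in the in-frame copy of species B
      pos <- max(2, floor(n_cod / 2))
      substring(sb, 3 * (pos - 1) + 1, 3 * pos) <- "TAA"
    } else if (role == "short_overlap") {
      # truncate so that at most 45 codons (135 nt <= 150 bp) can align
      keep <- min(45, n_cod)
      sb <- substring(sb, 1, 3 * keep)
    } else if (role == "low_coverage") {
      # keep > 150 bp of overlap but < 90% of the full length
      keep <- max(60, floor(0.65 * n_cod))
      sb <- substring(sb, 1, 3 * keep)
    }
    seq_a[i] <- sa
    seq_b[i] <- sb
    truth$true_omega[i] <- om
    truth$true_t[i] <- tt
  }

  # GO labels: the designated category is frequent among omega > 1 pairs
  # and rare elsewhere; a small pool of filler categories everywhere
  filler_pool <- sprintf("GO:%07d", c(8150, 3674, 5575, 6355, 9987,
                                      16043, 55085, 6979, 9058, 40007))
  go_ids <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    gos <- sample(filler_pool, sample(0:3, 1))
    p_enr <- if (!is.na(truth$true_omega[i]) && truth$true_omega[i] > 1 &&
                 roles[i] == "ortholog") 0.8 else 0.1
    if (runif(1) < p_enr) gos <- c(enriched_go, gos)
    go_ids[i] <- paste(unique(gos), collapse = ",")
  }
  truth$go_ids <- go_ids

  # per-species expression abundances; planted stress induction
  base <- runif(n_pairs, 0.5, 2)
  truth$abund_control_a <- base
  truth$abund_control_b <- base
  truth$abund_stress_a <- base
  truth$abund_stress_b <- base
  if (n_orthologs > 0) {
    is_ortho <- which(roles == "ortholog")
    n_ub <- floor(up_both_frac * length(is_ortho))
    n_ua <- floor(up_a_frac * length(is_ortho))
    n_ubo <- floor(up_b_frac * length(is_ortho))
    picks <- sample(is_ortho, min(length(is_ortho), n_ub + n_ua + n_ubo))
    up_both <- picks[seq_len(n_ub)]
    up_a <- picks[n_ub + seq_len(n_ua)]
    up_b <- picks[n_ub + n_ua + seq_len(n_ubo)]
    truth$abund_stress_a[c(up_both, up_a)] <-
      truth$abund_control_a[c(up_both, up_a)] * stress_fold
    truth$abund_stress_b[c(up_both, up_b)] <-
      truth$abund_control_b[c(up_both, up_b)] * stress_fold
    truth$planted_regulation <- "none"
    truth$planted_regulation[up_both] <- "up_both"
    truth$planted_regulation[up_a] <- "up_a_only"
    truth$planted_regulation[up_b] <- "up_b_only"
  } else {
    truth$planted_regulation <- character(n_pairs)
  }

  anno <- data.frame(gene_id = character(0), go_id = character(0),
                     stringsAsFactors = FALSE)
  if (n_pairs > 0) {
    has_go <- which(nzchar(truth$go_ids))
    if (length(has_go) > 0) {
      anno <- do.call(rbind, lapply(has_go, function(i) {
        data.frame(gene_id = truth$id_a[i],
                   go_id = strsplit(truth$go_ids[i], ",")[[1]],
                   stringsAsFactors = FALSE)
      }))
    }
  }

  list(
    fasta_a = data.frame(id = truth$id_a, seq = seq_a,
                         stringsAsFactors = FALSE),
    fasta_b = data.frame(id = truth$id_b, seq = seq_b,
                         stringsAsFactors = FALSE),
    annotations = anno,
    truth = truth
  )
}

#' Write a fixture to disk (FASTA x2, annotation TSV, truth TSV)
#'
#' @param fixture result of [generate_transcriptome_fixture()]
#' @param dir output directory (created if needed)
#' @return named character vector of the four file paths
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta_a = file.path(dir, "species_a.fasta"),
    fasta_b = file.path(dir, "species_b.fasta"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  if (nrow(fixture$fasta_a) > 0) write_fasta(fixture$fasta_a, paths["fasta_a"])
  else writeLines(character(0), paths["fasta_a"])
  if (nrow(fixture$fasta_b) > 0) write_fasta(fixture$fasta_b, paths["fasta_b"])
  else writeLines(character(0), paths["fasta_b"])
  write.table(fixture$annotations, paths["annotations"], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(fixture$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

#' Simulate expression reads from a fixture
#'
#' Reads are drawn gene-proportionally to `abundance x gene length` for
#' the requested species and condition, with uniform start positions on
#' either strand, substitution errors at `error_rate`, and Phred
#' qualities `qual_hi` except `qual_err` at planted error positions.
#'
#' @param fixture result of [generate_transcriptome_fixture()]
#' @param species `"a"` or `"b"`
#' @param condition `"control"` or `"stress"`
#' @param n_reads number of reads to draw
#' @param read_len read length; must not exceed the shortest gene
#' @param error_rate per-base substitution error probability
#' @param seed integer seed (required)
#' @param qual_hi,qual_err Phred scores for correct/error positions
#' @return read data frame (`id`, `seq`, `qual`) suitable for
#'   [write_fastq()]
#' @export
generate_reads <- function(fixture, species = c("a", "b"),
                           condition = c("control", "stress"),
                           n_reads, read_len = 75, error_rate = 0.01,
                           seed, qual_hi = 40L, qual_err = 10L) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  species <- match.arg(species)
  condition <- match.arg(condition)
  genes <- if (species == "a") fixture$fasta_a else fixture$fasta_b
  if (nrow(genes) == 0) stop("fixture has no genes for species ", species)
  lens <- nchar(genes$seq)
  if (read_len > min(lens)) {
    stop("read_len (", read_len, ") exceeds the shortest gene (",
         min(lens), " nt)")
  }
  abcol <- paste0("abund_", condition, "_", species)
  ab <- fixture$truth[[abcol]]
  set.seed(as.integer(seed))
  w <- ab * lens
  src <- sample.int(nrow(genes), n_reads, replace = TRUE, prob = w)
  starts <- floor(runif(n_reads) * (lens[src] - read_len + 1)) + 1
  fwd <- runif(n_reads) < 0.5
  seqs <- substring(genes$seq[src], starts, starts + read_len - 1)
  seqs[!fwd] <- vapply(seqs[!fwd], revcomp, character(1), USE.NAMES = FALSE)
  n_err <- rbinom(n_reads, read_len, error_rate)
  qual <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    q <- rep(as.integer(qual_hi), read_len)
    if (n_err[i] > 0) {
      pos <- sample.int(read_len, n_err[i])
      s <- strsplit(seqs[i], "")[[1]]
      for (p in pos) s[p] <- sample(setdiff(NUCS, s[p]), 1)
      seqs[i] <- paste(s, collapse = "")
      q[pos] <- as.integer(qual_err)
    }
    qual[[i]] <- q
  }
  data.frame(
    id = sprintf("read_%s_%s_%07d", species, condition, seq_len(n_reads)),
    seq = unname(seqs), qual = I(qual), stringsAsFactors = FALSE
  )
}
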