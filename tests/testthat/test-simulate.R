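# Codon-pair simulator and fixture/read generators.

test_that("codon tables match direct enumeration of the genetic code", {
  expect_equal(ng86_syn_sites("TTT"), 1 / 3)
  ours <- ng86_syn_sites(oracle_sense)
  theirs <- vapply(oracle_sense, oracle_syn_sites, numeric(1))
  expect_equal(ours, unname(theirs))
})

test_that("zero branch length returns identical sequences", {
  p <- codon_model_params(kappa = 2, omega = 0.5)
  sim <- simulate_codon_pair(100, p, t = 0, seed = 42)
  expect_identical(sim$seq_a, sim$seq_b)
  expect_equal(nchar(sim$seq_a), 300)
  expect_equal(sum(sim$counts), 0)
})

test_that("omega = 0 forbids nonsynonymous change", {
  p <- codon_model_params(kappa = 2, omega = 0)
  sim <- simulate_codon_pair(500, p, t = 0.5, seed = 7)
  expect_equal(sim$counts[["nonsyn_ts"]] + sim$counts[["nonsyn_tv"]], 0)
  expect_identical(translate_cds(sim$seq_a), translate_cds(sim$seq_b))

  # at small t, codons are hit at most once, so NG86 counts the same
  # synonymous-only picture: Nd = 0 and Ka = 0 exactly
  checked <- 0
  for (seed in 1:6) {
    small <- simulate_codon_pair(100, codon_model_params(kappa = 1,
                                                         omega = 0),
                                 t = 0.02, seed = seed)
    if (any(small$events_per_codon > 1)) next
    r <- ng86(codon_alignment_from_cds(small$seq_a, small$seq_b))
    expect_equal(r$Nd, 0)
    expect_equal(r$Ka, 0)
    checked <- checked + 1
  }
  expect_gt(checked, 2)
})

test_that("simulator output is stop-free, length-correct, seed-stable", {
  p <- codon_model_params()
  s1 <- simulate_codon_pair(80, p, t = 0.3, seed = 11)
  s2 <- simulate_codon_pair(80, p, t = 0.3, seed = 11)
  expect_identical(s1, s2)
  for (s in c(s1$seq_a, s1$seq_b)) {
    expect_equal(nchar(s), 240)
    expect_false(any(split_codons(s) %in% c("TAA", "TAG", "TGA")))
  }
  expect_error(simulate_codon_pair(0, p, t = 0.1, seed = 1), "n_codons")
  expect_error(simulate_codon_pair(10, p, t = -1, seed = 1), "t must")
  expect_error(simulate_codon_pair(10, p, t = 0.1), "seed")
})

test_that("realized counts equal the Hamming decomposition when no codon
          is hit twice", {
  p <- codon_model_params(kappa = 2, omega = 0.5)
  checked <- 0
  for (seed in 1:10) {
    sim <- simulate_codon_pair(150, p, t = 0.02, seed = seed)
    if (any(sim$events_per_codon > 1)) next
    cod_a <- split_codons(sim$seq_a)
    cod_b <- split_codons(sim$seq_b)
    diff <- which(cod_a != cod_b)
    syn <- sum(oracle_code[cod_a[diff]] == oracle_code[cod_b[diff]])
    expect_equal(sim$counts[["syn_ts"]] + sim$counts[["syn_tv"]], syn)
    expect_equal(sim$counts[["nonsyn_ts"]] + sim$counts[["nonsyn_tv"]],
                 length(diff) - syn)
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("neutral symmetric process realizes the enumerated synonymous
          flux share", {
  p <- codon_model_params(kappa = 1, omega = 1)
  syn <- 0; tot <- 0
  for (seed in 1:15) {
    sim <- simulate_codon_pair(400, p, t = 2, seed = 100 + seed)
    syn <- syn + sim$counts[["syn_ts"]] + sim$counts[["syn_tv"]]
    tot <- tot + sum(sim$counts)
  }
  expect_gt(tot, 1e4)
  share <- oracle_syn_flux_share()
  # binomial 4-sigma band around the enumerated expectation
  expect_lt(abs(syn / tot - share), 4 * sqrt(share * (1 - share) / tot))
})

test_that("fixture bookkeeping reflects requested roles and omegas", {
  fx <- generate_transcriptome_fixture(n_orthologs = 10,
                                       omega_grid = c(0.2), seed = 5)
  expect_equal(nrow(fx$truth), 10)
  expect_equal(fx$truth$true_omega, rep(0.2, 10))
  expect_equal(fx$truth$role, rep("ortholog", 10))
  expect_equal(fx$fasta_a$id, fx$truth$id_a)

  fx0 <- generate_transcriptome_fixture(0, 0, 0, omega_grid = c(0.2),
                                        seed = 5)
  expect_equal(nrow(fx0$truth), 0)
  expect_equal(nrow(fx0$fasta_a), 0)

  # planted stop contaminants carry an in-frame internal stop
  fxs <- generate_transcriptome_fixture(2, n_contaminants = 3,
                                        omega_grid = c(0.2), seed = 9)
  cont <- fxs$truth$role == "stop_contaminant"
  for (s in fxs$fasta_b$seq[cont]) {
    cods <- split_codons(s)
    expect_true(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("reads are exact substrings at zero error rate and follow
          planted abundances", {
  cds <- vapply(c(301, 302), function(s) random_cds(100, s), character(1))
  fx <- toy_fixture(cds, abund_control = c(1, 3), abund_stress = c(1, 3))
  reads <- generate_reads(fx, "a", "control", n_reads = 40000,
                          read_len = 50, error_rate = 0, seed = 33)
  hits <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads$seq[i]
    hit2 <- grepl(r, cds[2], fixed = TRUE) ||
      grepl(revcomp(r), cds[2], fixed = TRUE)
    hit1 <- grepl(r, cds[1], fixed = TRUE) ||
      grepl(revcomp(r), cds[1], fixed = TRUE)
    c(hit1, hit2)
  }, logical(2))
  expect_true(all(hits[1, ] | hits[2, ]))
  n2 <- sum(hits[2, ] & !hits[1, ])
  # abundance 1:3 at equal length -> binomial(40000, 0.75), 3-sigma band
  expect_lt(abs(n2 - 30000), 3 * sqrt(40000 * 0.75 * 0.25) + 50)

  expect_error(generate_reads(fx, "a", "control", n_reads = 10,
                              read_len = 400, seed = 1), "read_len")
})

test_that("read generation is byte-deterministic under a fixed seed", {
  cds <- vapply(c(311, 312), function(s) random_cds(80, s), character(1))
  fx <- toy_fixture(cds, c(1, 1), c(1, 1))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(generate_reads(fx, "a", "stress", 500, read_len = 40,
                             seed = 77), f1)
  write_fastq(generate_reads(fx, "a", "stress", 500, read_len = 40,
                             seed = 77), f2)
  expect_identical(readLines(f1), readLines(f2))
})
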