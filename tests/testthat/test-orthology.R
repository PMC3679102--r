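# ORF extraction, protein alignment, BBH and the paralog filters.

test_that("longest ATG-initiated ORF is found on either strand", {
  u <- list(id = "u1", seq = "AAATGGCTGCTTAAAA")
  cds <- extract_cds(u, min_orf_nt = 9)
  expect_equal(cds$nt, "ATGGCTGCT")
  expect_equal(cds$protein, "MAA")
  expect_equal(cds$span$strand, "+")
  expect_equal(c(cds$span$start, cds$span$end), c(2, 11))

  # reverse complement: same protein, minus strand recorded
  u2 <- list(id = "u2", seq = revcomp(u$seq))
  cds2 <- extract_cds(u2, min_orf_nt = 9)
  expect_equal(cds2$protein, "MAA")
  expect_equal(cds2$span$strand, "-")

  # no start codon -> no ORF
  expect_null(extract_cds(list(id = "u3", seq = "AAACCCGGGTTT"),
                          min_orf_nt = 9))
  # below the length floor -> no ORF
  expect_null(extract_cds(u, min_orf_nt = 150))
  expect_error(extract_cds(list(id = "u4", seq = "AXGT"), min_orf_nt = 9),
               "u4")
})

test_that("extracted ORFs never contain internal stops and respect the
          span coordinates", {
  set.seed(88)
  for (i in 1:20) {
    nt <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
    cds <- extract_cds(list(id = "x", seq = nt), min_orf_nt = 30)
    if (is.null(cds)) next
    expect_false(grepl("\\*", cds$protein))
    expect_equal(nchar(cds$nt), 3 * nchar(cds$protein))
    parent <- if (cds$span$strand == "+") nt else revcomp(nt)
    sub <- if (cds$span$strand == "+") {
      substring(nt, cds$span$start + 1, cds$span$end)
    } else {
      revcomp(substring(nt, cds$span$start + 1, cds$span$end))
    }
    expect_equal(sub, cds$nt)
  }
})

test_that("protein alignment scores match BLOSUM62 arithmetic", {
  a <- align_proteins("MAA", "MAA", mode = "local")
  expect_equal(a$score, 13)  # M:5 + A:4 + A:4
  expect_equal(a$overlap_nt, 9)
  expect_equal(a$coverage_a, 1)
  expect_error(align_proteins("A", ""), "empty")

  # local dominates global for any pair
  p <- translate_cds(random_cds(50, 21))
  q <- translate_cds(random_cds(50, 22))
  expect_gte(align_proteins(p, q, mode = "local")$score,
             align_proteins(p, q, mode = "global")$score)
})

test_that("BBH is reciprocal, symmetric and deterministic under ties", {
  nt <- random_cds(60, 31)
  one_a <- as_cds_set(data.frame(id = "a1", seq = nt), species = "a")
  one_b <- as_cds_set(data.frame(id = "b1", seq = nt), species = "b")
  pairs <- find_bbh(one_a, one_b)
  expect_equal(pairs$id_a, "a1")
  expect_equal(pairs$id_b, "b1")

  # an identical copy in B: tie broken lexicographically
  two_b <- as_cds_set(data.frame(id = c("b1", "b1_copy"), seq = c(nt, nt)),
                      species = "b")
  pairs2 <- find_bbh(one_a, two_b)
  expect_equal(pairs2$id_b, "b1")

  # symmetry on a mixed set
  fx <- generate_transcriptome_fixture(8, omega_grid = c(0.2, 2),
                                       seed = 17)
  ca <- as_cds_set(fx$fasta_a, "a")
  cb <- as_cds_set(fx$fasta_b, "b")
  ab <- find_bbh(ca, cb)
  ba <- find_bbh(cb, ca)
  expect_setequal(paste(ab$id_a, ab$id_b), paste(ba$id_b, ba$id_a))
  # each CDS appears in at most one pair
  expect_false(any(duplicated(ab$id_a)))
  expect_false(any(duplicated(ab$id_b)))
})

test_that("lower-scoring paralog decoys never enter the BBH set", {
  p <- codon_model_params(kappa = 2, omega = 0.3)
  sim <- simulate_codon_pair(150, p, t = 0.05, seed = 41)
  # decoy: a deeply diverged duplicate of the true partner
  decoy <- simulate_codon_pair(150, p, t = 1.5, seed = 42)
  ca <- as_cds_set(data.frame(id = "a1", seq = sim$seq_a), "a")
  cb <- as_cds_set(data.frame(id = c("b1", "b1_decoy"),
                              seq = c(sim$seq_b, decoy$seq_b)), "b")
  pairs <- find_bbh(ca, cb)
  expect_equal(pairs$id_b, "b1")
})

test_that("overlap, coverage and stop filters apply the declared
          boundaries", {
  nt <- random_cds(100, 51)
  stub_aln <- codon_alignment_from_cds(nt, nt)
  mk_pairs <- function(overlap, cov_a, cov_b) {
    data.frame(id_a = "a", id_b = "b", score = 500, overlap_nt = overlap,
               coverage_a = cov_a, coverage_b = cov_b,
               stringsAsFactors = FALSE)
  }
  # overlap 150 excluded (rule is strictly > 150), 151 retained
  f150 <- filter_ortholog_pairs(mk_pairs(150, 1, 1), list(stub_aln))
  expect_equal(f150$excluded$reasons, "overlap")
  f151 <- filter_ortholog_pairs(mk_pairs(151, 1, 1), list(stub_aln))
  expect_equal(nrow(f151$retained), 1)

  # coverage boundary: 0.90 inclusive retained; either side may fail
  fcov <- filter_ortholog_pairs(mk_pairs(300, 0.89, 0.95), list(stub_aln))
  expect_equal(fcov$excluded$reasons, "coverage")
  fcov2 <- filter_ortholog_pairs(mk_pairs(300, 0.9, 0.9), list(stub_aln))
  expect_equal(nrow(fcov2$retained), 1)

  # a mid-frame TAA flags stop_or_ambiguous
  with_stop <- paste0(substring(nt, 1, 30), "TAA", substring(nt, 34))
  aln_stop <- codon_alignment_from_cds(nt, with_stop)
  fstop <- filter_ortholog_pairs(mk_pairs(300, 1, 1), list(aln_stop))
  expect_equal(fstop$excluded$reasons, "stop_or_ambiguous")

  # excessive gap columns flag ambiguity
  gappy <- structure(list(
    pair_id = "g", codons_a = c("ATG", "---", "---", "GCT"),
    codons_b = c("ATG", "AAA", "CCC", "GCT"), gapless_len_nt = 6L
  ), class = "codon_alignment")
  fgap <- filter_ortholog_pairs(mk_pairs(300, 1, 1), list(gappy),
                                max_gap_col_frac = 0.2)
  expect_equal(fgap$excluded$reasons, "stop_or_ambiguous")
})
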