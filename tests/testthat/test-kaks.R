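# Codon alignment, NG86 / YN00 estimation, validity test, Ks filter and
# classification.

test_that("protein-guided codon alignment places whole-codon gaps", {
  # M-A vs MKA: the K column becomes a codon gap in a
  ca <- codon_align("ATGGCT", "ATGAAAGCT")
  expect_equal(ca$codons_a, c("ATG", "---", "GCT"))
  expect_equal(ca$codons_b, c("ATG", "AAA", "GCT"))
  expect_equal(ca$gapless_len_nt, 6L)

  # identical CDSs align gap-free
  nt <- random_cds(40, 61)
  ca2 <- codon_align(nt, nt)
  expect_equal(ca2$gapless_len_nt, nchar(nt))
  expect_false(any(ca2$codons_a == "---"))

  # column count times 3 covers the longer sequence
  a <- random_cds(30, 62)
  b <- paste0(substring(a, 1, 45), "AAATTTGGG", substring(a, 46))
  ca3 <- codon_align(a, b)
  expect_gte(3 * length(ca3$codons_a), max(nchar(a), nchar(b)))

  # internal stops are rejected unless explicitly tolerated
  with_stop <- paste0("ATGTAA", substring(a, 7))
  expect_error(codon_align(with_stop, a), "stop")
  expect_s3_class(codon_align(with_stop, a, check_stops = FALSE),
                  "codon_alignment")
})

test_that("identical sequences give zero rates and incalculable category", {
  nt <- random_cds(50, 63)
  aln <- codon_alignment_from_cds(nt, nt)
  for (est in list(ng86, yn00)) {
    r <- est(aln)
    expect_equal(r$Sd, 0)
    expect_equal(r$Nd, 0)
    expect_equal(r$Ka, 0)
    expect_equal(r$Ks, 0)
    expect_true(is.na(r$ratio))
    expect_equal(r$category, "incalculable")
    expect_equal(r$p_fisher, 1)
  }
})

test_that("NG86 site counts match enumeration and sites are conserved", {
  nt <- random_cds(200, 64)
  mut <- simulate_codon_pair(200, codon_model_params(), t = 0.15,
                             seed = 65)
  aln <- codon_alignment_from_cds(mut$seq_a, mut$seq_b)
  r <- ng86(aln)
  # S of each sequence by direct enumeration
  s_a <- sum(vapply(split_codons(mut$seq_a), oracle_syn_sites, numeric(1)))
  s_b <- sum(vapply(split_codons(mut$seq_b), oracle_syn_sites, numeric(1)))
  expect_equal(r$S, (s_a + s_b) / 2, tolerance = 1e-12)
  expect_equal(r$S + r$N, r$gapless_len_nt, tolerance = 1e-6)
  y <- yn00(aln)
  expect_equal(y$S + y$N, y$gapless_len_nt, tolerance = 1e-6)
})

test_that("single-codon differences are classified directly", {
  # TTT -> TTC is synonymous (Phe); TTT -> TTG is not (Phe -> Leu)
  base <- random_cds(30, 66)
  syn <- paste0(substring(base, 1, 87), "TTT")
  syn2 <- paste0(substring(base, 1, 87), "TTC")
  non <- paste0(substring(base, 1, 87), "TTG")
  rs <- ng86(codon_alignment_from_cds(syn, syn2))
  expect_equal(rs$Sd, 1)
  expect_equal(rs$Nd, 0)
  rn <- ng86(codon_alignment_from_cds(syn, non))
  expect_equal(rn$Sd, 0)
  expect_equal(rn$Nd, 1)
})

test_that("YN00 reduces to NG86 sites in the kappa=1 uniform limit and
          tracks the transition bias otherwise", {
  sim <- simulate_codon_pair(500, codon_model_params(kappa = 1, omega = 1),
                             t = 0.1, seed = 67)
  aln <- codon_alignment_from_cds(sim$seq_a, sim$seq_b)
  y <- yn00(aln)
  n <- ng86(aln)
  expect_lt(abs(y$S - n$S) / n$S, 0.05)

  sim2 <- simulate_codon_pair(500, codon_model_params(kappa = 4,
                                                      omega = 0.5),
                              t = 0.2, seed = 68)
  y2 <- yn00(codon_alignment_from_cds(sim2$seq_a, sim2$seq_b))
  expect_gt(y2$kappa, 1.5)  # strong transition bias must be detected
})

test_that("Fisher validity test matches hypergeometric enumeration", {
  # one-sided p for [[3,1],[1,3]] is 17/70; fisher_validity is two-sided
  expect_equal(oracle_fisher_greater(3, 1, 1, 3), 17 / 70)
  expect_equal(fisher_validity(4, 4, 3, 1),
               fisher.test(rbind(c(3, 1), c(1, 3)))$p.value)
  expect_equal(fisher_validity(10, 20, 0, 0), 1)
  # row-swap symmetry
  expect_equal(fisher_validity(12, 30, 4, 6), fisher_validity(30, 12, 6, 4))
  expect_error(fisher_validity(3, 3, 4, 1), "exceed")
})

test_that("the Ks filter excludes strictly above 0.1 and keeps
          undefined Ks", {
  mk <- function(ks) list(pair_id = "p", Ka = 0.01, Ks = ks,
                          ratio = NA_real_)
  out <- apply_ks_filter(list(mk(0.12), mk(0.10), mk(NA_real_)))
  expect_equal(length(out$excluded), 1)
  expect_equal(out$excluded[[1]]$Ks, 0.12)
  expect_equal(length(out$retained), 2)
})

test_that("selection categories follow the ratio bands", {
  mk <- function(ka, ks) {
    ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
    list(Ka = ka, Ks = ks, ratio = ratio)
  }
  expect_equal(classify_pair(mk(0.02, 0.01)), "positive")
  expect_equal(classify_pair(mk(0.007, 0.01)), "weak_purifying")
  expect_equal(classify_pair(mk(0.01, 0.01)), "weak_purifying") # ratio 1
  expect_equal(classify_pair(mk(0.004, 0.01)), "purifying")
  expect_equal(classify_pair(mk(0.01, NA_real_)), "ka_only")
  expect_equal(classify_pair(mk(0.01, 0)), "ka_only")
  expect_equal(classify_pair(mk(NA_real_, 0.01)), "ks_only")
  expect_equal(classify_pair(mk(0, 0.01)), "ks_only")
  expect_equal(classify_pair(mk(NA_real_, NA_real_)), "incalculable")
})

test_that("pair statistics count GC and gapless length per convention", {
  all_gc <- strrep("GGC", 10)
  expect_equal(pair_stats(codon_alignment_from_cds(all_gc, all_gc))$gc, 1)
  st <- pair_stats(codon_alignment_from_cds("ATG", "ATG"))
  expect_equal(st$gc, 1 / 3)
  # gapped example: only columns ungapped in both count
  ca <- codon_align("ATGGCT", "ATGAAAGCT")
  expect_equal(pair_stats(ca)$gapless_len_nt, 6L)
})

test_that("estimators agree on the side of neutrality away from
          omega = 1", {
  agree <- 0
  total <- 0
  for (om in c(0.2, 2)) {
    tab_ng <- simulate_kaks_replicates(om, 40, n_codons = 300, t = 0.1,
                                       seed = 500 + om * 10, method = "ng")
    tab_yn <- simulate_kaks_replicates(om, 40, n_codons = 300, t = 0.1,
                                       seed = 500 + om * 10, method = "yn")
    ok <- !is.na(tab_ng$ratio) & !is.na(tab_yn$ratio)
    agree <- agree + sum(sign(tab_ng$ratio[ok] - 1) ==
                           sign(tab_yn$ratio[ok] - 1))
    total <- total + sum(ok)
  }
  expect_gte(agree / total, 0.95)
})
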