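# Read mapping, RPKM and regulation/concordance classification.

test_that("RPKM follows the definition and its scaling laws", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(7, 500, 2e6), rpkm(7, 500, 1e6) / 2)
  # duplicating the library leaves RPKM unchanged
  expect_equal(rpkm(20, 800, 2e6), rpkm(10, 800, 1e6))
  expect_error(rpkm(1, 0, 1e6), "gene_length")
  expect_error(rpkm(1, 100, 0), "total_mapped")
})

test_that("error-free reads map uniquely back to their source genes", {
  cds <- vapply(c(701, 702, 703), function(s) random_cds(120, s),
                character(1))
  fx <- toy_fixture(cds, c(1, 1, 1), c(1, 1, 1))
  reads <- generate_reads(fx, "a", "control", n_reads = 3000,
                          read_len = 60, error_rate = 0, seed = 71)
  mp <- map_reads(reads, fx$fasta_a)
  expect_equal(mp$total_mapped, 3000)
  expect_equal(mp$n_ambiguous, 0)
  expect_equal(mp$n_unassigned, 0)
  expect_equal(mp$total_mapped + mp$n_ambiguous + mp$n_unassigned,
               nrow(reads))
})

test_that("mismatch cap and ambiguity rules are enforced", {
  gene <- random_cds(80, 72)
  genes <- data.frame(id = "g1", seq = gene, stringsAsFactors = FALSE)
  read <- substring(gene, 31, 90)
  flip <- function(s, pos) {
    x <- strsplit(s, "")[[1]]
    x[pos] <- setdiff(c("A", "C", "G", "T"), x[pos])[1]
    paste(x, collapse = "")
  }
  r3 <- flip(flip(flip(read, 5), 20), 40)
  r4 <- flip(r3, 55)
  reads <- data.frame(id = c("ok", "far"), seq = c(r3, r4),
                      stringsAsFactors = FALSE)
  mp <- map_reads(reads, genes, max_mismatch = 3)
  expect_equal(unname(mp$counts["g1"]), 1)
  expect_equal(mp$n_unassigned, 1)

  # a read present in two genes is ambiguous and discarded
  genes2 <- data.frame(id = c("g1", "g2"),
                       seq = c(gene, paste0(random_cds(20, 73),
                                            substring(gene, 1, 120))),
                       stringsAsFactors = FALSE)
  reads2 <- data.frame(id = "amb", seq = substring(gene, 1, 60),
                       stringsAsFactors = FALSE)
  mp2 <- map_reads(reads2, genes2)
  expect_equal(mp2$n_ambiguous, 1)
  expect_equal(mp2$total_mapped, 0)
})

test_that("regulation calls apply the log2 threshold symmetrically", {
  up <- classify_regulation(10, 20.5, pseudo = 0.1)
  expect_equal(up$reg_class, "up")
  same <- classify_regulation(15, 15)
  expect_equal(same$log2_ratio, 0)
  expect_equal(same$reg_class, "unchanged")
  down <- classify_regulation(20.5, 10)
  expect_equal(down$reg_class, "down")
  expect_equal(down$log2_ratio, -up$log2_ratio)
  expect_error(classify_regulation(1, 1, log2_threshold = 0), "> 0")
})

test_that("concordance combines the two species' calls", {
  recs <- data.frame(
    pair_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    species = rep(c("a", "b"), 4),
    reg_class = c("up", "up", "up", "unchanged", "unchanged", "up",
                  "down", "down"),
    stringsAsFactors = FALSE
  )
  cc <- concordance(recs)
  expect_equal(cc$call,
               c("up_both", "up_species_a_only", "up_species_b_only",
                 "other"))
  expect_error(concordance(recs[-1, ]), "p1")
})

test_that("planted stress induction is recovered through mapping and
          RPKM", {
  cds <- vapply(c(711, 712, 713, 714), function(s) random_cds(150, s),
                character(1))
  fx <- toy_fixture(cds, abund_control = c(1, 1, 1, 1),
                    abund_stress = c(4, 1, 1, 1))
  rc <- generate_reads(fx, "a", "control", 8000, read_len = 60, seed = 74)
  rs <- generate_reads(fx, "a", "stress", 8000, read_len = 60, seed = 75)
  ex <- expression_records(fx$fasta_a, rc, rs, species = "a")
  expect_equal(ex$reg_class[ex$gene_id == "g01"], "up")
  expect_true(all(ex$reg_class[ex$gene_id != "g01"] == "unchanged"))
})
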