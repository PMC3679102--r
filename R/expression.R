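# Mismatch-limited read assignment, RPKM, and salt-stress regulation /
# concordance classification.

#' Assign reads to genes by minimum Hamming distance
#'
#' Each read is placed at the gene and offset with the fewest mismatches
#' (both strands searched, no indels). Reads whose best placement
#' exceeds `max_mismatch` are unassigned; reads equally close to more
#' than one gene are discarded as ambiguous.
#'
#' @param reads read data frame (`id`, `seq`)
#' @param genes sequence-record data frame (`id`, `seq`)
#' @param max_mismatch maximum tolerated mismatches (default 3)
#' @return list with `counts` (named per-gene read counts),
#'   `total_mapped`, `n_ambiguous`, `n_unassigned`
#' @export
map_reads <- function(reads, genes, max_mismatch = 3) {
  genes_rc <- vapply(genes$seq, revcomp, character(1), USE.NAMES = FALSE)
  assign <- .map_reads_cpp(reads$seq, genes$seq, genes_rc,
                           as.integer(max_mismatch))
  counts <- tabulate(assign[assign > 0], nbins = nrow(genes))
  names(counts) <- genes$id
  list(
    counts = counts,
    total_mapped = sum(counts),
    n_ambiguous = sum(assign == -1),
    n_unassigned = sum(assign == 0)
  )
}

#' Reads per kilobase per million mapped reads
#'
#' @param count reads assigned to the gene
#' @param gene_length_nt gene length in nucleotides (> 0)
#' @param total_mapped total mapped reads in the library (> 0)
#' @return `1e9 * count / (gene_length_nt * total_mapped)`
#' @export
rpkm <- function(count, gene_length_nt, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(gene_length_nt <= 0)) stop("gene_length_nt must be > 0")
  1e9 * count / (gene_length_nt * total_mapped)
}

#' Classify stress regulation from a pair of RPKM values
#'
#' @param rpkm_control,rpkm_stress RPKM under the two conditions
#' @param log2_threshold regulation calls require
#'   `|log2 ratio| >= log2_threshold` (default 1, i.e. two-fold)
#' @param pseudo pseudo-count added to both RPKMs before the ratio
#' @return data frame with `log2_ratio` and `reg_class` (`up`, `down`,
#'   `unchanged`)
#' @export
classify_regulation <- function(rpkm_control, rpkm_stress,
                                log2_threshold = 1, pseudo = 0.1) {
  if (log2_threshold <= 0 || pseudo <= 0) stop("thresholds must be > 0")
  lr <- log2((rpkm_stress + pseudo) / (rpkm_control + pseudo))
  cls <- ifelse(lr >= log2_threshold, "up",
                ifelse(lr <= -log2_threshold, "down", "unchanged"))
  data.frame(log2_ratio = lr, reg_class = cls, stringsAsFactors = FALSE)
}

#' Cross-species concordance of stress regulation
#'
#' Combines the two species' regulation calls per ortholog pair:
#' `up_both` when both are up-regulated, `up_species_a_only` /
#' `up_species_b_only` when exactly one is, `other` otherwise.
#'
#' @param records expression record data frame with columns `pair_id`,
#'   `species` (values `"a"`/`"b"`) and `reg_class`
#' @return data frame with `pair_id` and `call`
#' @export
concordance <- function(records) {
  pairs <- unique(records$pair_id)
  calls <- vapply(pairs, function(p) {
    sub <- records[records$pair_id == p, ]
    ra <- sub$reg_class[sub$species == "a"]
    rb <- sub$reg_class[sub$species == "b"]
    if (length(ra) != 1 || length(rb) != 1) {
      stop("pair ", p, " lacks a record for one species")
    }
    if (ra == "up" && rb == "up") "up_both"
    else if (ra == "up") "up_species_a_only"
    else if (rb == "up") "up_species_b_only"
    else "other"
  }, character(1))
  data.frame(pair_id = pairs, call = unname(calls),
             stringsAsFactors = FALSE)
}

#' Per-pair expression records from control/stress read sets
#'
#' Maps both condition libraries against one species' gene set and
#' produces one expression record per gene with RPKM values and the
#' regulation call.
#'
#' @param genes sequence-record data frame for one species
#' @param reads_control,reads_stress read data frames
#' @param species species label stored in the records
#' @param max_mismatch mapping mismatch cap
#' @param log2_threshold,pseudo regulation-call parameters
#' @return data frame in the `expression` results-table schema, plus a
#'   `gene_id` column
#' @export
expression_records <- function(genes, reads_control, reads_stress,
                               species, max_mismatch = 3,
                               log2_threshold = 1, pseudo = 0.1) {
  mc <- map_reads(reads_control, genes, max_mismatch)
  ms <- map_reads(reads_stress, genes, max_mismatch)
  lens <- nchar(genes$seq)
  rc <- rpkm(mc$counts, lens, max(mc$total_mapped, 1))
  rs <- rpkm(ms$counts, lens, max(ms$total_mapped, 1))
  reg <- classify_regulation(rc, rs, log2_threshold, pseudo)
  data.frame(
    pair_id = genes$id, gene_id = genes$id, species = species,
    rpkm_control = unname(rc), rpkm_stress = unname(rs),
    log2_ratio = reg$log2_ratio, reg_class = reg$reg_class,
    stringsAsFactors = FALSE
  )
}
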