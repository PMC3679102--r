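# GO-category enrichment of positively selected genes against the
# ortholog background: one-sided Fisher exact test on the 2x2 table of
# category membership vs PSG membership.

#' GO category enrichment of positively selected genes
#'
#' For each category with at least one PSG member, builds the table
#' `a` (in category, PSG), `b` (in category, non-PSG), `c` (outside
#' category, PSG), `d` (outside category, non-PSG) over the background
#' set and computes a one-sided (over-representation) Fisher exact
#' p-value. No multiple-testing correction is applied by default; set
#' `adjust = TRUE` for a Benjamini-Hochberg column.
#'
#' @param annotations data frame with `gene_id`, `go_id` (as from
#'   [read_annotation()]); may cover only a subset of the background
#' @param psg_ids character vector of positively selected gene ids; must
#'   be a subset of `background_ids`
#' @param background_ids character vector defining the background set
#' @param alpha significance flag threshold (default 0.05)
#' @param report_all when `TRUE`, categories without PSG members are
#'   reported too (with p = 1 when `a` = 0 cannot be enriched)
#' @param adjust add a `p_adjusted` (Benjamini-Hochberg) column
#' @return data frame sorted by p-value then category id with columns
#'   `category_id`, `description`, `taxonomy`, `a`, `b`, `c`, `d`,
#'   `p_value`, `significant`
#' @export
go_enrichment <- function(annotations, psg_ids, background_ids,
                          alpha = 0.05, report_all = FALSE,
                          adjust = FALSE) {
  if (!all(psg_ids %in% background_ids)) {
    stop("psg_ids must be a subset of background_ids")
  }
  psg_ids <- unique(psg_ids)
  background_ids <- unique(background_ids)
  anno <- annotations[annotations$gene_id %in% background_ids, , drop = FALSE]
  cats <- sort(unique(anno$go_id))
  n_bg <- length(background_ids)
  n_psg <- length(psg_ids)
  rows <- lapply(cats, function(cat) {
    members <- unique(anno$gene_id[anno$go_id == cat])
    a <- sum(members %in% psg_ids)
    if (a == 0 && !report_all) return(NULL)
    b <- length(members) - a
    c_ <- n_psg - a
    d <- n_bg - n_psg - b
    p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(
      category_id = cat, description = NA_character_,
      taxonomy = NA_character_, a = a, b = b, c = c_, d = d,
      p_value = p, stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(
      category_id = character(0), description = character(0),
      taxonomy = character(0), a = integer(0), b = integer(0),
      c = integer(0), d = integer(0), p_value = numeric(0),
      significant = logical(0), stringsAsFactors = FALSE
    )
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$category_id), , drop = FALSE]
  rownames(out) <- NULL
  out$significant <- out$p_value <= alpha
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
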