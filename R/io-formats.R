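# Readers/writers for the external formats the pipeline touches.
#
# Sequence sets travel through the package as plain data frames with
# columns `id` and `seq` (plus a `qual` list column of integer Phred
# scores for reads). Parsing and serialisation are delegated to
# Biostrings; validation is done here.

.validate_ids <- function(ids, path) {
  if (any(!nzchar(ids)) || any(grepl("\\s", ids))) {
    stop("invalid record id (empty or containing whitespace) in ", path)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  invisible(TRUE)
}

.validate_alphabet <- function(seqs, ids, alphabet) {
  if (alphabet == "dna") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("non-nucleotide characters in record(s): ",
           paste(ids[bad], collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Read a FASTA file into a sequence-record data frame
#'
#' Sequences are upper-cased on read; duplicate ids and (for nucleotide
#' input) characters outside A,C,G,T,N are rejected.
#'
#' @param path path to a FASTA file
#' @param alphabet `"dna"` (default) restricts the alphabet to A,C,G,T,N;
#'   `"protein"` or `"any"` skip the alphabet check
#' @return data frame with columns `id`, `seq`, in file order
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein", "any")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  .validate_ids(ids, path)
  seqs <- toupper(as.character(x))
  .validate_alphabet(seqs, ids, alphabet)
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data frame with columns `id`, `seq`
#' @param path output path
#' @param width line-wrap width (default 60)
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, width = 60) {
  x <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a read data frame
#'
#' @param path path to a FASTQ file
#' @return data frame with columns `id`, `seq` and a list column `qual`
#'   of integer Phred scores
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty FASTQ file: ", path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  }
  idx <- seq(1, length(lines), by = 4)
  heads <- lines[idx]
  if (any(substring(heads, 1, 1) != "@")) {
    stop("malformed FASTQ header in ", path)
  }
  ids <- sub("\\s.*$", "", substring(heads, 2))
  seqs <- toupper(lines[idx + 1])
  quals <- lines[idx + 3]
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism)) {
    stop("sequence/quality length mismatch for read(s): ",
         paste(ids[mism], collapse = ", "))
  }
  .validate_ids(ids, path)
  .validate_alphabet(seqs, ids, "dna")
  qual <- lapply(quals, function(q) as.integer(utf8ToInt(q)) - 33L)
  data.frame(
    id = ids, seq = unname(seqs), qual = I(qual),
    stringsAsFactors = FALSE
  )
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param records data frame with columns `id`, `seq`, `qual`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(records, path) {
  qual_str <- vapply(records$qual, function(q) {
    intToUtf8(as.integer(q) + 33L)
  }, character(1))
  out <- character(4 * nrow(records))
  out[seq(1, length(out), 4)] <- paste0("@", records$id)
  out[seq(2, length(out), 4)] <- records$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- qual_str
  writeLines(out, path)
  invisible(path)
}

#' Read a two-column gene-to-GO annotation table
#'
#' Expects tab-separated lines `gene_id<TAB>GO:NNNNNNN`, one pair per
#' line, no header.
#'
#' @param path path to the annotation TSV
#' @return data frame with columns `gene_id`, `go_id`
#' @export
read_annotation <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("gene_id", "go_id"))
  bad <- !grepl("^GO:[0-9]{7}$", x$go_id)
  if (any(bad)) {
    stop("malformed GO id(s): ", paste(unique(x$go_id[bad]), collapse = ", "))
  }
  x
}

# fixed column orders per result schema
.result_schemas <- list(
  kaks = c("pair_id", "S", "N", "Sd", "Nd", "Ka", "Ks", "ratio", "kappa",
           "gc", "gapless_len_nt", "p_fisher", "category"),
  enrichment = c("category_id", "description", "taxonomy",
                 "a", "b", "c", "d", "p_value"),
  expression = c("pair_id", "species", "rpkm_control", "rpkm_stress",
                 "log2_ratio", "reg_class")
)

#' Write a results table with a fixed schema
#'
#' Tab-separated with a header row; columns in a deterministic order per
#' schema; floating-point values at 6 decimals; missing values as `NA`.
#'
#' @param records data frame carrying at least the schema's columns
#' @param path output path
#' @param schema one of `"kaks"`, `"enrichment"`, `"expression"`
#' @return `path`, invisibly
#' @export
write_results_table <- function(records, path,
                                schema = c("kaks", "enrichment", "expression")) {
  schema <- tryCatch(match.arg(schema),
                     error = function(e) stop("unknown schema: ", schema[1]))
  cols <- .result_schemas[[schema]]
  if (nrow(records) == 0) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                      cols))
  }
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- records[, cols, drop = FALSE]
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- out[[j]]
      out[[j]] <- ifelse(is.na(v), "NA",
                         formatC(v, format = "f", digits = 6))
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path path to the TSV
#' @param schema one of `"kaks"`, `"enrichment"`, `"expression"`
#' @return data frame with the schema's columns
#' @export
read_results_table <- function(path,
                               schema = c("kaks", "enrichment", "expression")) {
  schema <- tryCatch(match.arg(schema),
                     error = function(e) stop("unknown schema: ", schema[1]))
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  cols <- .result_schemas[[schema]]
  if (!identical(names(x), cols)) {
    stop("table at ", path, " does not match schema '", schema, "'")
  }
  x
}
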