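# Sequence and pair-table IO.
#
# Conventions used throughout the package:
#   * all sequences are uppercase RNA ({A,C,G,U}), T normalized to U on load;
#   * positions are 1-based, intervals closed [start, end];
#   * miRNA position 1 is the 5' base; the seed region is positions 1-8;
#   * only the given UTR strand is scanned (targets matched as written).

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and replaces T with U. Errors (with the 1-based offset of the
#' first offending character) if anything outside {A,C,G,U} remains.
#'
#' @param x character vector of sequences.
#' @param id optional identifiers used in error messages.
#' @return character vector of normalized RNA strings.
#' @export
normalize_rna <- function(x, id = NULL) {
  out <- chartr("Tt", "Uu", x)
  out <- toupper(out)
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    who <- if (!is.null(id)) paste0(" in record '", id[i], "'") else ""
    stop("non-ACGTU character", who, " at position ", bad[i],
         " (after T->U/case normalization)", call. = FALSE)
  }
  out
}

#' Read a multi-record FASTA file of miRNA or 3'UTR sequences
#'
#' Records are normalized to uppercase RNA. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @param kind `"mirna"` (mature miRNAs, length >= 15 enforced) or `"utr"`.
#' @return named character vector of RNA strings (names = record ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path, kind = c("mirna", "utr")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate record id in ", path, ": '", dup[1L], "'", call. = FALSE)
  }
  seqs <- normalize_rna(as.character(set), id = ids)
  if (kind == "mirna" && any(nchar(seqs) < 15L)) {
    short <- ids[nchar(seqs) < 15L][1L]
    stop("miRNA '", short, "' is shorter than 15 nt", call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of RNA strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a labeled miRNA-mRNA pair table
#'
#' Tab-separated, three or more columns: miRNA id, transcript (UTR) id,
#' label. Labels `1`/`+1` map to +1 (target) and `-1` to -1 (non-target);
#' anything else is an error citing the data row number.
#'
#' @param path path to the TSV file.
#' @param header `"auto"` (default; detected from whether row 1 column 3
#'   parses as a label), `TRUE` or `FALSE`.
#' @return data.frame with columns `mirna_id`, `utr_id`, `label` (integer
#'   +1/-1), in file order.
#' @export
read_pairs <- function(path, header = "auto") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  empty <- data.frame(mirna_id = character(), utr_id = character(),
                      label = integer(), stringsAsFactors = FALSE)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) return(empty)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           blank.lines.skip = TRUE, strip.white = TRUE)
  if (nrow(raw) == 0L) return(empty)
  if (ncol(raw) < 3L) stop("pair table needs >= 3 columns", call. = FALSE)
  is_label <- function(x) x %in% c("1", "+1", "-1")
  if (identical(header, "auto")) {
    # a header row has a non-numeric third field (e.g. "label"); a numeric
    # but invalid label like "2" is a data row and must error as one
    header <- suppressWarnings(is.na(as.numeric(raw[1L, 3L])))
  }
  if (isTRUE(header)) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) return(empty)
  lab_chr <- raw[[3L]]
  bad <- which(!is_label(lab_chr))
  if (length(bad)) {
    stop("invalid label '", lab_chr[bad[1L]], "' in pair row ", bad[1L],
         " (expected +1/1 or -1)", call. = FALSE)
  }
  data.frame(mirna_id = raw[[1L]], utr_id = raw[[2L]],
             label = ifelse(lab_chr == "-1", -1L, 1L),
             stringsAsFactors = FALSE)
}

#' Write a labeled pair table
#'
#' @param pairs data.frame with columns `mirna_id`, `utr_id`, `label`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("mirna_id", "utr_id", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Split a sequence into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
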