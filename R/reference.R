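## Concatenated in silico reference construction and the gene-interval map.

#' Build a concatenated in silico reference from gene sequences
#'
#' Concatenates a set of gene (e.g. UniGene consensus) sequences into a
#' single reference sequence, separating consecutive genes by a run of
#' `spacer_len` `N` characters so that read pairs cannot bridge two genes.
#' This mirrors the standard construction used when no genome assembly is
#' available and transcripts serve as the alignment target.
#'
#' @param genes a named character vector, a [Biostrings::DNAStringSet], or
#'   the path to a FASTA file of gene sequences.  Gene identifiers must be
#'   unique and sequences non-empty.
#' @param spacer_len integer, number of `N`s between consecutive genes
#'   (default 200).
#' @param ref_name name given to the concatenated sequence.
#' @return a list with elements
#'   * `reference`: [Biostrings::DNAStringSet] of length 1;
#'   * `intervals`: data.frame with columns `gene_id`, `start`, `end`,
#'     `length` (1-based inclusive coordinates on the reference).
#' @examples
#' ref <- build_insilico_reference(c(g1 = "ACGTACGT", g2 = "TTTT"),
#'                                 spacer_len = 5)
#' ref$intervals
#' @export
build_insilico_reference <- function(genes, spacer_len = 200L,
                                     ref_name = "insilico_ref") {
  if (is.character(genes) && length(genes) == 1L && file.exists(genes)) {
    genes <- Biostrings::readDNAStringSet(genes)
  }
  if (is.character(genes)) {
    genes <- Biostrings::DNAStringSet(genes)
  }
  if (!methods::is(genes, "DNAStringSet")) {
    stop("'genes' must be a named character vector, DNAStringSet or FASTA path")
  }
  if (length(genes) == 0L) stop("no gene sequences supplied")
  ids <- names(genes)
  if (is.null(ids) || any(!nzchar(ids))) stop("all genes must be named")
  ids <- sub("\\s.*$", "", ids)  # FASTA description lines: keep first token
  if (anyDuplicated(ids)) {
    stop("duplicate gene ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- Biostrings::width(genes)
  if (any(lens == 0L)) stop("zero-length gene sequence(s)")
  spacer_len <- as.integer(spacer_len)
  if (is.na(spacer_len) || spacer_len < 0L) stop("'spacer_len' must be >= 0")

  starts <- cumsum(c(1L, head(lens, -1L) + spacer_len))
  ends <- starts + lens - 1L
  spacer <- paste(rep("N", spacer_len), collapse = "")
  refseq <- paste(as.character(genes), collapse = spacer)
  reference <- Biostrings::DNAStringSet(refseq)
  names(reference) <- ref_name

  intervals <- data.frame(gene_id = ids, start = starts, end = ends,
                          length = lens, stringsAsFactors = FALSE)
  list(reference = reference, intervals = intervals)
}

#' Extract a gene's sequence back out of the concatenated reference
#'
#' Inverse of [build_insilico_reference()] for a single interval; used to
#' verify the reference round-trips.
#'
#' @param reference `DNAStringSet` of length 1 (or character scalar).
#' @param interval one row of the interval table.
#' @return character scalar, the gene sequence.
#' @export
extract_gene_sequence <- function(reference, interval) {
  refchr <- as.character(reference)[[1L]]
  substr(refchr, interval$start, interval$end)
}

#' Write / read the gene-interval map
#'
#' Tab-separated, 1-based inclusive coordinates (unlike BED), with a header
#' line `gene_id  start  end  length`.
#'
#' @param intervals data.frame as returned by [build_insilico_reference()].
#' @param path file path.
#' @return `read_gene_intervals` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
write_gene_intervals <- function(intervals, path) {
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_intervals
#' @export
read_gene_intervals <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "length")
  if (!all(need %in% names(x))) {
    stop("interval file must have columns: ", paste(need, collapse = ", "))
  }
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x$length <- as.integer(x$length)
  x
}
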