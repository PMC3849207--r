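## SAM/BAM input and the alignment-level filters.

SAM_FLAG <- c(paired = 0x1L, proper = 0x2L, unmapped = 0x4L,
              mate_unmapped = 0x8L, reverse = 0x10L, first_mate = 0x40L,
              second_mate = 0x80L, secondary = 0x100L, dup = 0x400L,
              supplementary = 0x800L)

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Read a SAM or BAM alignment file into a table
#'
#' Parses the file with Rsamtools (SAM input is converted to BAM in a
#' temporary location first) and lays each read's bases out in reference
#' space, so that the base at any overlapped reference position can be
#' looked up by offset.  Records flagged unmapped are skipped.
#'
#' @param path SAM or BAM file.  SAM files must carry `@SQ` headers.
#' @param reference_names optional character vector of expected reference
#'   sequence names; a mismatch with the file's `@SQ` headers aborts.
#' @return `data.table` with one row per alignment record: `qname`,
#'   `flag`, `rname`, `pos` (1-based leftmost), `end`, `mapq`, `cigar`,
#'   `seqtext` (read bases in reference space, deletions as `-`), and
#'   uniqueness tags `XA`/`X0` when present.
#' @export
read_alignments <- function(path, reference_names = NULL) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  } else {
    bam <- path
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  sq <- names(hdr$targets)
  if (!is.null(reference_names) && !all(reference_names %in% sq)) {
    stop("alignment header @SQ does not match the expected reference (",
         paste(setdiff(reference_names, sq), collapse = ", "), " missing)")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("XA", "X0")
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(b$qname)
  if (n == 0L) {
    return(data.table(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      end = integer(), mapq = integer(),
                      cigar = character(), seqtext = character(),
                      XA = character(), X0 = integer()))
  }
  mapped <- !has_flag(b$flag, SAM_FLAG[["unmapped"]]) & !is.na(b$pos)
  ## reference-space layout handles I/D/S/N CIGAR operations
  lay <- GenomicAlignments::sequenceLayer(b$seq[mapped], b$cigar[mapped],
                                          from = "query", to = "reference")
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[mapped])
  xa <- b$tag$XA
  x0 <- b$tag$X0
  dt <- data.table(
    qname = b$qname[mapped],
    flag = b$flag[mapped],
    rname = as.character(b$rname)[mapped],
    pos = b$pos[mapped],
    end = b$pos[mapped] + w - 1L,
    mapq = b$mapq[mapped],
    cigar = b$cigar[mapped],
    seqtext = as.character(lay),
    XA = if (is.null(xa)) NA_character_ else xa[mapped],
    X0 = if (is.null(x0)) NA_integer_ else x0[mapped]
  )
  dt
}

#' Filter alignments on mapping quality, pairing and uniqueness
#'
#' Removes records with mapping quality at or below `min_mapq` (a MAPQ of
#' exactly `min_mapq` is removed), records that are not part of a mapped
#' pair (unpaired reads, or reads whose mate is unmapped), and records
#' that are not uniquely mapped.  Uniqueness means: not flagged secondary
#' or supplementary, and no aligner-reported alternative hit (`XA` tag
#' absent, `X0` absent or equal to 1).  When the aligner emits no such
#' tags the surviving mapping-quality requirement acts as the uniqueness
#' proxy.
#'
#' @param aln alignment `data.table` from [read_alignments()].
#' @param min_mapq phred threshold (default 20); records with
#'   `mapq <= min_mapq` are removed.
#' @return the surviving rows (a copy); the input is not modified.
#' @export
filter_alignments <- function(aln, min_mapq = 20L) {
  if (nrow(aln) == 0L) return(data.table::copy(aln))
  f <- aln$flag
  keep <- aln$mapq > min_mapq &
    has_flag(f, SAM_FLAG[["paired"]]) &
    !has_flag(f, SAM_FLAG[["unmapped"]]) &
    !has_flag(f, SAM_FLAG[["mate_unmapped"]]) &
    !has_flag(f, SAM_FLAG[["secondary"]]) &
    !has_flag(f, SAM_FLAG[["supplementary"]]) &
    (is.na(aln$XA)) &
    (is.na(aln$X0) | aln$X0 == 1L)
  aln[keep]
}

## Bases carried by alignments at given reference positions.
## aln: rows for one reference sequence; positions: integer vector.
## Returns data.table(qname, pos, base) with one row per
## (alignment, overlapped position); bases other than A/C/G/T (N, gaps)
## are dropped.
alignment_bases_at <- function(aln, positions) {
  if (nrow(aln) == 0L || length(positions) == 0L) {
    return(data.table(qname = character(), pos = integer(),
                      base = character()))
  }
  posdt <- data.table(pos = sort(unique(as.integer(positions))))
  a <- aln[, .(qname, start = pos, end, seqtext)]
  a[, rowid := .I]
  hits <- a[posdt, on = .(start <= pos, end >= pos), nomatch = NULL,
            .(qname, rowid = x.rowid, pos = i.pos, start = x.start,
              seqtext = x.seqtext)]
  if (nrow(hits) == 0L) {
    return(data.table(qname = character(), pos = integer(),
                      base = character()))
  }
  hits[, base := substring(seqtext, pos - start + 1L, pos - start + 1L)]
  hits <- hits[base %chin% BASES, .(qname, pos, base)]
  hits[]
}
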