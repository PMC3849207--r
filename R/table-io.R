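## Assignment-table serialization (TSV, lossless round trip).

#' Write / read an assignment table
#'
#' One row per HSP position: `gene_id`, `sequence_name`, `position`
#' (1-based on the concatenated reference), `ref_base`,
#' `polyploid_consensus`, then one column per subgenome containing either
#' an assigned base (A/C/G/T) or a status code (`UNASSIGNED`,
#' `DIPLOID_LOW_COV`, `DIPLOID_AMBIGUOUS`).  The reader recovers exactly
#' what the writer was given.
#'
#' @param table assignment data.frame ([assign_subgenome_bases()]).
#' @param path file path.
#' @return the reader returns the data.frame; the writer returns `path`
#'   invisibly.
#' @export
write_assignment_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment_table
#' @export
read_assignment_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("gene_id", "sequence_name", "position", "ref_base",
            "polyploid_consensus")
  if (!all(need %in% names(x))) {
    stop("assignment table must have columns: ",
         paste(need, collapse = ", "))
  }
  x$position <- as.integer(x$position)
  x
}

## subgenome columns of an assignment table
assignment_genomes <- function(table) {
  setdiff(names(table), c("gene_id", "sequence_name", "position",
                          "ref_base", "polyploid_consensus"))
}

## TRUE where the cell holds an assigned base
cell_is_base <- function(x) x %in% BASES
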