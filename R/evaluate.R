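## Accuracy accounting against a ground-truth table.

#' Evaluate an assignment table against simulator truth
#'
#' Per-subgenome accounting in the style of a nullisomic-tetrasomic
#' evaluation: positions for which the truth table offers no base (the
#' analogue of positions a truth-line experiment cannot resolve), where
#' the subgenome was silenced, or where the genome's diploid relative was
#' low-coverage or ambiguous (as recorded in the assignment table), are
#' ignored; the remaining considered positions are split into correct,
#' incorrect and unassigned, with percentages over the considered
#' denominator.  Ignore precedence: truth unavailable, then silenced,
#' then the diploid categories.
#' @param truth truth data.frame: `gene_id`, `position`, one true-base
#'   column per subgenome (the simulator's `truth.tsv`).
#' @param expressed optional data.frame `gene_id`, `genome`, `expressed`
#'   (logical); omitted means nothing was silenced.
#' @return data.frame with one row per subgenome: `genome`,
#'   `hsp_positions`, `truth_unavailable`, `silenced`, `diploid_low_cov`,
#'   `diploid_ambiguous`, `considered`, `correct`, `incorrect`,
#'   `unassigned`, `pct_correct`, `pct_incorrect`, `pct_unassigned`.
#' @export
evaluate_against_truth <- function(assignments, truth, expressed = NULL) {
  genomes <- assignment_genomes(assignments)
  tr <- data.table::as.data.table(truth)
  if (!all(genomes %in% names(tr))) {
    stop("truth table lacks column(s): ",
         paste(setdiff(genomes, names(tr)), collapse = ", "))
  }
  at <- data.table::as.data.table(assignments)
  n_no_truth <- length(setdiff(at$position, tr$position))
  m <- merge(at, tr, by = "position", suffixes = c("", ".truth"))
  if (!is.null(expressed)) {
    ex <- data.table::as.data.table(expressed)
    ex[, expressed := as.logical(expressed)]
  }
  rows <- lapply(genomes, function(g) {
    cell <- m[[g]]
    tbase <- m[[paste0(g, ".truth")]]
    sil <- rep(FALSE, nrow(m))
    if (!is.null(expressed)) {
      silg <- ex[genome == g & expressed == FALSE, gene_id]
      sil <- m$gene_id %in% silg
    }
    lowcov <- !sil & cell == "DIPLOID_LOW_COV"
    ambig <- !sil & cell == "DIPLOID_AMBIGUOUS"
    considered <- !sil & !lowcov & !ambig
    corr <- considered & cell_is_base(cell) & cell == tbase
    incorr <- considered & cell_is_base(cell) & cell != tbase
    unasg <- considered & !cell_is_base(cell)
    nc <- sum(considered)
    data.frame(
      genome = g,
      hsp_positions = nrow(at),
      truth_unavailable = n_no_truth,
      silenced = sum(sil),
      diploid_low_cov = sum(lowcov),
      diploid_ambiguous = sum(ambig),
      considered = nc,
      correct = sum(corr),
      incorrect = sum(incorr),
      unassigned = sum(unasg),
      pct_correct = if (nc > 0) 100 * sum(corr) / nc else NA_real_,
      pct_incorrect = if (nc > 0) 100 * sum(incorr) / nc else NA_real_,
      pct_unassigned = if (nc > 0) 100 * sum(unasg) / nc else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read a simulator truth / expression table
#'
#' @param path `truth.tsv` or `expressed.tsv` written by
#'   [simulate_reads_and_alignments()].
#' @return data.frame.
#' @export
read_truth_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
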