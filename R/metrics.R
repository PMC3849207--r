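## Post-hoc summary statistics over an assignment table.

#' Shared-base percentages between subgenomes (and versus diploids)
#'
#' For every unordered pair of subgenomes, the percentage of HSP
#' positions at which the two assigned bases agree, computed over
#' positions where a base was assigned to *all* subgenomes (so the
#' denominator is identical across subgenome pairs).  When diploid
#' profiles are supplied, each subgenome is additionally compared with
#' its own diploid relative over the fully-assigned positions at which
#' that diploid has an unambiguous, adequately covered base (these rows
#' carry their own denominators).
#'
#' @param assignments assignment data.frame.
#' @param profiles optional named list of diploid profiles
#'   ([build_diploid_profiles()]).
#' @param min_diploid_cov diploid coverage threshold used for the
#'   diploid comparisons (default 3).
#' @return data.frame with columns `comparison` (`"subgenomes"` or
#'   `"vs_diploid"`), `a`, `b`, `n_positions`, `n_shared`, `percent`.
#'   With zero qualifying positions `percent` is `NA` and the row is
#'   flagged by `n_positions = 0`.
#' @export
shared_base_percentages <- function(assignments, profiles = NULL,
                                    min_diploid_cov = 3L) {
  genomes <- assignment_genomes(assignments)
  cellmat <- as.matrix(assignments[, genomes, drop = FALSE])
  full <- rowSums(matrix(cell_is_base(cellmat),
                         ncol = length(genomes))) == length(genomes)
  rows <- list()
  if (length(genomes) >= 2L) {
    for (i in seq_len(length(genomes) - 1L)) {
      for (j in seq(i + 1L, length(genomes))) {
        a <- genomes[i]; b <- genomes[j]
        n <- sum(full)
        sh <- sum(full & cellmat[, a] == cellmat[, b])
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = "subgenomes", a = a, b = b,
          n_positions = n, n_shared = sh,
          percent = if (n > 0) 100 * sh / n else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(profiles)) {
    pos <- assignments$position
    for (g in intersect(genomes, names(profiles))) {
      prof <- profiles[[g]]
      info <- profile_informative(prof, min_diploid_cov)
      dipbase <- rep(NA_character_, length(pos))
      idx <- match(pos, prof$position)
      ok <- !is.na(idx) & info[pmax(idx, 1L)]
      dipbase[ok] <- prof$base[idx[ok]]
      use <- full & !is.na(dipbase)
      n <- sum(use)
      sh <- sum(use & cellmat[, g] == dipbase)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "vs_diploid", a = g, b = paste0("diploid_", g),
        n_positions = n, n_shared = sh,
        percent = if (n > 0) 100 * sh / n else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(comparison = character(), a = character(),
                      b = character(), n_positions = integer(),
                      n_shared = integer(), percent = numeric(),
                      stringsAsFactors = FALSE)
  }
  if (any(out$n_positions == 0)) {
    warning("zero qualifying positions for some comparison(s)")
  }
  out
}

#' Fraction of tri-homeoallelic HSP positions
#'
#' Percentage of fully-assigned HSP positions (a base assigned to all
#' subgenomes) at which the assigned bases are pairwise distinct, i.e.
#' the position carries three different homeoalleles.
#'
#' @param assignments assignment data.frame with three subgenome columns.
#' @return single numeric percentage (`NA` when no position is fully
#'   assigned).
#' @export
tri_homeoallelic_fraction <- function(assignments) {
  genomes <- assignment_genomes(assignments)
  cellmat <- as.matrix(assignments[, genomes, drop = FALSE])
  isb <- matrix(cell_is_base(cellmat), ncol = length(genomes))
  full <- rowSums(isb) == length(genomes)
  if (!any(full)) return(NA_real_)
  ndist <- apply(cellmat[full, , drop = FALSE], 1L,
                 function(x) length(unique(x)))
  100 * sum(ndist == length(genomes)) / sum(full)
}
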