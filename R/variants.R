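## Variant lists (HSPs for the polyploid, SBSs for the diploids),
## per-position depth tables, and the Methods-style variant filters.
##
## A variant list is a tab-separated file with a header and columns
##   sequence_name  position  ref_base  consensus  [quality]  [coverage]
## Coordinates are 1-based on the named sequence (the concatenated
## reference).  `consensus` is a single IUPAC letter; for a polyploid HSP
## an ambiguous letter enumerates the homeoallele set (A/C -> M), for a
## diploid an ambiguous letter flags a heterozygous, uninformative call.

#' Read / write a variant list
#'
#' @param path file path of a tab-separated variant list.
#' @return data.frame with columns `sequence_name`, `position`,
#'   `ref_base`, `consensus` and, when present, `quality` and `coverage`.
#' @export
read_variant_list <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = NA)
  need <- c("sequence_name", "position", "ref_base", "consensus")
  if (!all(need %in% names(x))) {
    stop("variant list must have columns: ", paste(need, collapse = ", "),
         " (got: ", paste(names(x), collapse = ", "), ")")
  }
  x$position <- as.integer(x$position)
  x$ref_base <- toupper(x$ref_base)
  x$consensus <- toupper(x$consensus)
  if ("quality" %in% names(x)) x$quality <- as.numeric(x$quality)
  if ("coverage" %in% names(x)) x$coverage <- as.integer(x$coverage)
  x
}

#' @rdname read_variant_list
#' @param records variant data.frame.
#' @export
write_variant_list <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter a variant list on quality, coverage and ambiguity
#'
#' Retains records with quality strictly above `min_quality` (a phred
#' score of exactly `min_quality` is removed) and coverage of at least
#' `min_cov` reads.  With `drop_ambiguous = TRUE` (appropriate for diploid
#' substitution lists) records whose consensus is an ambiguous IUPAC code
#' are removed as well.  Records whose consensus is not a valid IUPAC
#' letter are dropped with a warning.  Records lacking a quality or
#' coverage column pass the corresponding check.
#'
#' @param records variant data.frame (see [read_variant_list()]).
#' @param min_quality phred threshold; records with `quality <= min_quality`
#'   are removed (default 20).
#' @param min_cov minimum read coverage (default 3).
#' @param drop_ambiguous drop IUPAC-ambiguous consensus calls.
#' @return the surviving records, same columns, original order.
#' @export
filter_variants <- function(records, min_quality = 20, min_cov = 3L,
                            drop_ambiguous = FALSE) {
  if (nrow(records) == 0L) return(records)
  ok_code <- records$consensus %in% names(Biostrings::IUPAC_CODE_MAP)
  if (any(!ok_code)) {
    warning(sum(!ok_code), " record(s) with unknown IUPAC consensus dropped")
  }
  keep <- ok_code
  if ("quality" %in% names(records)) {
    keep <- keep & records$quality > min_quality
  }
  if ("coverage" %in% names(records)) {
    keep <- keep & records$coverage >= min_cov
  }
  if (drop_ambiguous) {
    keep <- keep & is_unambiguous_base(records$consensus)
  }
  records[keep, , drop = FALSE]
}

#' Read / write a per-position depth table
#'
#' Tab-separated with header `sequence_name  position  depth`; supplies
#' diploid read depth at positions absent from the substitution list
#' (where the diploid matches the reference).
#'
#' @param path file path.
#' @return data.frame with the three columns.
#' @export
read_depth_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sequence_name", "position", "depth")
  if (!all(need %in% names(x))) {
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  }
  x$position <- as.integer(x$position)
  x$depth <- as.integer(x$depth)
  x
}

#' @rdname read_depth_table
#' @param depths depth data.frame.
#' @export
write_depth_table <- function(depths, path) {
  utils::write.table(depths, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build per-HSP diploid profiles from substitution lists and depth
#'
#' For every HSP position of the polyploid and every diploid relative,
#' derives the diploid's base, read coverage and ambiguity flag.  A
#' position present in the diploid's substitution list takes that call
#' (flagged ambiguous when the consensus is an IUPAC multi-base code);
#' a position absent from the list is taken to match the reference base,
#' with coverage looked up in the depth table (0 when absent there too).
#'
#' @param hsps polyploid HSP variant data.frame (defines the positions
#'   and reference bases).
#' @param sbs_lists named list of diploid substitution data.frames, one
#'   per subgenome label (e.g. `list(A = ..., B = ..., D = ...)`).
#' @param depth_tables named list of depth data.frames matching
#'   `sbs_lists`; entries may be `NULL` when the substitution lists carry
#'   a `coverage` column for every HSP position.
#' @param min_diploid_cov coverage below which a position is uninformative
#'   (default 3); recorded in the profile as attribute `min_diploid_cov`.
#' @return named list of `data.table`s, one per genome, with columns
#'   `position`, `base` (NA when not a unique base), `coverage`,
#'   `ambiguous`.
#' @export
build_diploid_profiles <- function(hsps, sbs_lists, depth_tables = NULL,
                                   min_diploid_cov = 3L) {
  stopifnot(is.list(sbs_lists), !is.null(names(sbs_lists)))
  hs <- data.table::as.data.table(hsps)[, .(sequence_name, position, ref_base)]
  data.table::setkey(hs, sequence_name, position)
  out <- list()
  for (g in names(sbs_lists)) {
    sbs <- data.table::as.data.table(sbs_lists[[g]])
    prof <- data.table::copy(hs)
    prof[, `:=`(base = ref_base, coverage = 0L, ambiguous = FALSE)]
    ## coverage from depth table where supplied
    dt <- depth_tables[[g]]
    if (!is.null(dt)) {
      dt <- data.table::as.data.table(dt)
      prof[dt, coverage := as.integer(i.depth),
           on = c("sequence_name", "position")]
    }
    ## overlay the diploid's own calls
    if (nrow(sbs) > 0L) {
      cols <- c("sequence_name", "position", "consensus",
                intersect("coverage", names(sbs)))
      sb <- sbs[, ..cols]
      data.table::setnames(sb, "consensus", "dip_call")
      if ("coverage" %in% names(sb)) {
        data.table::setnames(sb, "coverage", "dip_cov")
      }
      prof <- merge(prof, sb, by = c("sequence_name", "position"),
                    all.x = TRUE)
      hit <- !is.na(prof$dip_call)
      amb <- hit & !is_unambiguous_base(prof$dip_call)
      prof[hit & !amb, base := dip_call]
      prof[amb, `:=`(base = NA_character_, ambiguous = TRUE)]
      if ("dip_cov" %in% names(prof)) {
        prof[hit & !is.na(prof$dip_cov), coverage := as.integer(dip_cov)]
        prof[, dip_cov := NULL]
      }
      prof[, dip_call := NULL]
    }
    prof[, ref_base := NULL]
    data.table::setattr(prof, "min_diploid_cov", as.integer(min_diploid_cov))
    data.table::setattr(prof, "genome_label", g)
    out[[g]] <- prof
  }
  out
}

## informative = usable for identity: unique base present, adequately covered
profile_informative <- function(profile, min_diploid_cov) {
  !profile$ambiguous & !is.na(profile$base) &
    profile$coverage >= min_diploid_cov
}
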