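## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

ASSIGN_STATES <- c("UNASSIGNED", "DIPLOID_LOW_COV", "DIPLOID_AMBIGUOUS")

#' Decode an IUPAC nucleotide code to its base set
#'
#' @param code character vector of single IUPAC letters.
#' @return list of character vectors, one per input code, each the set of
#'   bases the code stands for (e.g. `"M"` -> `c("A","C")`).
#' @examples
#' iupac_to_bases(c("A", "M", "H"))
#' @export
iupac_to_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  code <- toupper(code)
  bad <- !code %in% names(map)
  if (any(bad)) {
    stop("unknown IUPAC code(s): ", paste(unique(code[bad]), collapse = ", "))
  }
  lapply(strsplit(unname(map[code]), ""), identity)
}

#' Encode a set of bases as a single IUPAC code
#'
#' @param bases character vector drawn from A, C, G, T.
#' @return single IUPAC letter covering exactly this base set.
#' @examples
#' bases_to_iupac(c("A", "C"))   # "M"
#' @export
bases_to_iupac <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (!all(bases %in% BASES)) {
    stop("bases must be drawn from A, C, G, T")
  }
  map <- Biostrings::IUPAC_CODE_MAP
  keysorted <- vapply(strsplit(unname(map), ""),
                      function(x) paste(sort(x), collapse = ""), "")
  hit <- names(map)[match(paste(bases, collapse = ""), keysorted)]
  if (is.na(hit)) stop("no IUPAC code for base set: ",
                       paste(bases, collapse = ","))
  hit
}

is_unambiguous_base <- function(code) {
  toupper(code) %in% BASES
}

## canonical pattern key: "pos:base;pos:base;..." with positions increasing
pattern_key <- function(pos, base) {
  o <- order(pos)
  paste(paste0(pos[o], ":", base[o]), collapse = ";")
}

## inverse of pattern_key -> data.table(pos, base)
parse_pattern_key <- function(keys) {
  sites <- strsplit(keys, ";", fixed = TRUE)
  n <- lengths(sites)
  flat <- unlist(sites, use.names = FALSE)
  pb <- strsplit(flat, ":", fixed = TRUE)
  data.table(
    key = rep(keys, n),
    pos = as.integer(vapply(pb, `[`, "", 1L)),
    base = vapply(pb, `[`, "", 2L)
  )
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

msg <- function(...) message("[homeoassign] ", sprintf(...))
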