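## Base-pattern construction and cleaning (engine steps 1 and 2).
##
## A base pattern is the ordered sequence of (position, base) pairs a read
## pair exhibits over the HSP positions it covers, together with the
## number of read pairs showing exactly that pattern.  Patterns are the
## unit all downstream assignment works on; reads are never revisited.
##
## Internal representation: a list of class "base_patterns" with
##   $patterns : data.table(key, support)           one row per pattern
##   $sites    : data.table(key, pos, base)         pattern sites, ordered
## where `key` is the canonical string "pos:base;pos:base;...".

new_base_patterns <- function(patterns, sites) {
  structure(list(patterns = patterns, sites = sites),
            class = "base_patterns")
}

#' @export
print.base_patterns <- function(x, ...) {
  cat(sprintf("<base_patterns: %d pattern(s), total support %d>\n",
              nrow(x$patterns), sum(x$patterns$support)))
  invisible(x)
}

empty_base_patterns <- function() {
  new_base_patterns(
    data.table::as.data.table(list(key = character(), support = integer())),
    data.table::as.data.table(list(key = character(), pos = integer(),
                                   base = character()))
  )
}

#' Build base patterns from aligned read pairs at HSP positions
#'
#' Considers both mates of a read pair together and records the bases the
#' pair shows at every HSP position it overlaps.  Read pairs whose mates
#' overlap and disagree at a shared HSP position are dropped entirely (one
#' of the two reads must carry a sequencing error).  A base of `N` (or any
#' non-ACGT character) at an HSP simply excludes that site from the
#' pattern.  Identical patterns are merged, summing their read support;
#' pairs overlapping no HSP contribute nothing.
#'
#' @param aln alignment `data.table` ([read_alignments()] rows, already
#'   filtered, restricted to one gene); mates are grouped by `qname`.
#' @param hsps integer vector of HSP positions (1-based, reference
#'   coordinates) for the gene.
#' @return object of class `base_patterns`.
#' @export
build_base_patterns <- function(aln, hsps) {
  obs <- alignment_bases_at(aln, hsps)
  if (nrow(obs) == 0L) return(empty_base_patterns())
  ## forward/reverse discrepancy at a shared HSP -> drop the whole pair
  data.table::setorder(obs, qname, pos, base)
  n <- nrow(obs)
  if (n > 1L) {
    samepp <- obs$qname[-1L] == obs$qname[-n] & obs$pos[-1L] == obs$pos[-n]
    diffb <- obs$base[-1L] != obs$base[-n]
    bad <- unique(obs$qname[-1L][samepp & diffb])
    if (length(bad)) obs <- obs[!qname %chin% bad]
    if (nrow(obs) == 0L) return(empty_base_patterns())
  }
  obs <- unique(obs, by = c("qname", "pos"))  # overlapping agreeing mates: once
  pat <- obs[, .(key = paste(paste0(pos, ":", base), collapse = ";")),
             by = qname]
  patterns <- pat[, .(support = .N), by = key]
  sites <- unique(obs[pat, on = "qname"][, .(key, pos, base)])
  data.table::setorder(sites, key, pos)
  data.table::setorder(patterns, key)
  new_base_patterns(patterns, sites)
}

## Adjacent base pairs within each pattern: consecutive covered sites.
## Returns data.table(key, p1, p2, b1, b2, support).
pattern_adjacent_pairs <- function(bp) {
  s <- bp$sites
  if (nrow(s) == 0L) {
    return(data.table::as.data.table(list(
      key = character(), p1 = integer(), p2 = integer(),
      b1 = character(), b2 = character(), support = integer())))
  }
  s <- s[order(key, pos)]
  pr <- s[, if (.N >= 2L) .(p1 = pos[-.N], p2 = pos[-1L],
                            b1 = base[-.N], b2 = base[-1L]), by = key]
  if (nrow(pr) == 0L) {
    return(data.table::as.data.table(list(
      key = character(), p1 = integer(), p2 = integer(),
      b1 = character(), b2 = character(), support = integer())))
  }
  pr[bp$patterns, support := i.support, on = "key"]
  pr[]
}

#' Remove patterns supported by likely sequencing errors
#'
#' For every pair of consecutive covered HSP positions within a pattern
#' ("base pair"), counts the reads supporting that (base1, base2)
#' combination across all patterns, and the total reads carrying any base
#' combination at those two positions.  A pattern is removed when any of
#' its base pairs is present in less than `min_pair_fraction` of the reads
#' at those positions.  Patterns covering fewer than two HSPs carry no
#' base pair and are never removed by this rule.
#'
#' @param bp `base_patterns` object for one gene.
#' @param min_pair_fraction threshold fraction in `[0, 1]` (default 0.05);
#'   a base pair at exactly the threshold is retained ("less than").
#' @return list with `base_patterns` elements `kept` and `removed`.
#' @export
filter_error_patterns <- function(bp, min_pair_fraction = 0.05) {
  stop_if_not_scalar_prob(min_pair_fraction, "min_pair_fraction")
  pr <- pattern_adjacent_pairs(bp)
  if (nrow(pr) == 0L) {
    return(list(kept = bp, removed = empty_base_patterns()))
  }
  agg <- pr[, .(pair_support = sum(support)), by = .(p1, p2, b1, b2)]
  agg[, site_total := sum(pair_support), by = .(p1, p2)]
  pr[agg, frac := i.pair_support / i.site_total,
     on = c("p1", "p2", "b1", "b2")]
  drop_keys <- unique(pr[frac < min_pair_fraction, key])
  subset_split(bp, drop_keys)
}

#' Remove patterns embedded within longer patterns
#'
#' Pattern P is embedded in pattern Q when every (position, base) site of
#' P also occurs in Q and P covers strictly fewer sites.  Embedded
#' patterns are removed.  When an embedded pattern has exactly one maximal
#' container (a containing pattern that is itself not embedded), its read
#' support is added to that container; when several maximal containers
#' compete, the support is discarded as of ambiguous origin.  The
#' operation is idempotent: no kept pattern is a strict sub-pattern of
#' another.
#'
#' @param bp `base_patterns` object for one gene.
#' @return list with `base_patterns` elements `kept` (support merged where
#'   unambiguous) and `removed` (original supports).
#' @export
remove_embedded_patterns <- function(bp) {
  n <- nrow(bp$patterns)
  if (n <= 1L) return(list(kept = bp, removed = empty_base_patterns()))
  meta <- bp$sites[, .(first_pos = min(pos), last_pos = max(pos),
                       n_sites = .N), by = key]
  ## candidate containers: span covers span, strictly more sites
  x <- meta[, .(xkey = key, first_pos, last_pos, n_sites_x = n_sites)]
  y <- meta[, .(ykey = key, first_pos, last_pos, n_sites_y = n_sites)]
  cand <- x[y, on = .(first_pos <= first_pos, last_pos >= last_pos),
            nomatch = NULL, allow.cartesian = TRUE,
            .(xkey, ykey, nx = n_sites_x, ny = n_sites_y)]
  cand <- cand[nx > ny & xkey != ykey]
  if (nrow(cand) > 0L) {
    ## verify site-set containment with one keyed join over all candidates
    cand[, cid := .I]
    ys <- bp$sites[cand[, .(key = ykey, cid, xkey)], on = "key",
                   allow.cartesian = TRUE,
                   .(cid, xkey, pos, base)]
    hit <- bp$sites[ys, on = c(key = "xkey", pos = "pos", base = "base"),
                    which = TRUE]
    badid <- unique(ys$cid[is.na(hit)])
    cand <- cand[!cid %in% badid]
  }
  if (nrow(cand) == 0L) {
    return(list(kept = bp, removed = empty_base_patterns()))
  }
  embedded <- unique(cand$ykey)
  kept_keys <- setdiff(bp$patterns$key, embedded)
  ## merge support into a unique maximal container
  maxcand <- cand[xkey %chin% kept_keys]
  ncont <- maxcand[, .(n_cont = .N, container = xkey[1L]), by = ykey]
  uniq <- ncont[n_cont == 1L]
  res <- subset_split(bp, embedded)
  if (nrow(uniq) > 0L) {
    addsup <- bp$patterns[uniq, on = c(key = "ykey"),
                          .(container, add = support)]
    addsup <- addsup[, .(add = sum(add)), by = container]
    res$kept$patterns[addsup, support := support + i.add,
                      on = c(key = "container")]
  }
  res
}

## split a base_patterns object into kept / removed by key
subset_split <- function(bp, drop_keys) {
  if (length(drop_keys) == 0L) {
    return(list(kept = new_base_patterns(data.table::copy(bp$patterns),
                                         data.table::copy(bp$sites)),
                removed = empty_base_patterns()))
  }
  keep <- !bp$patterns$key %chin% drop_keys
  list(
    kept = new_base_patterns(bp$patterns[keep],
                             bp$sites[!key %chin% drop_keys]),
    removed = new_base_patterns(bp$patterns[!keep],
                                bp$sites[key %chin% drop_keys])
  )
}

#' Dump base patterns as a table
#'
#' Debug view of a `base_patterns` object: one row per pattern with its
#' canonical site string and read support.
#'
#' @param x `base_patterns` object.
#' @param ... unused.
#' @return data.frame with columns `pattern` and `support`.
#' @export
as.data.frame.base_patterns <- function(x, ...) {
  data.frame(pattern = x$patterns$key, support = x$patterns$support,
             stringsAsFactors = FALSE)
}
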