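## Subgenome assignment engine (steps 3-5) and orchestration.

#' Score a base pattern against a diploid profile
#'
#' Percentage identity of a pattern with one diploid relative, computed
#' only over informative sites: positions where the diploid has a unique
#' (unambiguous) base covered by at least `min_diploid_cov` reads.
#' Low-coverage, ambiguous and absent diploid positions are excluded from
#' both numerator and denominator.
#'
#' @param pattern data.frame with columns `pos` and `base` (one pattern).
#' @param profile one diploid profile (see [build_diploid_profiles()]).
#' @param min_diploid_cov minimum diploid read coverage (default 3).
#' @return list with `identity` (NA when no informative site),
#'   `informative_sites` and `matches`.
#' @export
score_pattern <- function(pattern, profile, min_diploid_cov = 3L) {
  prof <- data.table::as.data.table(profile)
  idx <- match(pattern$pos, prof$position)
  hit <- !is.na(idx)
  info <- hit & profile_informative(prof, min_diploid_cov)[idx]
  n_info <- sum(info)
  n_match <- sum(info & pattern$base == prof$base[idx])
  list(identity = if (n_info > 0L) n_match / n_info else NA_real_,
       informative_sites = n_info, matches = n_match)
}

## Vectorised scoring of all patterns in `bp` against all profiles.
## Returns data.table(key, genome, identity, informative, matches);
## identity is NA when a pattern has no informative site in that genome.
score_patterns_all <- function(bp, profiles, min_diploid_cov = 3L) {
  out <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    g <- names(profiles)[i]
    prof <- profiles[[g]]
    info <- profile_informative(prof, min_diploid_cov)
    pdt <- data.table(position = prof$position, dbase = prof$base,
                      info = info)
    s <- bp$sites[pdt, on = c(pos = "position"), nomatch = NULL,
                  .(key, base, dbase, info)]
    sc <- s[info == TRUE,
            .(informative = .N, matches = sum(base == dbase)), by = key]
    sc <- merge(data.table::as.data.table(list(key = bp$patterns$key)), sc, by = "key",
                all.x = TRUE)
    sc[is.na(informative), `:=`(informative = 0L, matches = 0L)]
    sc[, identity := ifelse(informative > 0L, matches / informative,
                            NA_real_)]
    sc[, genome := g]
    out[[i]] <- sc
  }
  data.table::rbindlist(out)
}

#' Assign base patterns to subgenomes by diploid similarity
#'
#' A pattern is assigned to every subgenome for which its percentage
#' identity with the corresponding diploid relative is at least
#' `min_identity` (default 50%), identity being computed over informative
#' diploid sites only (see [score_pattern()]).  A pattern assigned to no
#' subgenome is routed to the designated distant genome when one is set:
#' the pattern must originate from one of the subgenomes, and low
#' diploid identity is the expected signature of the distant relative.
#'
#' @param bp `base_patterns` object (after step-2 cleaning).
#' @param profiles named list of diploid profiles.
#' @param min_identity assignment threshold in `[0, 1]` (default 0.5); a
#'   pattern at exactly the threshold is assigned ("at least").
#' @param min_diploid_cov minimum diploid coverage (default 3).
#' @param distant_genome label of at most one subgenome whose diploid
#'   relative is comparatively diverged, or `NULL`.
#' @return data.table with one row per (pattern, genome) assignment:
#'   `key`, `genome`, `identity` (the identity used for downstream
#'   prioritisation; 0 when the pattern had no informative diploid site),
#'   `informative`, `support`, and `via_distant` (logical).
#' @export
assign_patterns_to_genomes <- function(bp, profiles, min_identity = 0.5,
                                       min_diploid_cov = 3L,
                                       distant_genome = NULL) {
  stop_if_not_scalar_prob(min_identity, "min_identity")
  if (!is.null(distant_genome)) {
    if (length(distant_genome) != 1L ||
        !distant_genome %in% names(profiles)) {
      stop("'distant_genome' must name exactly one of the profiled genomes")
    }
  }
  if (nrow(bp$patterns) == 0L) {
    return(data.table::as.data.table(list(
      key = character(), genome = character(), identity = numeric(),
      informative = integer(), support = integer(),
      via_distant = logical())))
  }
  sc <- score_patterns_all(bp, profiles, min_diploid_cov)
  asg <- sc[!is.na(identity) & identity >= min_identity]
  asg[, via_distant := FALSE]
  if (!is.null(distant_genome)) {
    orphan <- setdiff(bp$patterns$key, unique(asg$key))
    if (length(orphan)) {
      extra <- sc[genome == distant_genome & key %chin% orphan]
      extra[is.na(identity), identity := 0]
      extra[, via_distant := TRUE]
      asg <- rbind(asg, extra)
    }
  }
  asg[bp$patterns, support := i.support, on = "key"]
  data.table::setorder(asg, genome, key)
  asg[, .(key, genome, identity, informative, support, via_distant)]
}

#' Iteratively assign per-position bases from one subgenome's patterns
#'
#' Step-4 consensus sweep.  Each sweep evaluates every still-unassigned
#' HSP position against the patterns that are live at sweep start: the
#' nucleotides present at the position are collected, each represented by
#' the maximum diploid identity among the live patterns carrying it.  A
#' single nucleotide is assigned outright; with several, the nucleotide
#' whose maximum identity strictly exceeds all others is assigned, and an
#' identity tie across different nucleotides leaves the position
#' unassigned for this sweep.  After a sweep, patterns contradicting any
#' assigned base (carrying a different base at an assigned position) are
#' discarded, and sweeping continues until a sweep assigns nothing.
#' Termination is bounded by the number of HSP positions.
#'
#' @param genome_patterns data.table with columns `key`, `identity`
#'   (and optionally `support`): the patterns assigned to this genome.
#' @param bp `base_patterns` object holding the pattern sites.
#' @param hsps integer vector of the gene's HSP positions.
#' @return list with
#'   * `assigned`: data.table(`pos`, `base`, `src_identity`) — the
#'     assigned bases and the identity of their source pattern;
#'   * `discarded`: keys of patterns discarded as contradicting;
#'   * `live`: keys of patterns still live at termination;
#'   * `sweeps`: number of productive sweeps (sweeps assigning at least
#'     one position); bounded by the number of HSP positions.
#' @export
assign_bases_iteratively <- function(genome_patterns, bp, hsps) {
  assigned <- data.table(pos = integer(), base = character(),
                         src_identity = numeric())
  if (nrow(genome_patterns) == 0L) {
    return(list(assigned = assigned, discarded = character(),
                live = character(), sweeps = 0L))
  }
  sites <- bp$sites[key %chin% genome_patterns$key]
  sites <- sites[genome_patterns, on = "key", nomatch = NULL,
                 .(key, pos, base, identity)]
  live <- unique(genome_patterns$key)
  discarded <- character()
  unpos <- sort(unique(intersect(sites$pos, hsps)))
  sweeps <- 0L
  repeat {
    cand <- sites[key %chin% live & pos %in% unpos]
    if (nrow(cand) == 0L) break
    bybase <- cand[, .(maxid = max(identity)), by = .(pos, base)]
    pick <- bybase[, {
      if (.N == 1L) {
        .(base = base, src_identity = maxid)
      } else {
        o <- order(-maxid)
        if (maxid[o[1L]] > maxid[o[2L]]) {
          .(base = base[o[1L]], src_identity = maxid[o[1L]])
        } else {
          .(base = character(), src_identity = numeric())
        }
      }
    }, by = pos]
    if (nrow(pick) == 0L) break
    sweeps <- sweeps + 1L  # productive sweep: >= 1 new assignment
    assigned <- rbind(assigned, pick[, .(pos, base, src_identity)])
    unpos <- setdiff(unpos, pick$pos)
    ## batch removal of contradicting patterns between sweeps
    contr <- unique(sites[assigned, on = "pos", nomatch = NULL
                          ][base != i.base, key])
    contr <- intersect(contr, live)
    if (length(contr)) {
      live <- setdiff(live, contr)
      discarded <- c(discarded, contr)
    }
    if (length(unpos) == 0L) break
  }
  data.table::setorder(assigned, pos)
  list(assigned = assigned, discarded = sort(discarded),
       live = sort(live), sweeps = sweeps)
}

#' Revisit discarded patterns against the assigned bases
#'
#' Step-5 rescue.  Patterns discarded during the iterative sweeps are
#' re-scored against the bases already assigned to the genome (the
#' diploid plays no role here): identity is the fraction of a pattern's
#' sites, among positions currently assigned, that agree with the
#' assigned base.  Patterns covering no assigned position are unusable.
#' Patterns are processed in a single deterministic pass, in descending
#' identity (ties broken by higher support, then lexicographically by
#' pattern string).  Each pattern may fill any still-unassigned position
#' it covers, and may change an assigned base only when its identity is
#' strictly better than the identity recorded for the currently assigned
#' base's source pattern.
#'
#' @param discarded_bp `base_patterns` object holding the discarded
#'   patterns (sites and supports).
#' @param assigned data.table(`pos`, `base`, `src_identity`) from
#'   [assign_bases_iteratively()].
#' @return updated `assigned` table (same columns).
#' @export
rescue_with_discarded <- function(discarded_bp, assigned) {
  if (nrow(discarded_bp$patterns) == 0L || nrow(assigned) == 0L) {
    return(data.table::copy(assigned))
  }
  asg <- data.table::copy(assigned)
  s <- discarded_bp$sites
  ## working arrays over the union of positions
  posuniv <- sort(unique(c(asg$pos, s$pos)))
  abase <- rep(NA_character_, length(posuniv))
  aid <- rep(NA_real_, length(posuniv))
  i0 <- match(asg$pos, posuniv)
  abase[i0] <- asg$base
  aid[i0] <- asg$src_identity
  ## identity of each discarded pattern vs the step-4 assignments
  si <- match(s$pos, posuniv)
  over <- abase[si]
  ovrows <- !is.na(over)
  if (!any(ovrows)) return(asg)
  sc <- data.table::as.data.table(
    list(key = s$key[ovrows], hitm = s$base[ovrows] == over[ovrows]))
  sc <- sc[, .(identity = mean(hitm)), by = key]
  sc[discarded_bp$patterns, support := i.support, on = "key"]
  data.table::setorder(sc, -identity, -support, key)
  rows_by_key <- split(seq_len(nrow(s)), s$key)
  for (i in seq_len(nrow(sc))) {
    k <- sc$key[i]; pid <- sc$identity[i]
    rows <- rows_by_key[[k]]
    p <- si[rows]
    b <- s$base[rows]
    cur <- abase[p]
    fill <- is.na(cur)
    if (any(fill)) {
      abase[p[fill]] <- b[fill]
      aid[p[fill]] <- pid
    }
    chg <- !fill & cur != b & pid > aid[p]
    if (any(chg)) {
      abase[p[chg]] <- b[chg]
      aid[p[chg]] <- pid
    }
  }
  keep <- !is.na(abase)
  out <- data.table(pos = posuniv[keep], base = abase[keep],
                    src_identity = aid[keep])
  data.table::setorder(out, pos)
  out
}

#' Characterize one gene: full five-step assignment
#'
#' Composes pattern construction, error and embedding filters, pattern-
#' to-genome assignment, the per-genome iterative base sweeps, and the
#' discarded-pattern rescue for a single gene, and reports one row per
#' (HSP position, subgenome) cell.  Positions a genome's engine leaves
#' unassigned are labelled `DIPLOID_LOW_COV` or `DIPLOID_AMBIGUOUS` when
#' that genome's diploid relative was uninformative there, else
#' `UNASSIGNED`.
#'
#' For the rescue step each genome draws on the union of patterns
#' discarded in any genome's sweeps, minus the patterns still live in the
#' genome under consideration.
#'
#' @param aln filtered alignment rows for the gene.
#' @param hsps integer vector of the gene's HSP positions.
#' @param profiles named list of diploid profiles (restricted or not;
#'   only the gene's positions are used).
#' @param min_pair_fraction,min_identity,min_diploid_cov engine
#'   parameters (defaults 0.05, 0.5, 3).
#' @param distant_genome optional distant-genome label.
#' @return data.table with columns `position`, `genome`, `state`
#'   (`"ASSIGNED"` or a status code) and `base` (NA unless assigned).
#' @export
characterize_gene <- function(aln, hsps, profiles,
                              min_pair_fraction = 0.05,
                              min_identity = 0.5,
                              min_diploid_cov = 3L,
                              distant_genome = NULL) {
  genomes <- names(profiles)
  hsps <- sort(unique(as.integer(hsps)))
  if (length(hsps) == 0L) {
    return(data.table(position = integer(), genome = character(),
                      state = character(), base = character()))
  }
  bp0 <- build_base_patterns(aln, hsps)
  bp1 <- filter_error_patterns(bp0, min_pair_fraction)$kept
  bp2 <- remove_embedded_patterns(bp1)$kept
  asg <- assign_patterns_to_genomes(bp2, profiles, min_identity,
                                    min_diploid_cov, distant_genome)
  step4 <- lapply(genomes, function(g) {
    assign_bases_iteratively(asg[genome == g], bp2, hsps)
  })
  names(step4) <- genomes
  all_discarded <- unique(unlist(lapply(step4, `[[`, "discarded")))
  final <- lapply(genomes, function(g) {
    pool <- setdiff(all_discarded, step4[[g]]$live)
    if (length(pool)) {
      dbp <- new_base_patterns(bp2$patterns[key %chin% pool],
                               bp2$sites[key %chin% pool])
      rescue_with_discarded(dbp, step4[[g]]$assigned)
    } else {
      step4[[g]]$assigned
    }
  })
  names(final) <- genomes
  cells <- data.table::CJ(position = hsps, genome = genomes)
  cells[, `:=`(state = "UNASSIGNED", base = NA_character_)]
  for (g in genomes) {
    a <- final[[g]]
    if (nrow(a) > 0L) {
      cells[a, on = c(position = "pos"),
            `:=`(state = ifelse(genome == g, "ASSIGNED", state),
                 base = ifelse(genome == g, i.base, base))]
    }
    prof <- profiles[[g]]
    info <- profile_informative(prof, min_diploid_cov)
    lowcov <- prof$position[!info & !prof$ambiguous]
    ambig <- prof$position[prof$ambiguous]
    cells[genome == g & state == "UNASSIGNED" & position %in% ambig,
          state := "DIPLOID_AMBIGUOUS"]
    cells[genome == g & state == "UNASSIGNED" & position %in% lowcov,
          state := "DIPLOID_LOW_COV"]
    ## positions absent from the profile: no diploid data at all
    cells[genome == g & state == "UNASSIGNED" &
            !position %in% prof$position, state := "DIPLOID_LOW_COV"]
  }
  data.table::setorder(cells, position, genome)
  cells[]
}

#' Run the full assignment over a dataset
#'
#' Whole-run orchestration: reads the SAM/BAM alignments, the polyploid
#' HSP list, one substitution list (and optional depth table) per diploid
#' relative, and the gene-interval map; applies the alignment and variant
#' filters; builds diploid profiles; and characterizes every gene
#' independently.  Genes are processed in interval order; the result is
#' deterministic given identical inputs and parameters.
#'
#' @param sam path to the polyploid SAM or BAM alignment.
#' @param hsp_list path to the polyploid HSP variant list.
#' @param diploid_lists named character vector of substitution-list paths,
#'   one per subgenome label (e.g. `c(A = ..., B = ..., D = ...)`).
#' @param intervals path to the gene-interval map
#'   ([write_gene_intervals()] format).
#' @param depth_tables optional named character vector of per-position
#'   depth tables matching `diploid_lists`.
#' @param distant_genome optional label of the distant subgenome.
#' @param min_mapq,min_variant_quality,min_variant_cov input filters
#'   (defaults 20, 20, 3).
#' @param min_pair_fraction,min_identity,min_diploid_cov engine
#'   parameters (defaults 0.05, 0.5, 3).
#' @return assignment table: data.frame with one row per HSP position —
#'   `gene_id`, `sequence_name`, `position`, `ref_base`,
#'   `polyploid_consensus`, then one column per subgenome holding either
#'   an assigned base or a status code (`UNASSIGNED`, `DIPLOID_LOW_COV`,
#'   `DIPLOID_AMBIGUOUS`).
#' @export
assign_subgenome_bases <- function(sam, hsp_list, diploid_lists, intervals,
                                   depth_tables = NULL,
                                   distant_genome = NULL,
                                   min_mapq = 20L,
                                   min_variant_quality = 20,
                                   min_variant_cov = 3L,
                                   min_pair_fraction = 0.05,
                                   min_identity = 0.5,
                                   min_diploid_cov = 3L) {
  if (is.null(names(diploid_lists)) || any(!nzchar(names(diploid_lists)))) {
    stop("'diploid_lists' must be named by subgenome label")
  }
  if (length(diploid_lists) > 3L) {
    stop("at most three subgenomes are supported")
  }
  genomes <- names(diploid_lists)
  iv <- read_gene_intervals(intervals)

  hsps <- filter_variants(read_variant_list(hsp_list),
                          min_quality = min_variant_quality,
                          min_cov = min_variant_cov,
                          drop_ambiguous = FALSE)
  sbs <- lapply(genomes, function(g) {
    if (!file.exists(diploid_lists[[g]])) {
      stop("missing diploid substitution list for genome ", g, ": ",
           diploid_lists[[g]])
    }
    filter_variants(read_variant_list(diploid_lists[[g]]),
                    min_quality = min_variant_quality,
                    min_cov = min_variant_cov,
                    drop_ambiguous = FALSE)
  })
  names(sbs) <- genomes
  depths <- NULL
  if (!is.null(depth_tables)) {
    depths <- lapply(genomes, function(g) {
      if (is.na(depth_tables[g]) || !nzchar(depth_tables[g])) return(NULL)
      read_depth_table(depth_tables[[g]])
    })
    names(depths) <- genomes
  }
  profiles <- build_diploid_profiles(hsps, sbs, depths, min_diploid_cov)

  aln <- filter_alignments(read_alignments(sam), min_mapq)
  ivdt <- data.table::as.data.table(iv)
  ## map alignments and HSPs to genes by leftmost position
  aln[, gene_id := ivdt$gene_id[findInterval(pos, ivdt$start)]]
  aln[pos > ivdt$end[findInterval(pos, ivdt$start)], gene_id := NA]
  hdt <- data.table::as.data.table(hsps)
  hdt[, gene_id := ivdt$gene_id[findInterval(position, ivdt$start)]]
  hdt <- hdt[!is.na(gene_id) &
               position <= ivdt$end[findInterval(position, ivdt$start)]]

  rows <- vector("list", nrow(ivdt))
  for (i in seq_len(nrow(ivdt))) {
    g <- ivdt$gene_id[i]
    gh <- hdt[gene_id == g]
    if (nrow(gh) == 0L) next
    ga <- aln[gene_id == g]
    gprof <- lapply(profiles, function(p) p[position %in% gh$position])
    cells <- characterize_gene(ga, gh$position, gprof,
                               min_pair_fraction, min_identity,
                               min_diploid_cov, distant_genome)
    wide <- data.table::dcast(
      cells, position ~ genome,
      value.var = c("state", "base")
    )
    for (gg in genomes) {
      st <- wide[[paste0("state_", gg)]]
      ba <- wide[[paste0("base_", gg)]]
      wide[, (gg) := ifelse(st == "ASSIGNED", ba, st)]
    }
    keepcols <- c("position", genomes)
    wide <- wide[, ..keepcols]
    wide <- merge(wide,
                  data.table::as.data.table(
                    gh[, .(position, sequence_name, ref_base,
                           polyploid_consensus = consensus)]),
                  by = "position")
    wide[, gene_id := g]
    rows[[i]] <- wide
  }
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(out) == 0L) {
    out <- data.table(gene_id = character(), sequence_name = character(),
                      position = integer(), ref_base = character(),
                      polyploid_consensus = character())
    for (gg in genomes) out[, (gg) := character()]
    return(data.table::setDF(out))
  }
  data.table::setcolorder(out, c("gene_id", "sequence_name", "position",
                                 "ref_base", "polyploid_consensus",
                                 genomes))
  data.table::setorder(out, position)
  data.table::setDF(out)
  out
}
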