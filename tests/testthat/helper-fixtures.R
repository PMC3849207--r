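## Shared fixtures and independent brute-force oracles.
##
## Patterns are described here as plain R lists:
##   list(pos = integer vector, base = character vector, support = int)
## and converted to/from the package's base_patterns representation, so
## the oracles never touch the implementation's data structures.

library(data.table)

## canonical pattern key (positions assumed sorted)
pkey <- function(pos, base) paste(paste0(pos, ":", base), collapse = ";")

## ---- converters ------------------------------------------------------

bp_from_list <- function(pats) {
  if (length(pats) == 0L) {
    return(build_base_patterns(empty_aln(), integer()))
  }
  keys <- vapply(pats, function(p) {
    o <- order(p$pos)
    paste(paste0(p$pos[o], ":", p$base[o]), collapse = ";")
  }, "")
  sup <- vapply(pats, function(p) as.integer(p$support), 1L)
  pdt <- data.table::as.data.table(list(key = keys, support = sup))
  pdt <- pdt[, .(support = sum(support)), by = key]
  sites <- data.table::rbindlist(lapply(seq_along(pats), function(i) {
    o <- order(pats[[i]]$pos)
    data.table::as.data.table(list(key = keys[i],
                                   pos = as.integer(pats[[i]]$pos[o]),
                                   base = pats[[i]]$base[o]))
  }))
  sites <- unique(sites)
  data.table::setorder(pdt, key)
  data.table::setorder(sites, key, pos)
  structure(list(patterns = pdt, sites = sites), class = "base_patterns")
}

bp_to_list <- function(bp) {
  lapply(seq_len(nrow(bp$patterns)), function(i) {
    k <- bp$patterns$key[i]
    s <- bp$sites[bp$sites$key == k, ]
    list(pos = s$pos, base = s$base, support = bp$patterns$support[i])
  })
}

## canonical (sorted key + support) form for set comparison
bp_canon <- function(bp) {
  d <- as.data.frame(bp)
  d[order(d$pattern), , drop = FALSE] |> (\(x) {
    rownames(x) <- NULL
    x
  })()
}

## ---- direct alignment-table builders (no SAM file needed) -----------

empty_aln <- function() {
  data.table::as.data.table(list(
    qname = character(), flag = integer(), rname = character(),
    pos = integer(), end = integer(), mapq = integer(),
    cigar = character(), seqtext = character(),
    XA = character(), X0 = integer()))
}

## one mate laid out in reference space
make_mate <- function(qname, pos, seqtext, mate = 1L, mapq = 60L,
                      rname = "ref", XA = NA_character_,
                      X0 = NA_integer_, flag = NULL) {
  if (is.null(flag)) {
    flag <- 0x1L + 0x2L + (if (mate == 1L) 0x40L else 0x80L)
  }
  data.table::as.data.table(list(
    qname = qname, flag = as.integer(flag), rname = rname,
    pos = as.integer(pos), end = as.integer(pos + nchar(seqtext) - 1L),
    mapq = as.integer(mapq), cigar = paste0(nchar(seqtext), "M"),
    seqtext = seqtext, XA = XA, X0 = X0))
}

make_aln <- function(...) data.table::rbindlist(list(...))

## a minimal diploid profile table
make_profile <- function(position, base, coverage = 30L,
                         ambiguous = FALSE, seqname = "insilico_ref") {
  n <- length(position)
  data.table::as.data.table(list(
    sequence_name = rep(seqname, n), position = as.integer(position),
    base = base, coverage = as.integer(rep_len(coverage, n)),
    ambiguous = rep_len(ambiguous, n)))
}

## ---- brute-force oracles --------------------------------------------

## error filter: enumerate adjacent pair supports by hand
oracle_pair_filter <- function(pats, min_frac) {
  sup <- new.env(parent = emptyenv())
  tot <- new.env(parent = emptyenv())
  bump <- function(e, k, v) assign(k, v + (if (exists(k, e)) get(k, e) else 0),
                                   envir = e)
  for (p in pats) {
    o <- order(p$pos)
    k <- length(p$pos)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) {
      pk <- paste(p$pos[o][i], p$pos[o][i + 1L],
                  p$base[o][i], p$base[o][i + 1L], sep = "|")
      tk <- paste(p$pos[o][i], p$pos[o][i + 1L], sep = "|")
      bump(sup, pk, p$support)
      bump(tot, tk, p$support)
    }
  }
  removed <- vapply(pats, function(p) {
    o <- order(p$pos)
    k <- length(p$pos)
    if (k < 2L) return(FALSE)
    for (i in seq_len(k - 1L)) {
      pk <- paste(p$pos[o][i], p$pos[o][i + 1L],
                  p$base[o][i], p$base[o][i + 1L], sep = "|")
      tk <- paste(p$pos[o][i], p$pos[o][i + 1L], sep = "|")
      if (get(pk, sup) / get(tk, tot) < min_frac) return(TRUE)
    }
    FALSE
  }, TRUE)
  list(kept = pats[!removed], removed = pats[removed])
}

## embedding removal with unique-maximal-container support merge
oracle_embedding <- function(pats) {
  n <- length(pats)
  sitestr <- lapply(pats, function(p) paste0(p$pos, ":", p$base))
  emb_in <- function(i, j) {
    length(sitestr[[i]]) < length(sitestr[[j]]) &&
      all(sitestr[[i]] %in% sitestr[[j]])
  }
  embedded <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) i != j && emb_in(i, j), TRUE))
  }, TRUE)
  kept <- pats[!embedded]
  keptidx <- which(!embedded)
  for (i in which(embedded)) {
    containers <- keptidx[vapply(keptidx, function(j) emb_in(i, j), TRUE)]
    if (length(containers) == 1L) {
      ki <- match(containers, keptidx)
      kept[[ki]]$support <- kept[[ki]]$support + pats[[i]]$support
    }
  }
  list(kept = kept, removed = pats[embedded])
}

## step-4 sweeps, straight from the textual semantics
oracle_step4 <- function(pats, hsps) {
  ## pats: list(pos, base, identity); returns list(assigned df, discarded idx)
  live <- seq_along(pats)
  assigned <- data.frame(pos = integer(), base = character(),
                         stringsAsFactors = FALSE)
  discarded <- integer()
  repeat {
    newly <- data.frame(pos = integer(), base = character(),
                        stringsAsFactors = FALSE)
    unpos <- setdiff(sort(unique(unlist(lapply(pats[live], `[[`, "pos")))),
                     assigned$pos)
    unpos <- intersect(unpos, hsps)
    for (p in unpos) {
      tab <- list()
      for (i in live) {
        hit <- which(pats[[i]]$pos == p)
        if (length(hit) == 0L) next
        b <- pats[[i]]$base[hit]
        idn <- pats[[i]]$identity
        if (is.null(tab[[b]]) || idn > tab[[b]]) tab[[b]] <- idn
      }
      if (length(tab) == 0L) next
      if (length(tab) == 1L) {
        newly <- rbind(newly, data.frame(pos = p, base = names(tab)))
      } else {
        v <- unlist(tab)
        o <- order(-v)
        if (v[o[1L]] > v[o[2L]]) {
          newly <- rbind(newly,
                         data.frame(pos = p, base = names(v)[o[1L]]))
        }
      }
    }
    if (nrow(newly) == 0L) break
    assigned <- rbind(assigned, newly)
    contr <- live[vapply(live, function(i) {
      hit <- match(assigned$pos, pats[[i]]$pos)
      any(!is.na(hit) & pats[[i]]$base[hit] != assigned$base)
    }, TRUE)]
    discarded <- c(discarded, contr)
    live <- setdiff(live, contr)
  }
  assigned <- assigned[order(assigned$pos), , drop = FALSE]
  rownames(assigned) <- NULL
  list(assigned = assigned, discarded = sort(discarded))
}

## ---- random instance generator (fixed alphabet, small sizes) --------

rand_instance <- function(max_hsps = 5L, max_pats = 8L) {
  n_hsps <- sample.int(max_hsps, 1L)
  hsps <- sort(sample.int(60L, n_hsps))
  n_pats <- sample.int(max_pats, 1L)
  pats <- lapply(seq_len(n_pats), function(i) {
    k <- sample.int(n_hsps, 1L)
    pos <- sort(sample(hsps, k))
    list(pos = pos,
         base = sample(c("A", "C", "G", "T"), k, replace = TRUE),
         support = sample.int(5L, 1L),
         identity = sample(seq(0, 1, by = 0.25), 1L))
  })
  list(hsps = hsps, pats = pats)
}

## merge duplicate patterns the way pattern construction would
merge_duplicate_pats <- function(pats) {
  keys <- vapply(pats, function(p)
    paste(paste0(p$pos, ":", p$base), collapse = ";"), "")
  out <- list()
  for (k in unique(keys)) {
    grp <- pats[keys == k]
    m <- grp[[1L]]
    m$support <- sum(vapply(grp, `[[`, 1L, "support"))
    out[[length(out) + 1L]] <- m
  }
  out
}

## ---- tiny SAM writer for I/O tests -----------------------------------

write_test_sam <- function(path, records, refname = "insilico_ref",
                           reflen = 1000L) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", refname, reflen))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, pos, seq, mapq = 60L,
                       rname = "insilico_ref", rnext = "=", pnext = 1L,
                       tlen = 0L, tags = character()) {
  f <- paste(qname, flag, rname, pos, mapq,
             paste0(nchar(seq), "M"), rnext, pnext, tlen, seq,
             strrep("I", nchar(seq)), sep = "\t")
  if (length(tags)) f <- paste(c(f, tags), collapse = "\t")
  f
}

## ---- small end-to-end fixture ----------------------------------------

## worked-example gene: 100 bp, HSPs at 5, 12, 40, 55, 92 with allele
## sets A/C, C/T, C/G, A/C/T, C/G planted across three subgenomes
worked_example_sim <- function(error_rate = 0, coverage = 30) {
  set.seed(404)
  L <- 100L
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  hsp_pos <- c(5L, 12L, 40L, 55L, 92L)
  alleles <- list(A = c("A", "C", "C", "A", "C"),
                  B = c("C", "T", "G", "C", "G"),
                  D = c("C", "C", "C", "T", "C"))
  ref[hsp_pos] <- c("A", "C", "C", "A", "C")  # reference shows one allele
  subg <- lapply(alleles, function(a) {
    s <- ref
    s[hsp_pos] <- a
    list(geneX = paste(s, collapse = ""))
  })
  cfg <- sim_config(n_genes = 1L, gene_length_range = c(L, L),
                    read_length = 30L, fragment_mean = 60,
                    fragment_sd = 0, coverage_per_subgenome = coverage,
                    sequencing_error_rate = error_rate,
                    expression_silencing_prob = 0,
                    uniform_coverage = TRUE, distant_genome = "B",
                    seed = 11L)
  sim_from_genomes(list(geneX = paste(ref, collapse = "")),
                   subgenomes = subg, config = cfg)
}

## run the full file-based pipeline for a sim object; returns list with
## the assignment table and evaluation report
run_pipeline <- function(sim, dir = tempfile("fix"), ...) {
  paths <- simulate_reads_and_alignments(sim, dir)
  g <- sim$config$genomes
  tbl <- assign_subgenome_bases(
    sam = paths$sam, hsp_list = paths$hsp_list,
    diploid_lists = setNames(unlist(paths[paste0("sbs_", g)]), g),
    intervals = paths$intervals,
    depth_tables = setNames(unlist(paths[paste0("depth_", g)]), g),
    distant_genome = sim$config$distant_genome, ...)
  ev <- evaluate_against_truth(tbl, read_truth_table(paths$truth),
                               read_truth_table(paths$expressed))
  list(paths = paths, table = tbl, eval = ev)
}
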