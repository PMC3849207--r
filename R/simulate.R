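## Synthetic allopolyploid fixtures with known truth.
##
## The generator emulates, at desk scale, the structure of a hexaploid
## transcriptome experiment: a common ancestral gene set diverges into
## three subgenomes; each subgenome has an extant diploid relative (one
## deliberately more diverged, modelling a distant progenitor-relative);
## paired-end reads with uniform sequencing errors are drawn per
## expressed (gene, subgenome); alignments are emitted at their true
## coordinates (ideal aligner); and variant lists come from a simple
## majority pileup honouring the standard coverage/ambiguity filters.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 50 genes of 1-2 kb, 2% per-site subgenome divergence from the
#' ancestor, diploid relatives at 0.5% extra divergence except the
#' distant B relative at 2%, 75 bp paired-end reads at 30x coverage per
#' subgenome with 0.5% per-base sequencing error.
#'
#' @param n_genes number of genes.
#' @param gene_length_range integer length-2 vector, min/max gene length.
#' @param subgenome_divergence per-site substitution probability from the
#'   ancestor, per subgenome.
#' @param diploid_extra_divergence named numeric, per-site substitution
#'   probability of each diploid relative from its subgenome; the names
#'   define the subgenome labels.
#' @param distant_genome label of the subgenome whose relative is distant
#'   (`NULL` for none).
#' @param read_length read length in bp.
#' @param fragment_mean,fragment_sd fragment-size distribution (bp).
#' @param coverage_per_subgenome expected fold coverage contributed by
#'   each subgenome (and by each diploid's own sequencing run).
#' @param sequencing_error_rate per-base substitution error probability.
#' @param expression_silencing_prob probability that a (gene, subgenome)
#'   pair is transcriptionally silenced and contributes no reads.
#' @param spacer_len `N`-spacer length of the in silico reference.
#' @param uniform_coverage when `TRUE`, fragments are tiled
#'   deterministically so every position of every gene is covered in
#'   every subgenome (idealised sequencing; no random start positions).
#' @param min_allele_frac allele fraction for the majority pileup caller.
#' @param seed integer seed; the whole fixture is a pure function of this
#'   configuration.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 50L,
                       gene_length_range = c(1000L, 2000L),
                       subgenome_divergence = 0.02,
                       diploid_extra_divergence = c(A = 0.005, B = 0.02,
                                                    D = 0.005),
                       distant_genome = "B",
                       read_length = 75L,
                       fragment_mean = 300,
                       fragment_sd = 30,
                       coverage_per_subgenome = 30,
                       sequencing_error_rate = 0.005,
                       expression_silencing_prob = 0.05,
                       spacer_len = 200L,
                       uniform_coverage = FALSE,
                       min_allele_frac = 0.2,
                       seed = 1L) {
  stopifnot(n_genes >= 1L, length(gene_length_range) == 2L,
            gene_length_range[1L] >= 1L,
            gene_length_range[1L] <= gene_length_range[2L],
            read_length >= 1L, fragment_mean >= read_length,
            fragment_sd >= 0, coverage_per_subgenome > 0)
  stop_if_not_scalar_prob(subgenome_divergence, "subgenome_divergence")
  stop_if_not_scalar_prob(sequencing_error_rate, "sequencing_error_rate")
  stop_if_not_scalar_prob(expression_silencing_prob,
                          "expression_silencing_prob")
  stop_if_not_scalar_prob(min_allele_frac, "min_allele_frac")
  if (is.null(names(diploid_extra_divergence)) ||
      any(!nzchar(names(diploid_extra_divergence)))) {
    stop("'diploid_extra_divergence' must be named by subgenome label")
  }
  for (v in diploid_extra_divergence) {
    stop_if_not_scalar_prob(v, "diploid_extra_divergence")
  }
  if (!is.null(distant_genome) &&
      !distant_genome %in% names(diploid_extra_divergence)) {
    stop("'distant_genome' is not one of the subgenome labels")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  structure(list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    subgenome_divergence = subgenome_divergence,
    diploid_extra_divergence = diploid_extra_divergence,
    genomes = names(diploid_extra_divergence),
    distant_genome = distant_genome,
    read_length = as.integer(read_length),
    fragment_mean = fragment_mean,
    fragment_sd = fragment_sd,
    coverage_per_subgenome = coverage_per_subgenome,
    sequencing_error_rate = sequencing_error_rate,
    expression_silencing_prob = expression_silencing_prob,
    spacer_len = as.integer(spacer_len),
    uniform_coverage = isTRUE(uniform_coverage),
    min_allele_frac = min_allele_frac,
    seed = seed
  ), class = "sim_config")
}

## uniform random substitutions (Jukes-Cantor-like, no indels)
mutate_bases <- function(bases, p) {
  if (p <= 0) return(bases)
  hit <- which(stats::runif(length(bases)) < p)
  if (length(hit)) {
    ## draw one of the three alternative bases
    alt <- matrix(BASES[t(vapply(bases[hit],
                                 function(b) which(BASES != b),
                                 integer(3L)))], ncol = 3L)
    bases[hit] <- alt[cbind(seq_along(hit),
                            sample.int(3L, length(hit), replace = TRUE))]
  }
  bases
}

#' Simulate ancestor, subgenomes and diploid relatives
#'
#' Draws a random ancestral sequence per gene, derives each subgenome by
#' independent per-site substitution at `subgenome_divergence`, and each
#' diploid relative from its subgenome at that genome's
#' `diploid_extra_divergence`.  HSPs (the ground truth) are exactly the
#' positions where the subgenomes do not all carry the same base.
#' Silencing flags are drawn here as well.  The ancestor gene set serves
#' as the in silico reference.
#'
#' @param config a [sim_config()] object.
#' @return object of class `subgenome_sim`: a list with `config`,
#'   `reference` (DNAStringSet), `intervals`, `ancestor`, `subgenomes`,
#'   `diploids` (named lists of per-gene base-character vectors), `truth`
#'   (data.table: `gene_id`, `sequence_name`, `position`, one true-base
#'   column per subgenome) and `expressed` (data.table: `gene_id`,
#'   `genome`, `expressed`).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lens <- seq.int(config$gene_length_range[1L],
                  config$gene_length_range[2L])
  glens <- lens[sample.int(length(lens), config$n_genes, replace = TRUE)]
  ids <- sprintf("gene%03d", seq_len(config$n_genes))
  ancestor <- lapply(glens, function(L) sample(BASES, L, replace = TRUE))
  names(ancestor) <- ids
  subgenomes <- lapply(config$genomes, function(g) {
    x <- lapply(ancestor, mutate_bases, p = config$subgenome_divergence)
    names(x) <- ids
    x
  })
  names(subgenomes) <- config$genomes
  diploids <- lapply(config$genomes, function(g) {
    x <- lapply(subgenomes[[g]], mutate_bases,
                p = config$diploid_extra_divergence[[g]])
    names(x) <- ids
    x
  })
  names(diploids) <- config$genomes
  expressed <- data.table::CJ(gene_id = ids, genome = config$genomes)
  expressed[, expressed :=
              stats::runif(.N) >= config$expression_silencing_prob]
  assemble_sim(config, ancestor, subgenomes, diploids, expressed)
}

#' Build a simulation object from hand-specified genomes
#'
#' Constructs the same `subgenome_sim` object as [simulate_genomes()],
#' but from explicitly supplied sequences, for planted-truth scenarios
#' (e.g. a small worked-example gene with chosen allele sets).
#'
#' @param reference_genes named list (or named character vector) of
#'   reference gene sequences.
#' @param subgenomes named list (one per subgenome label) of lists of
#'   gene sequences matching `reference_genes` in names and lengths.
#' @param diploids like `subgenomes`; defaults to the subgenomes
#'   themselves (faithful relatives).
#' @param config a [sim_config()] object (sequence-generation fields are
#'   ignored; read/coverage/error fields are used downstream).
#' @return `subgenome_sim` object.
#' @export
sim_from_genomes <- function(reference_genes, subgenomes,
                             diploids = subgenomes, config) {
  stopifnot(inherits(config, "sim_config"))
  force(diploids)  # default refers to `subgenomes`, reassigned below
  tochars <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      strsplit(toupper(x), "")[[1L]]
    } else {
      toupper(as.character(x))
    }
  }
  ids <- names(reference_genes)
  stopifnot(!is.null(ids), all(nzchar(ids)))
  ancestor <- lapply(reference_genes, tochars)
  names(ancestor) <- ids
  conv <- function(gset) {
    out <- lapply(ids, function(id) {
      v <- tochars(gset[[id]])
      stopifnot(length(v) == length(ancestor[[id]]))
      v
    })
    names(out) <- ids
    out
  }
  subgenomes <- lapply(subgenomes, conv)
  diploids <- lapply(diploids, conv)
  stopifnot(identical(names(subgenomes), config$genomes),
            identical(names(diploids), config$genomes))
  expressed <- data.table::CJ(gene_id = ids, genome = config$genomes)
  expressed[, expressed := TRUE]
  assemble_sim(config, ancestor, subgenomes, diploids, expressed)
}

## shared tail of the two constructors: reference, intervals, truth
assemble_sim <- function(config, ancestor, subgenomes, diploids,
                         expressed) {
  ids <- names(ancestor)
  genes <- vapply(ancestor, paste, "", collapse = "")
  ref <- build_insilico_reference(genes, config$spacer_len)
  iv <- ref$intervals
  refname <- names(ref$reference)
  truth <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    mat <- vapply(config$genomes, function(g) subgenomes[[g]][[id]],
                  character(length(ancestor[[id]])))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
    isdiff <- rowSums(mat != mat[, 1L]) > 0L
    if (!any(isdiff)) next
    loc <- which(isdiff)
    tr <- data.table(gene_id = id, sequence_name = refname,
                     position = iv$start[i] + loc - 1L)
    for (g in config$genomes) tr[, (g) := mat[loc, g]]
    truth[[i]] <- tr
  }
  truth <- data.table::rbindlist(truth[!vapply(truth, is.null, TRUE)])
  if (nrow(truth) == 0L) {
    truth <- data.table(gene_id = character(), sequence_name = character(),
                        position = integer())
    for (g in config$genomes) truth[, (g) := character()]
  }
  structure(list(config = config, reference = ref$reference,
                 intervals = iv, ancestor = ancestor,
                 subgenomes = subgenomes, diploids = diploids,
                 truth = truth, expressed = expressed),
            class = "subgenome_sim")
}

#' @export
print.subgenome_sim <- function(x, ...) {
  cat(sprintf(
    "<subgenome_sim: %d gene(s), %d subgenome(s), %d truth HSP(s), seed %d>\n",
    nrow(x$intervals), length(x$subgenomes), nrow(x$truth),
    x$config$seed))
  invisible(x)
}

## ---------------------------------------------------------------------
## read generation and majority pileup

## paired fragments for one gene sequence; returns data.table with one
## row per mate: qname, mate, start (local), seqtext (error-injected)
sim_gene_reads <- function(bases, gene_id, label, config) {
  L <- length(bases)
  rl <- min(config$read_length, L)
  npairs <- max(1L, as.integer(ceiling(
    config$coverage_per_subgenome * L / (2 * rl))))
  if (config$uniform_coverage) {
    frag <- as.integer(min(config$fragment_mean, L))
    starts <- unique(as.integer(round(
      seq(1L, L - frag + 1L, length.out = npairs))))
    frags <- rep.int(frag, length(starts))
  } else {
    frags <- as.integer(round(stats::rnorm(npairs, config$fragment_mean,
                                           config$fragment_sd)))
    frags <- pmin(pmax(frags, rl), L)
    starts <- as.integer(floor(stats::runif(npairs) * (L - frags + 1))) + 1L
  }
  n <- length(starts)
  s1 <- starts
  s2 <- starts + frags - rl
  qn <- sprintf("%s_%s_%05d", label, gene_id, seq_len(n))
  seqstr <- paste(bases, collapse = "")
  r1 <- substring(seqstr, s1, s1 + rl - 1L)
  r2 <- substring(seqstr, s2, s2 + rl - 1L)
  dt <- data.table(
    qname = rep(qn, 2L),
    mate = rep(1:2, each = n),
    start = c(s1, s2),
    seqtext = inject_errors(c(r1, r2), config$sequencing_error_rate)
  )
  dt[, `:=`(gene_id = gene_id, rl = rl,
            frag = rep(frags, 2L), fstart = rep(s1, 2L))]
  dt
}

## uniform per-base substitution errors; error sites drawn with
## replacement (double hits at one site are vanishingly rare and harmless)
inject_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  rl <- nchar(reads)
  nerr <- stats::rbinom(length(reads), rl, rate)
  tot <- sum(nerr)
  if (tot == 0L) return(reads)
  idx <- rep.int(seq_along(reads), nerr)
  at <- as.integer(floor(stats::runif(tot) * rl[idx])) + 1L
  cur <- substring(reads[idx], at, at)
  altm <- matrix(c(2L, 3L, 4L, 1L, 3L, 4L, 1L, 2L, 4L, 1L, 2L, 3L),
                 nrow = 4L, byrow = TRUE)
  newb <- BASES[altm[cbind(match(cur, BASES),
                           sample.int(3L, tot, replace = TRUE))]]
  for (j in seq_len(tot)) {
    substr(reads[idx[j]], at[j], at[j]) <- newb[j]
  }
  reads
}

## per-position base counts (4 x L matrix) from a read table of one gene
pileup_counts <- function(reads, L) {
  if (nrow(reads) == 0L) return(matrix(0L, nrow = 4L, ncol = L))
  rl <- nchar(reads$seqtext)
  pos <- rep(reads$start, rl) + sequence(rl) - 1L
  b <- unlist(strsplit(reads$seqtext, "", fixed = TRUE), use.names = FALSE)
  bi <- match(b, BASES)
  ok <- !is.na(bi) & pos >= 1L & pos <= L
  idx <- (pos[ok] - 1L) * 4L + bi[ok]
  matrix(tabulate(idx, 4L * L), nrow = 4L)
}

## majority caller on a count matrix: returns per-position list columns
## cov, alleles (qualifying bases)
qualifying_alleles <- function(cnt, min_allele_frac) {
  cov <- colSums(cnt)
  qual <- cnt >= 2L & sweep(cnt, 2L, pmax(cov, 1L), "/") >= min_allele_frac
  list(cov = cov, qual = qual)
}

#' Simulate reads, alignments and variant lists for a fixture
#'
#' Generates paired-end reads for every expressed (gene, subgenome) of
#' the polyploid and for each diploid relative, writes an ideal-aligner
#' SAM against the concatenated reference, and calls variants by simple
#' majority pileup: polyploid HSPs are positions with at least two
#' alleles each seen in >= 2 reads at >= `min_allele_frac` of the
#' coverage (consensus is the IUPAC code of the allele set); diploid
#' substitutions are positions whose call differs from the reference,
#' with heterozygous-looking positions emitted as ambiguous IUPAC calls.
#' Per-position diploid depth at the HSP positions is written alongside.
#'
#' @param sim `subgenome_sim` object.
#' @param dir output directory (created if needed).
#' @return named list of file paths: `reference`, `genes`, `intervals`,
#'   `sam`, `hsp_list`, per-genome `sbs_<G>` and `depth_<G>`, `truth`,
#'   `expressed`.
#' @export
simulate_reads_and_alignments <- function(sim, dir) {
  stopifnot(inherits(sim, "subgenome_sim"))
  config <- sim$config
  set.seed(config$seed + 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  iv <- sim$intervals
  refname <- names(sim$reference)
  reflen <- Biostrings::width(sim$reference)[1L]
  ids <- iv$gene_id

  ## --- polyploid reads -------------------------------------------------
  exp_dt <- sim$expressed
  poly_reads <- vector("list", 0L)
  for (g in config$genomes) {
    for (i in seq_along(ids)) {
      id <- ids[i]
      if (!exp_dt[gene_id == id & genome == g, expressed]) next
      rd <- sim_gene_reads(sim$subgenomes[[g]][[id]], id,
                           paste0("poly", g), config)
      poly_reads[[length(poly_reads) + 1L]] <- rd
    }
  }
  poly_reads <- data.table::rbindlist(poly_reads)

  ## --- diploid reads ---------------------------------------------------
  dip_reads <- list()
  for (g in config$genomes) {
    rds <- lapply(seq_along(ids), function(i) {
      sim_gene_reads(sim$diploids[[g]][[ids[i]]], ids[i],
                     paste0("dip", g), config)
    })
    dip_reads[[g]] <- data.table::rbindlist(rds)
  }

  ## --- SAM for the polyploid -------------------------------------------
  sam_path <- file.path(dir, "polyploid.sam")
  write_sim_sam(poly_reads, iv, refname, reflen, sam_path)

  ## --- variant calling -------------------------------------------------
  hsp_rows <- vector("list", length(ids))
  dip_cnts <- lapply(config$genomes, function(g) vector("list", length(ids)))
  names(dip_cnts) <- config$genomes
  for (i in seq_along(ids)) {
    id <- ids[i]
    L <- iv$length[i]
    cnt <- pileup_counts(poly_reads[gene_id == id], L)
    qa <- qualifying_alleles(cnt, config$min_allele_frac)
    nallele <- colSums(qa$qual)
    call <- which(nallele >= 2L & qa$cov >= 3L)
    if (length(call)) {
      cons <- vapply(call, function(p)
        bases_to_iupac(BASES[qa$qual[, p]]), "")
      hsp_rows[[i]] <- data.table(
        sequence_name = refname,
        position = iv$start[i] + call - 1L,
        ref_base = vapply(call, function(p) sim$ancestor[[id]][p], ""),
        consensus = cons,
        quality = 60,
        coverage = as.integer(qa$cov[call])
      )
    }
    for (g in config$genomes) {
      dip_cnts[[g]][[i]] <- pileup_counts(dip_reads[[g]][gene_id == id], L)
    }
  }
  hsps <- data.table::rbindlist(hsp_rows[!vapply(hsp_rows, is.null, TRUE)])
  if (nrow(hsps) == 0L) {
    hsps <- data.table(sequence_name = character(), position = integer(),
                       ref_base = character(), consensus = character(),
                       quality = numeric(), coverage = integer())
  }
  hsp_path <- file.path(dir, "hsp_list.tsv")
  write_variant_list(hsps, hsp_path)

  ## --- diploid substitution lists and depth at HSP positions -----------
  paths <- list(
    reference = file.path(dir, "reference.fasta"),
    genes = file.path(dir, "genes.fasta"),
    intervals = file.path(dir, "intervals.tsv"),
    sam = sam_path, hsp_list = hsp_path
  )
  for (g in config$genomes) {
    sbs_rows <- vector("list", length(ids))
    dep_rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      id <- ids[i]
      L <- iv$length[i]
      cnt <- dip_cnts[[g]][[i]]
      qa <- qualifying_alleles(cnt, config$min_allele_frac)
      nallele <- colSums(qa$qual)
      refb <- sim$ancestor[[id]]
      ## call: majority base, ambiguous when >= 2 qualifying alleles
      maj <- BASES[max.col(t(cnt), ties.method = "first")]
      callable <- which(qa$cov >= 3L & nallele >= 1L)
      cons <- character(L)
      for (p in callable) {
        cons[p] <- if (nallele[p] >= 2L) {
          bases_to_iupac(BASES[qa$qual[, p]])
        } else {
          BASES[qa$qual[, p]]
        }
      }
      isvar <- callable[cons[callable] != refb[callable]]
      if (length(isvar)) {
        sbs_rows[[i]] <- data.table(
          sequence_name = refname,
          position = iv$start[i] + isvar - 1L,
          ref_base = refb[isvar],
          consensus = cons[isvar],
          quality = 60,
          coverage = as.integer(qa$cov[isvar])
        )
      }
      ghsp <- hsps[position >= iv$start[i] & position <= iv$end[i],
                   position]
      if (length(ghsp)) {
        loc <- ghsp - iv$start[i] + 1L
        dep_rows[[i]] <- data.table(sequence_name = refname,
                                    position = ghsp,
                                    depth = as.integer(qa$cov[loc]))
      }
    }
    sbs <- data.table::rbindlist(sbs_rows[!vapply(sbs_rows, is.null, TRUE)])
    if (nrow(sbs) == 0L) {
      sbs <- data.table(sequence_name = character(), position = integer(),
                        ref_base = character(), consensus = character(),
                        quality = numeric(), coverage = integer())
    }
    dep <- data.table::rbindlist(dep_rows[!vapply(dep_rows, is.null, TRUE)])
    if (nrow(dep) == 0L) {
      dep <- data.table(sequence_name = character(), position = integer(),
                        depth = integer())
    }
    paths[[paste0("sbs_", g)]] <- file.path(dir, paste0("sbs_", g, ".tsv"))
    paths[[paste0("depth_", g)]] <-
      file.path(dir, paste0("depth_", g, ".tsv"))
    write_variant_list(sbs, paths[[paste0("sbs_", g)]])
    write_depth_table(dep, paths[[paste0("depth_", g)]])
  }

  ## --- remaining artefacts ---------------------------------------------
  Biostrings::writeXStringSet(sim$reference, paths$reference)
  genes <- Biostrings::DNAStringSet(
    vapply(sim$ancestor, paste, "", collapse = ""))
  Biostrings::writeXStringSet(genes, paths$genes)
  write_gene_intervals(iv, paths$intervals)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$expressed <- file.path(dir, "expressed.tsv")
  utils::write.table(sim$expressed, paths$expressed, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

## serialize the simulated read table as a proper paired-end SAM file
write_sim_sam <- function(reads, iv, refname, reflen, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", refname, reflen),
           sprintf("@PG\tID:homeoassign-sim\tPN:homeoassign\tVN:%s",
                   as.character(utils::packageVersion("homeoassign"))))
  if (nrow(reads) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  gstart <- setNames(iv$start, iv$gene_id)
  off <- gstart[reads$gene_id] - 1L
  gpos <- reads$start + off
  fstart_g <- reads$fstart + off
  mate2_start <- fstart_g + reads$frag - reads$rl
  flag <- ifelse(reads$mate == 1L, 99L, 147L)
  pnext <- ifelse(reads$mate == 1L, mate2_start, fstart_g)
  tlen <- ifelse(reads$mate == 1L, reads$frag, -reads$frag)
  rec <- data.table(
    qname = reads$qname, flag = flag, rname = refname, pos = gpos,
    mapq = 60L, cigar = paste0(nchar(reads$seqtext), "M"),
    rnext = "=", pnext = pnext, tlen = tlen, seq = reads$seqtext,
    qual = vapply(nchar(reads$seqtext),
                  function(n) strrep("I", n), "")
  )
  data.table::setorder(rec, pos, qname)
  writeLines(hdr, path)
  data.table::fwrite(rec, path, sep = "\t", col.names = FALSE,
                     append = TRUE, quote = FALSE)
  invisible(path)
}
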