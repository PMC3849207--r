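## Pattern-to-genome assignment (step 3), iterative base assignment
## (step 4) and discarded-pattern rescue (step 5).

test_that("pattern scoring counts informative diploid sites only", {
  prof <- make_profile(c(5L, 12L, 40L, 55L),
                       base = c("A", "C", "G", "T"))
  pat <- data.frame(pos = c(5L, 12L, 40L, 55L),
                    base = c("A", "C", "C", "A"))
  sc <- score_pattern(pat, prof)
  expect_equal(sc$identity, 0.5)        # 2 of 4 informative match
  expect_equal(sc$informative_sites, 4L)
  pat2 <- data.frame(pos = c(5L, 12L, 40L), base = c("A", "C", "G"))
  expect_equal(score_pattern(pat2, prof)$identity, 1.0)
  ## low-coverage sites drop out of the denominator
  prof2 <- make_profile(c(5L, 12L, 40L, 55L),
                        base = c("A", "C", "G", "T"),
                        coverage = c(30L, 30L, 2L, 2L))
  sc2 <- score_pattern(pat, prof2)
  expect_equal(sc2$informative_sites, 2L)
  expect_equal(sc2$identity, 1.0)
  ## no informative site: identity undefined
  prof3 <- make_profile(c(5L, 12L), base = c("A", "C"), coverage = 0L)
  expect_true(is.na(score_pattern(pat2, prof3)$identity))
})

test_that("patterns are assigned per genome at the 50% threshold", {
  profs <- list(
    A = make_profile(c(1L, 2L, 3L, 4L), c("A", "C", "G", "T")),
    B = make_profile(c(1L, 2L, 3L, 4L), c("C", "G", "T", "A")),
    D = make_profile(c(1L, 2L, 3L, 4L), c("A", "C", "T", "A")))
  bp <- bp_from_list(list(
    list(pos = 1:4, base = c("A", "C", "A", "C"), support = 5L)))
  asg <- assign_patterns_to_genomes(bp, profs)
  ## identity: A 2/4 = 0.5 (assigned, "at least 50%"), B 0/4, D 2/4
  expect_setequal(asg$genome, c("A", "D"))
  expect_equal(unique(asg$identity), 0.5)
})

test_that("a pattern can be assigned to several genomes (no argmax)", {
  profs <- list(
    A = make_profile(1:2, c("A", "C")),
    D = make_profile(1:2, c("A", "C")))
  bp <- bp_from_list(list(
    list(pos = 1:2, base = c("A", "C"), support = 1L)))
  asg <- assign_patterns_to_genomes(bp, profs)
  expect_setequal(asg$genome, c("A", "D"))
})

test_that("unassignable patterns fall to the designated distant genome", {
  profs <- list(
    A = make_profile(1:4, c("A", "C", "G", "T")),
    B = make_profile(1:4, c("C", "G", "T", "A")),
    D = make_profile(1:4, c("G", "T", "A", "C")))
  bp <- bp_from_list(list(
    list(pos = 1:4, base = c("T", "A", "C", "G"), support = 2L)))
  none <- assign_patterns_to_genomes(bp, profs)
  expect_equal(nrow(none), 0L)
  asg <- assign_patterns_to_genomes(bp, profs, distant_genome = "B")
  expect_equal(asg$genome, "B")
  expect_true(asg$via_distant)
  expect_error(assign_patterns_to_genomes(bp, profs,
                                          distant_genome = "Z"),
               "distant_genome")
})

test_that("raising min_identity never adds assignments (monotonicity)", {
  set.seed(321)
  for (rep in 1:30) {
    inst <- rand_instance()
    pats <- merge_duplicate_pats(inst$pats)
    bp <- bp_from_list(pats)
    profs <- list(
      A = make_profile(inst$hsps,
                       sample(c("A", "C", "G", "T"), length(inst$hsps),
                              replace = TRUE)),
      D = make_profile(inst$hsps,
                       sample(c("A", "C", "G", "T"), length(inst$hsps),
                              replace = TRUE)))
    lo <- assign_patterns_to_genomes(bp, profs, min_identity = 0.3)
    hi <- assign_patterns_to_genomes(bp, profs, min_identity = 0.7)
    lo_set <- paste(lo$key, lo$genome)
    hi_set <- paste(hi$key, hi$genome)
    expect_true(all(hi_set %in% lo_set))
  }
})

gp <- function(bp, keys, ids) {
  data.table::as.data.table(list(key = keys, identity = ids,
                                 support = rep(1L, length(keys))))
}

test_that("a single live pattern assigns all its bases", {
  bp <- bp_from_list(list(
    list(pos = c(5L, 12L), base = c("A", "C"), support = 1L)))
  res <- assign_bases_iteratively(gp(bp, bp$patterns$key, 0.9), bp,
                                  hsps = c(5L, 12L))
  expect_equal(res$assigned$pos, c(5L, 12L))
  expect_equal(res$assigned$base, c("A", "C"))
  expect_equal(res$discarded, character())
})

test_that("higher-identity nucleotide wins and contradictions cascade", {
  ## P1 (id 0.9): 40:C, 55:A ; P2 (id 0.6): 40:G, 92:G ; P3 (id 0.7): 92:C
  pats <- list(
    list(pos = c(40L, 55L), base = c("C", "A"), support = 3L),
    list(pos = c(40L, 92L), base = c("G", "G"), support = 2L),
    list(pos = 92L, base = "C", support = 1L))
  bp <- bp_from_list(pats)
  keys <- vapply(pats, function(p) pkey(p$pos, p$base), "")
  gpat <- gp(bp, keys, c(0.9, 0.6, 0.7))
  res <- assign_bases_iteratively(gpat, bp, hsps = c(40L, 55L, 92L))
  ## sweep 1: 40 -> C (0.9 beats 0.6), 55 -> A, 92 tied? no: G(0.6) vs
  ## C(0.7) -> C; P2 then contradicts 40 and is removed
  expect_equal(res$assigned[res$assigned$pos == 40L, ]$base, "C")
  expect_equal(res$assigned[res$assigned$pos == 92L, ]$base, "C")
  expect_equal(res$discarded, keys[2L])
})

test_that("an identity tie across nucleotides leaves the position open", {
  pats <- list(
    list(pos = 40L, base = "C", support = 5L),
    list(pos = 40L, base = "G", support = 5L))
  bp <- bp_from_list(pats)
  keys <- vapply(pats, function(p) pkey(p$pos, p$base), "")
  res <- assign_bases_iteratively(gp(bp, keys, c(0.8, 0.8)), bp, 40L)
  expect_equal(nrow(res$assigned), 0L)
})

test_that("step-4 sweeps match the brute-force oracle on random input", {
  set.seed(5150)
  for (rep in 1:150) {
    inst <- rand_instance()
    pats <- merge_duplicate_pats(inst$pats)
    bp <- bp_from_list(pats)
    keys <- vapply(pats, function(p) pkey(p$pos, p$base), "")
    ids <- vapply(pats, `[[`, 1, "identity")
    res <- assign_bases_iteratively(gp(bp, keys, ids), bp, inst$hsps)
    want <- oracle_step4(pats, inst$hsps)
    expect_equal(as.data.frame(res$assigned[, c("pos", "base")]),
                 want$assigned, ignore_attr = TRUE)
    expect_setequal(res$discarded, unique(keys[want$discarded]))
    ## termination bound: productive sweeps never exceed |hsps|
    expect_lte(res$sweeps, length(inst$hsps))
  }
})

test_that("rescue fills unassigned positions from discarded patterns", {
  assigned <- data.table::as.data.table(list(
    pos = c(5L, 12L, 40L), base = c("A", "C", "G"),
    src_identity = c(0.9, 0.9, 0.9)))
  disc <- bp_from_list(list(
    list(pos = c(5L, 12L, 40L, 55L), base = c("A", "C", "G", "T"),
         support = 2L)))
  out <- rescue_with_discarded(disc, assigned)
  expect_equal(out[out$pos == 55L, ]$base, "T")   # 3/3 match, 4th gained
})

test_that("rescue never downgrades an assignment (strictly-better rule)", {
  assigned <- data.table::as.data.table(list(
    pos = c(5L, 12L), base = c("A", "C"), src_identity = c(0.9, 0.9)))
  disc <- bp_from_list(list(
    list(pos = c(5L, 12L), base = c("A", "T"), support = 50L)))
  out <- rescue_with_discarded(disc, assigned)   # identity vs assigned 0.5
  expect_equal(out[out$pos == 12L, ]$base, "C")
  ## and with no discarded patterns, assignments are untouched
  none <- build_base_patterns(empty_aln(), integer())
  expect_identical(as.data.frame(rescue_with_discarded(none, assigned)),
                   as.data.frame(assigned))
})

test_that("rescue replaces a base only on strictly better identity", {
  assigned <- data.table::as.data.table(list(
    pos = c(5L, 12L, 40L, 55L), base = c("A", "C", "G", "T"),
    src_identity = c(0.9, 0.9, 0.9, 0.5)))
  ## discarded pattern matches 3 of 4 assigned -> identity 0.75 > 0.5 at 55
  disc <- bp_from_list(list(
    list(pos = c(5L, 12L, 40L, 55L), base = c("A", "C", "G", "C"),
         support = 1L)))
  out <- rescue_with_discarded(disc, assigned)
  expect_equal(out[out$pos == 55L, ]$base, "C")
  expect_equal(out[out$pos == 5L, ]$base, "A")
})

test_that("characterize_gene marks uninformative-diploid positions", {
  ## genome B's diploid has zero coverage everywhere
  profs <- list(
    A = make_profile(c(5L, 12L), c("A", "C")),
    B = make_profile(c(5L, 12L), c("A", "C"), coverage = 0L),
    D = make_profile(c(5L, 12L), c("C", "T")))
  aln <- make_aln(
    make_mate("a1", 1L, paste0("GGGGA", "GGGGGG", "C", strrep("G", 8)), 1L),
    make_mate("d1", 1L, paste0("GGGGC", "GGGGGG", "T", strrep("G", 8)), 1L),
    ## matches neither diploid: the distant genome's own haplotype
    make_mate("b1", 1L, paste0("GGGGT", "GGGGGG", "G", strrep("G", 8)), 1L))
  cells <- characterize_gene(aln, c(5L, 12L), profs)
  bcells <- cells[cells$genome == "B", ]
  expect_true(all(bcells$state == "DIPLOID_LOW_COV"))
  ## with B designated distant, the orphan pattern assigns bases to B
  cells2 <- characterize_gene(aln, c(5L, 12L), profs,
                              distant_genome = "B")
  b2 <- cells2[cells2$genome == "B", ]
  expect_equal(b2$state, c("ASSIGNED", "ASSIGNED"))
  expect_equal(b2$base, c("T", "G"))
})

test_that("genes with zero HSPs yield empty output", {
  profs <- list(A = make_profile(integer(), character()))
  cells <- characterize_gene(empty_aln(), integer(), profs)
  expect_equal(nrow(cells), 0L)
})
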