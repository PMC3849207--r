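## Pattern construction (step 1) and cleaning filters (step 2).

test_that("identical read-pair patterns merge with summed support", {
  aln <- make_aln(
    make_mate("p1", 1L, strrep("A", 20), 1L),
    make_mate("p1", 30L, strrep("A", 20), 2L),
    make_mate("p2", 1L, strrep("A", 20), 1L),
    make_mate("p2", 30L, strrep("A", 20), 2L)
  )
  bp <- build_base_patterns(aln, hsps = c(5L, 12L, 35L))
  expect_equal(nrow(bp$patterns), 1L)
  expect_equal(bp$patterns$support, 2L)
  expect_equal(bp$sites$pos, c(5L, 12L, 35L))
})

test_that("mate discrepancy at a shared HSP discards the whole pair", {
  ## mates overlap at positions 10..19; HSP at 12 disagrees (C vs T)
  aln <- make_aln(
    make_mate("bad", 1L, paste0(strrep("A", 11), "C", strrep("A", 7)), 1L),
    make_mate("bad", 10L, paste0("AA", "T", strrep("A", 12)), 2L),
    make_mate("good", 1L, strrep("A", 19), 1L),
    make_mate("good", 10L, strrep("A", 15), 2L)
  )
  bp <- build_base_patterns(aln, hsps = c(5L, 12L))
  expect_equal(nrow(bp$patterns), 1L)
  expect_equal(bp$patterns$key, "5:A;12:A")
  expect_equal(bp$patterns$support, 1L)  # agreeing overlap counted once
})

test_that("N at an HSP drops the site, not the pattern", {
  aln <- make_aln(
    make_mate("p", 1L, paste0("AAAA", "N", strrep("A", 10)), 1L))
  bp <- build_base_patterns(aln, hsps = c(5L, 12L))
  expect_equal(bp$patterns$key, "12:A")
})

test_that("read pairs overlapping no HSP yield no pattern", {
  aln <- make_aln(make_mate("p", 100L, strrep("A", 20), 1L))
  bp <- build_base_patterns(aln, hsps = c(5L, 12L))
  expect_equal(nrow(bp$patterns), 0L)
})

test_that("worked-example gene produces the expected four-site pattern", {
  ## HSPs at 5, 12, 40, 55, 92; a pair spanning 1-60 shows A,C,C,A
  s <- strrep("G", 60)
  substr(s, 5, 5) <- "A"; substr(s, 12, 12) <- "C"
  substr(s, 40, 40) <- "C"; substr(s, 55, 55) <- "A"
  aln <- make_aln(
    make_mate("pair", 1L, substr(s, 1, 30), 1L),
    make_mate("pair", 31L, substr(s, 31, 60), 2L))
  bp <- build_base_patterns(aln, hsps = c(5L, 12L, 40L, 55L, 92L))
  expect_equal(bp$patterns$key, "5:A;12:C;40:C;55:A")
})

test_that("error filter removes patterns with a rare adjacent base pair", {
  pats <- list(
    list(pos = c(5L, 12L), base = c("A", "C"), support = 50L),
    list(pos = c(5L, 12L), base = c("A", "T"), support = 2L))
  res <- filter_error_patterns(bp_from_list(pats), 0.05)
  ## 2 / 52 = 3.8% < 5% -> removed
  expect_equal(res$removed$patterns$key, "5:A;12:T")
  expect_equal(res$kept$patterns$key, "5:A;12:C")
})

test_that("pair-fraction boundary: < 5% removed, exactly 5% retained", {
  at_threshold <- list(
    list(pos = c(5L, 12L), base = c("A", "T"), support = 1L),
    list(pos = c(5L, 12L), base = c("G", "C"), support = 19L))
  res <- filter_error_patterns(bp_from_list(at_threshold), 0.05)
  expect_equal(nrow(res$removed$patterns), 0L)  # 1/20 = 5.0% retained
  below <- list(
    list(pos = c(5L, 12L), base = c("A", "T"), support = 49L),
    list(pos = c(5L, 12L), base = c("G", "C"), support = 951L))
  res2 <- filter_error_patterns(bp_from_list(below), 0.05)
  expect_equal(res2$removed$patterns$key, "5:A;12:T")  # 4.9% removed
})

test_that("error filter edge cases behave as specified", {
  pats <- list(
    list(pos = c(5L, 12L), base = c("A", "C"), support = 1000L),
    list(pos = 5L, base = "T", support = 1L))        # single site
  ## single-site patterns are never removed by the pair rule
  res <- filter_error_patterns(bp_from_list(pats), 0.05)
  expect_equal(nrow(res$removed$patterns), 0L)
  ## a zero threshold removes nothing
  many <- list(
    list(pos = c(5L, 12L), base = c("A", "C"), support = 1L),
    list(pos = c(5L, 12L), base = c("T", "G"), support = 999L))
  expect_equal(nrow(filter_error_patterns(bp_from_list(many),
                                          0)$removed$patterns), 0L)
  expect_error(filter_error_patterns(bp_from_list(many), 1.5), "\\[0, 1\\]")
})

test_that("consecutive means consecutive within the pattern's sites", {
  ## pattern skipping HSP 12 pairs 5 with 40 directly
  pats <- list(
    list(pos = c(5L, 40L), base = c("A", "G"), support = 1L),
    list(pos = c(5L, 40L), base = c("C", "T"), support = 99L))
  res <- filter_error_patterns(bp_from_list(pats), 0.05)
  expect_equal(res$removed$patterns$key, "5:A;40:G")
})

test_that("embedded pattern merges support into a unique container", {
  pats <- list(
    list(pos = 5L, base = "A", support = 7L),
    list(pos = c(5L, 12L), base = c("A", "C"), support = 10L))
  res <- remove_embedded_patterns(bp_from_list(pats))
  expect_equal(res$kept$patterns$key, "5:A;12:C")
  expect_equal(res$kept$patterns$support, 17L)
  expect_equal(res$removed$patterns$key, "5:A")
  expect_equal(res$removed$patterns$support, 7L)
})

test_that("embedded pattern with competing containers loses its support", {
  pats <- list(
    list(pos = 5L, base = "A", support = 7L),
    list(pos = c(5L, 12L), base = c("A", "C"), support = 10L),
    list(pos = c(5L, 12L), base = c("A", "T"), support = 4L))
  res <- remove_embedded_patterns(bp_from_list(pats))
  expect_setequal(res$kept$patterns$key, c("5:A;12:C", "5:A;12:T"))
  expect_equal(sum(res$kept$patterns$support), 14L)   # 7 discarded
})

test_that("non-nested patterns of equal length are both kept", {
  pats <- list(
    list(pos = c(5L, 12L), base = c("A", "C"), support = 3L),
    list(pos = c(5L, 12L), base = c("C", "C"), support = 2L))
  res <- remove_embedded_patterns(bp_from_list(pats))
  expect_equal(nrow(res$kept$patterns), 2L)
  expect_equal(nrow(res$removed$patterns), 0L)
})

test_that("embedding removal reaches a fixpoint (idempotent)", {
  set.seed(101)
  for (rep in 1:25) {
    inst <- rand_instance()
    bp <- bp_from_list(inst$pats)
    once <- remove_embedded_patterns(bp)$kept
    twice <- remove_embedded_patterns(once)$kept
    expect_identical(bp_canon(once), bp_canon(twice))
    ## no kept pattern is a strict sub-pattern of another
    keys <- strsplit(once$patterns$key, ";", fixed = TRUE)
    for (i in seq_along(keys)) {
      for (j in seq_along(keys)) {
        if (i == j) next
        expect_false(length(keys[[i]]) < length(keys[[j]]) &&
                       all(keys[[i]] %in% keys[[j]]))
      }
    }
  }
})

test_that("step-2 filters match the brute-force oracle on random input", {
  set.seed(2024)
  for (rep in 1:150) {
    inst <- rand_instance()
    pats <- merge_duplicate_pats(inst$pats)
    bp <- bp_from_list(pats)
    ## error filter
    got <- filter_error_patterns(bp, 0.05)
    want <- oracle_pair_filter(pats, 0.05)
    expect_identical(bp_canon(got$kept), bp_canon(bp_from_list(want$kept)))
    expect_identical(bp_canon(got$removed),
                     bp_canon(bp_from_list(want$removed)))
    ## embedding removal
    got2 <- remove_embedded_patterns(bp)
    want2 <- oracle_embedding(pats)
    expect_identical(bp_canon(got2$kept),
                     bp_canon(bp_from_list(want2$kept)))
    expect_identical(bp_canon(got2$removed),
                     bp_canon(bp_from_list(want2$removed)))
  }
})

test_that("filters conserve read support up to documented discards", {
  set.seed(77)
  for (rep in 1:40) {
    inst <- rand_instance()
    pats <- merge_duplicate_pats(inst$pats)
    bp <- bp_from_list(pats)
    total <- sum(bp$patterns$support)
    ef <- filter_error_patterns(bp, 0.05)
    ## error filter only partitions support
    expect_equal(sum(ef$kept$patterns$support) +
                   sum(ef$removed$patterns$support), total)
    em <- remove_embedded_patterns(ef$kept)
    ## embedding keeps at most the filtered total (multi-container
    ## support is discarded, never duplicated)
    expect_lte(sum(em$kept$patterns$support),
               sum(ef$kept$patterns$support))
    want <- oracle_embedding(bp_to_list(ef$kept))
    expect_equal(sum(em$kept$patterns$support),
                 sum(vapply(want$kept, `[[`, 1L, "support")))
  }
})
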