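one_anchor_map <- function(orientation = "+") {
  synteny_map("A", "B", data.frame(
    src_chrom = "s1", src_start = 0L, src_end = 1000L,
    tgt_chrom = "t1", tgt_start = 5000L, tgt_end = 6000L,
    orientation = orientation))
}

test_that("positions inside a forward anchor interpolate proportionally", {
  cand <- locate_bounds(one_anchor_map("+"), "s1", 100L, 200L)
  expect_true(cand$ok)
  expect_equal(cand$chrom, "t1")
  expect_equal(cand$start, 5100L)
  expect_equal(cand$end, 5200L)
  expect_equal(cand$orientation, "+")
  expect_false(cand$widened)
})

test_that("reverse anchors mirror the arithmetic", {
  cand <- locate_bounds(one_anchor_map("-"), "s1", 100L, 200L)
  expect_equal(cand$start, 5800L)
  expect_equal(cand$end, 5900L)
  expect_equal(cand$orientation, "-")
})

test_that("translation is monotone inside an anchor", {
  mf <- one_anchor_map("+"); mr <- one_anchor_map("-")
  pos_f <- vapply(seq(0L, 990L, by = 10L), function(p)
    locate_bounds(mf, "s1", p, p + 1L)$start, integer(1L))
  pos_r <- vapply(seq(0L, 990L, by = 10L), function(p)
    locate_bounds(mr, "s1", p, p + 1L)$start, integer(1L))
  expect_true(all(diff(pos_f) > 0L))
  expect_true(all(diff(pos_r) < 0L))
})

test_that("no anchor on the scaffold is an explicit failure", {
  r <- locate_bounds(one_anchor_map(), "nowhere", 0L, 10L)
  expect_false(r$ok)
  expect_equal(r$reason, "no-anchor")
})

test_that("binary-search lookup equals the linear-scan oracle", {
  m <- random_anchor_map(300, seed = 21)
  set.seed(22)
  qs <- sort(sample.int(600000L, 2000L)) - 1L
  anchors_df <- as.data.frame(m$anchors)
  for (q in qs) {
    got <- locate_bounds(m, "s1", q, q + 50L)
    want1 <- oracle_resolve(anchors_df, "s1", q)
    want2 <- oracle_resolve(anchors_df, "s1", q + 49L)
    if (is.null(want1) || is.null(want2)) { expect_false(got$ok); next }
    expect_true(got$ok)
    cross <- want1$chrom != want2$chrom
    expect_equal(got$cross_scaffold, cross)
    if (!cross) {
      expect_equal(got$start, min(want1$lo, want2$lo))
      expect_equal(got$end, max(want1$hi, want2$hi))
      expect_equal(got$chrom, want1$chrom)
    }
  }
})

test_that("two exact hops compose into a net shift", {
  mAB <- synteny_map("A", "B", data.frame(
    src_chrom = "s1", src_start = 0L, src_end = 10000L,
    tgt_chrom = "s1", tgt_start = 1000L, tgt_end = 11000L, orientation = "+"))
  mBC <- synteny_map("B", "C", data.frame(
    src_chrom = "s1", src_start = 0L, src_end = 20000L,
    tgt_chrom = "s1", tgt_start = 200L, tgt_end = 20200L, orientation = "+"))
  g <- build_graph(c("A", "B", "C"), list(mAB, mBC))
  p <- translation_path(g, "A", "C")
  r <- translate_through_path(g, p, "s1", 500L, 700L)
  expect_true(r$ok)
  expect_equal(length(r$candidates), 1L)
  expect_equal(r$candidates[[1L]]$start, 500L + 1000L + 200L)
  expect_equal(r$candidates[[1L]]$end, 700L + 1000L + 200L)
  # reverse composed with reverse is forward
  mABr <- synteny_map("A", "B", data.frame(
    src_chrom = "s1", src_start = 0L, src_end = 10000L,
    tgt_chrom = "s1", tgt_start = 0L, tgt_end = 10000L, orientation = "-"))
  mBCr <- synteny_map("B", "C", data.frame(
    src_chrom = "s1", src_start = 0L, src_end = 10000L,
    tgt_chrom = "s1", tgt_start = 0L, tgt_end = 10000L, orientation = "-"))
  g2 <- build_graph(c("A", "B", "C"), list(mABr, mBCr))
  r2 <- translate_through_path(g2, translation_path(g2, "A", "C"),
                               "s1", 500L, 700L)
  expect_equal(r2$candidates[[1L]]$orientation, "+")
  expect_equal(r2$candidates[[1L]]$start, 500L)
})

test_that("identity path returns the input interval", {
  fx <- identity_fixture()
  g <- build_graph(names(fx$genomes), fx$maps)
  p <- translation_path(g, "A", "B")
  r <- translate_through_path(g, p, "s1", 1234L, 1534L)
  expect_equal(r$candidates[[1L]]$start, 1234L)
  expect_equal(r$candidates[[1L]]$end, 1534L)
})

test_that("round trip through the inverted map contains the original", {
  fx <- small_chain_fixture()
  mAB <- fx$maps[["A-B"]]
  g <- build_graph(c("A", "B"), list(mAB))
  pab <- translation_path(g, "A", "B")
  pba <- translation_path(g, "B", "A")
  set.seed(17)
  lens <- scaffold_lengths(fx$genomes$A)
  tested <- 0L
  for (i in 1:100) {
    ch <- sample(names(lens), 1L)
    s <- sample.int(lens[[ch]] - 300L, 1L)
    fwd <- translate_through_path(g, pab, ch, s, s + 200L)
    if (!fwd$ok || length(fwd$candidates) != 1L || fwd$candidates[[1L]]$widened)
      next
    c1 <- fwd$candidates[[1L]]
    back <- translate_through_path(g, pba, c1$chrom, c1$start, c1$end)
    if (!back$ok || length(back$candidates) != 1L) next
    c2 <- back$candidates[[1L]]
    expect_equal(c2$chrom, ch)
    expect_lte(c2$start, s)
    expect_gte(c2$end, s + 200L)
    tested <- tested + 1L
  }
  expect_gt(tested, 30L)
})

test_that("candidates pass, split at spans, and split across scaffolds", {
  mk_cand <- function(chrom1, lo1, chrom2, lo2, span, ori1 = "+", ori2 = "+") {
    structure(list(ok = TRUE, genome = "B",
                   chrom = if (chrom1 == chrom2) chrom1 else NA_character_,
                   start = lo1, end = lo1 + span,
                   orientation = ori1,
                   consistent = chrom1 == chrom2 && ori1 == ori2,
                   cross_scaffold = chrom1 != chrom2, widened = TRUE,
                   bounds = list(
                     list(chrom = chrom1, lo = lo1, hi = lo1 + 10L,
                          orient = ori1, widened = TRUE),
                     list(chrom = chrom2, lo = lo2, hi = lo1 + span,
                          orient = ori2, widened = TRUE)),
                   split_side = "none"), class = "candidate_interval")
  }
  # 80,000 nt consistent: unchanged
  out <- check_and_split(mk_cand("t1", 1000L, "t1", 70000L, 80000L))
  expect_equal(length(out), 1L)
  expect_equal(out[[1L]]$split_side, "none")
  expect_equal(out[[1L]]$end - out[[1L]]$start, 80000L)
  # 300,000 nt: two 50,000 nt candidates, one per side
  out <- check_and_split(mk_cand("t1", 1000L, "t1", 280000L, 300000L))
  expect_equal(length(out), 2L)
  expect_equal(vapply(out, `[[`, "", "split_side"), c("left", "right"))
  expect_true(all(vapply(out, function(c) c$end - c$start, integer(1L)) ==
                    50000L))
  expect_equal(out[[1L]]$start, 1000L)              # anchored at left bound
  expect_equal(out[[2L]]$end, 1000L + 300000L)      # anchored at right bound
  # cross-scaffold bounds: always split, regardless of span
  out <- check_and_split(mk_cand("t1", 1000L, "t2", 2000L, 5000L))
  expect_equal(length(out), 2L)
  expect_equal(out[[1L]]$chrom, "t1")
  expect_equal(out[[2L]]$chrom, "t2")
  # inconsistent orientation on one scaffold: split too
  out <- check_and_split(mk_cand("t1", 1000L, "t1", 40000L, 50000L,
                                 ori1 = "+", ori2 = "-"))
  expect_equal(length(out), 2L)
})

test_that("substitution-only candidates always contain the truth", {
  fx <- cached("subonly_contain", function() evolve(evolution_spec(
    ancestor_length = 80000L, n_scaffolds = 1L, n_genomes = 2L,
    topology = "chain", sub_rate = 0.05, indel_rate = 0,
    n_inversions = 0L, n_duplications = 0L, n_genes = 5L, seed = 303L)))
  g <- build_graph(names(fx$genomes), fx$maps)
  p <- translation_path(g, "A", "B")
  blocks <- sample_blocks(fx$genomes$A, 200, 200, seed = 8)
  tm <- fx$root_truth$B
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i]
    truth <- truth_map_interval(tm, b$chrom, b$start, b$end)
    r <- translate_through_path(g, p, b$chrom, b$start, b$end)
    expect_true(r$ok)
    c1 <- r$candidates[[1L]]
    expect_equal(c1$chrom, truth$chrom)
    expect_lte(c1$start, truth$start)
    expect_gte(c1$end, truth$end)
  }
})
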