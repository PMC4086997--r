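# exact binomial tail values P(X >= k), X ~ Binomial(n, 1/4), computed
# once with an arbitrary-precision rational oracle and frozen here
exact_binom_tails <- list(
  list(n = 50L, k = 50L, p = 7.88860905221011805411728565283e-31),
  list(n = 50L, k = 20L, p = 0.0139176086786606648007189816030),
  list(n = 100L, k = 40L, p = 0.000686592207962991070185196934832),
  list(n = 100L, k = 25L, p = 0.538328867918588568259652308937),
  list(n = 120L, k = 50L, p = 0.0000469624283658730738655257432414),
  list(n = 200L, k = 60L, p = 0.0624722310564640471346675366798),
  list(n = 80L, k = 30L, p = 0.00893967429330317722863783454780),
  list(n = 100L, k = 100L, p = 6.22301527786114170714406405378e-61),
  list(n = 64L, k = 16L, p = 0.547868935595775080688195272528),
  list(n = 150L, k = 55L, p = 0.00100364777309221133821008193635))

test_that("identical sequences align full length with zero offsets", {
  set.seed(71)
  s <- rand_dna(100)
  a <- banded_affine_align(s, s)
  expect_equal(a$score, 100)
  expect_equal(a$k_start, 0L)
  expect_equal(a$k_end, 0L)
  expect_equal(a$matches, 100L)
  expect_equal(a$length, 100L)
  expect_true(a$accepted)
})

test_that("a central mismatch costs one mismatch, no gaps", {
  set.seed(73)
  s <- rand_dna(100)
  t <- s
  mid <- substr(s, 50, 50)
  substr(t, 50, 50) <- setdiff(c("A", "C", "G", "T"), mid)[1L]
  a <- banded_affine_align(s, t)
  expect_equal(a$score, 99 - 1)
  expect_equal(a$length, 100L)
  expect_equal(a$matches, 99L)
})

test_that("alignment score is symmetric for symmetric schemes", {
  set.seed(79)
  for (i in 1:20) {
    a <- rand_dna(120); b <- rand_dna(120)
    expect_equal(banded_affine_align(a, b)$score,
                 banded_affine_align(b, a)$score)
  }
})

test_that("banded scores equal the full-matrix Gotoh when in-band", {
  set.seed(83)
  # substitution-only pairs: the optimal path is the centered diagonal,
  # inside the band by construction
  for (i in 1:120) {
    m <- sample(40:200, 1L)
    a <- rand_dna(m)
    b <- strsplit(a, "")[[1L]]
    nm <- sample(m, max(1L, rpois(1L, m * 0.1)), replace = FALSE)
    b[nm] <- vapply(b[nm], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1L))
    b <- paste(b, collapse = "")
    expect_equal(banded_affine_align(a, b, band_center = 0L)$score,
                 oracle_gotoh_score(a, b))
  }
})

test_that("banded scores never exceed the unbanded optimum", {
  set.seed(89)
  for (i in 1:60) {
    a <- rand_dna(sample(50:200, 1L))
    b <- rand_dna(sample(50:200, 1L))
    expect_lte(banded_affine_align(a, b)$score, oracle_gotoh_score(a, b))
  }
})

test_that("binomial tail p-values match the exact oracle to 1e-9", {
  for (cs in exact_binom_tails) {
    expect_equal(alignment_pvalue(cs$k, cs$n), cs$p, tolerance = 1e-9)
  }
  # chance-level matching is not significant
  expect_gt(alignment_pvalue(25L, 100L), 0.5)
  # p decreases monotonically in matches at fixed length
  ps <- vapply(10:100, alignment_pvalue, numeric(1L), length = 100L)
  expect_true(all(diff(ps) < 0))
})

test_that("acceptance flips exactly at the 1e-4 threshold", {
  # at length 100, 43 matches is the first count at or below 1e-4
  expect_lte(alignment_pvalue(43L, 100L), 1e-4)
  expect_gt(alignment_pvalue(42L, 100L), 1e-4)
  s <- scoring_scheme()
  expect_equal(s$pvalue_threshold, 1e-4)
})

test_that("scoring schemes validate penalty ordering", {
  expect_error(scoring_scheme(mismatch = 0.5), "gap_open")
  expect_error(scoring_scheme(gap_open = -0.5, mismatch = -1), "gap_open")
  expect_silent(scoring_scheme(match = 2, mismatch = -2, gap_open = -5))
})

test_that("refinement recovers exact coordinates, adjusting clipped ends", {
  set.seed(97)
  src <- rand_dna(300)
  lead <- 5000L
  genome <- genome_seq("T", c(t1 = paste0(rand_dna(lead), src, rand_dna(4000))))
  cand <- structure(list(ok = TRUE, genome = "T", chrom = "t1",
                         start = lead - 700L, end = lead + 300L + 900L,
                         orientation = "+", consistent = TRUE,
                         cross_scaffold = FALSE, widened = TRUE,
                         bounds = NULL, split_side = "none"),
                    class = "candidate_interval")
  r <- refine_feature(src, list(cand), genome)
  expect_true(r$ok)
  expect_equal(r$start, lead)
  expect_equal(r$end, lead + 300L)
  expect_equal(r$k_start, 0L)

  # corrupt the first 5 source bases: the alignment clips them and the
  # reported start is adjusted back by -k
  src2 <- src
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
  for (i in 1:5) substr(src2, i, i) <- flip(substr(src, i, i))
  r2 <- refine_feature(src2, list(cand), genome)
  expect_true(r2$ok)
  expect_equal(r2$k_start, 5L)
  expect_equal(r2$start, lead)
  expect_equal(r2$end, lead + 300L)
})

test_that("reverse-orientation features map back to forward coordinates", {
  set.seed(101)
  src <- rand_dna(250)
  lead <- 3000L
  genome <- genome_seq("T", c(t1 = paste0(rand_dna(lead), revcomp(src),
                                          rand_dna(3000))))
  cand <- structure(list(ok = TRUE, genome = "T", chrom = "t1",
                         start = lead - 500L, end = lead + 250L + 500L,
                         orientation = "-", consistent = TRUE,
                         cross_scaffold = FALSE, widened = TRUE,
                         bounds = NULL, split_side = "none"),
                    class = "candidate_interval")
  r <- refine_feature(src, list(cand), genome)
  expect_true(r$ok)
  expect_equal(r$chrom, "t1")
  expect_equal(r$start, lead)
  expect_equal(r$end, lead + 250L)
  expect_equal(r$orientation, "-")
})

test_that("short sources align whole; failures name the failing end", {
  set.seed(103)
  src <- rand_dna(80)
  genome <- genome_seq("T", c(t1 = paste0(rand_dna(500), src, rand_dna(500))))
  cand <- structure(list(ok = TRUE, genome = "T", chrom = "t1",
                         start = 300L, end = 900L, orientation = "+",
                         consistent = TRUE, cross_scaffold = FALSE,
                         widened = TRUE, bounds = NULL, split_side = "none"),
                    class = "candidate_interval")
  r <- refine_feature(src, list(cand), genome)
  expect_true(r$ok)
  expect_equal(r$start, 500L)
  expect_equal(r$end, 580L)
  # an unrelated source is rejected, not mis-placed
  bad <- refine_feature(rand_dna(300), list(cand), genome)
  expect_false(bad$ok)
  expect_match(bad$reason, "rejected")
})
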