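# Shared simulated fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small chain fixture with all mutation types, for module-level tests
small_chain_fixture <- function() {
  cached("small_chain", function() {
    evolve(evolution_spec(
      ancestor_length = 120000L, n_scaffolds = 2L, n_genomes = 3L,
      topology = "chain", sub_rate = 0.05, indel_rate = 2e-4,
      n_inversions = 1L, inversion_size = c(2000L, 8000L),
      n_duplications = 1L, duplication_size = c(500L, 2000L),
      n_genes = 12L, seed = 401L))
  })
}

# identity fixture: no mutations at all
identity_fixture <- function() {
  cached("identity", function() {
    evolve(evolution_spec(
      ancestor_length = 40000L, n_scaffolds = 2L, n_genomes = 3L,
      topology = "star", sub_rate = 0, indel_rate = 0,
      n_inversions = 0L, n_duplications = 0L, n_genes = 8L, seed = 402L))
  })
}

# random anchor set on one scaffold for lookup tests: non-overlapping
# source intervals, shuffled target placement, mixed orientation
random_anchor_map <- function(n_anchors, seed, src_len = 500000L) {
  set.seed(seed)
  starts <- sort(sample.int(src_len - 2000L, n_anchors))
  starts <- starts + seq(0L, by = 2000L, length.out = n_anchors)
  lens <- sample(100:1500, n_anchors, replace = TRUE)
  tgt_starts <- sample.int(10 * src_len, n_anchors)
  tlens <- pmax(50L, as.integer(round(lens * runif(n_anchors, 0.7, 1.3))))
  anchors <- data.table::data.table(
    src_chrom = "s1", src_start = starts, src_end = starts + lens,
    tgt_chrom = sample(c("t1", "t2"), n_anchors, replace = TRUE, prob = c(.9, .1)),
    tgt_start = tgt_starts, tgt_end = tgt_starts + tlens,
    orientation = sample(c("+", "-"), n_anchors, replace = TRUE))
  synteny_map("A", "B", anchors)
}
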