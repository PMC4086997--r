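test_that("FASTA reading loads, case-folds and sanitizes records", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT"), p)
  g <- read_fasta(p, "g1")
  expect_identical(unname(g$scaffolds["s1"]), "ACGT")

  writeLines(c(">s1", "acgn", ">s2", "TT"), p)
  g <- read_fasta(p, "g1")
  expect_identical(unname(g$scaffolds), c("ACGN", "TT"))
  expect_identical(names(g$scaffolds), c("s1", "s2"))

  writeLines(c(">s1", "ACGT", ">s1", "TT"), p)
  expect_error(read_fasta(p), "duplicate")
})

test_that("FASTA writing round-trips a generated multi-scaffold genome", {
  set.seed(7)
  g <- genome_seq("g", c(a = rand_dna(300), b = rand_dna(75), c = rand_dna(1)))
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, p)
  g2 <- read_fasta(p, "g")
  expect_identical(g2$scaffolds, g$scaffolds)
})

test_that("synteny map rows convert 1-based inclusive to half-open", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\t101\t200\td1\t501\t600\t+",
               "c1\t301\t400\td1\t701\t800\t-"), p)
  m <- read_synteny_map(p, "A", "B", "lastz_general")
  expect_equal(m$anchors$src_start, c(100L, 300L))
  expect_equal(m$anchors$src_end, c(200L, 400L))
  expect_equal(m$anchors$tgt_start, c(500L, 700L))
  expect_equal(m$anchors$tgt_end, c(600L, 800L))
  expect_equal(m$anchors$orientation, c("+", "-"))
})

test_that("satsuma dialect finds the orientation token after identity", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("c1\t11\t20\td2\t31\t40\t0.97\t-", p)
  m <- read_synteny_map(p, "A", "B", "satsuma")
  expect_equal(m$anchors$orientation, "-")
  expect_equal(m$anchors$tgt_start, 30L)
})

test_that("malformed rows abort with line numbers unless downgraded", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\t101\t200\td1\t501\t600\t+",
               "c1\tnot\ta\tgood\trow"), p)
  expect_error(read_synteny_map(p, "A", "B"), "line")
  expect_warning(m <- read_synteny_map(p, "A", "B", skip_bad_rows = TRUE),
                 "skipped")
  expect_equal(nrow(m$anchors), 1L)
})

test_that("a large generated map matches an independent line parse", {
  set.seed(11)
  n <- 1000L
  starts <- sort(sample.int(5e6, n))
  anchors <- data.table::data.table(
    src_chrom = sample(c("c1", "c2"), n, TRUE),
    src_start = starts, src_end = starts + sample(50:900, n, TRUE),
    tgt_chrom = sample(c("d1", "d2"), n, TRUE),
    tgt_start = starts + 17L, tgt_end = starts + 17L + sample(50:900, n, TRUE),
    orientation = sample(c("+", "-"), n, TRUE))
  m <- synteny_map("A", "B", anchors)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_synteny_map(m, p, "lastz_general")
  m2 <- read_synteny_map(p, "A", "B", "lastz_general")
  expect_equal(nrow(m2$anchors), n)
  # reference parse: split each line by hand and undo the convention
  ref <- do.call(rbind, lapply(readLines(p), function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    data.frame(src_chrom = f[1], src_start = as.integer(f[2]) - 1L,
               src_end = as.integer(f[3]), tgt_chrom = f[4],
               tgt_start = as.integer(f[5]) - 1L, tgt_end = as.integer(f[6]),
               orientation = f[7])
  }))
  ref <- ref[order(ref$src_chrom, ref$src_start, ref$src_end), ]
  expect_equal(as.data.frame(m2$anchors), ref, ignore_attr = TRUE)
})

test_that("invert_map is an involution that swaps sides", {
  m <- synteny_map("A", "B", data.frame(
    src_chrom = "c", src_start = 100L, src_end = 200L,
    tgt_chrom = "d", tgt_start = 500L, tgt_end = 600L, orientation = "+"))
  inv <- invert_map(m)
  expect_equal(inv$src_genome, "B")
  expect_equal(inv$anchors$src_start, 500L)
  expect_equal(inv$anchors$tgt_start, 100L)
  expect_equal(inv$anchors$orientation, "+")
  back <- invert_map(inv)
  expect_equal(back$anchors, m$anchors)
  expect_equal(nrow(inv$anchors), nrow(m$anchors))
})

test_that("GTF parsing groups exons into transcripts and loci", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "# comment",
    paste0("s1\tsrc\texon\t11\t20\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "g1.t1"; extra "kept";'),
    paste0("s1\tsrc\texon\t111\t140\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "g1.t1";'),
    "s1\tsrc\tCDS\t11\t20\t.\t+\t0\tgene_id \"g1\"; transcript_id \"g1.t1\";"),
    p)
  fh <- read_gtf(p)
  expect_equal(nrow(fh$loci), 1L)
  expect_equal(nrow(fh$transcripts), 1L)
  expect_equal(nrow(fh$exons), 2L)
  expect_equal(fh$exons$start, c(10L, 110L))   # 1-based inclusive -> half-open
  expect_equal(fh$exons$end, c(20L, 140L))
  expect_match(fh$exons$attrs[1L], 'extra "kept"')
  ex <- exons_of(fh, "g1.t1")
  expect_equal(nrow(ex), 2L)
  expect_equal(transcripts_of(fh, "g1")$transcript_id, "g1.t1")
})

test_that("fixture GTF counts equal the generator manifest", {
  fx <- small_chain_fixture()
  d <- withr::local_tempdir()
  write_fixture(fx, d)
  fh <- read_gtf(file.path(d, "A.gtf"))
  man <- fx$manifest[genome == "A"]
  expect_equal(nrow(fh$exons), nrow(man))
  expect_equal(nrow(fh$transcripts), data.table::uniqueN(man$transcript_id))
  expect_equal(nrow(fh$loci), data.table::uniqueN(man$gene_id))
})

test_that("written outputs round-trip through the GTF reader", {
  fx <- identity_fixture()
  g <- build_graph(names(fx$genomes), fx$maps)
  rt <- run_translate(fx$genomes, g, fx$genes, "A", "B")
  d <- withr::local_tempdir()
  files <- write_outputs(rt$results, NULL, d)
  fh <- read_gtf(files[["translated"]])
  ok <- rt$results[translated == TRUE][order(tgt_chrom, tgt_start)]
  expect_equal(fh$exons$start, ok$tgt_start)
  expect_equal(fh$exons$end, ok$tgt_end)
  # original attributes are preserved verbatim, provenance appended
  expect_true(all(grepl('gene_id "', fh$exons$attrs)))
  expect_true(all(grepl('src_genome "A"', fh$exons$attrs)))
})

test_that("empty result sets still produce a valid GTF with header", {
  res <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), gene_id = character(), transcript_id = character(),
    source = character(), feature = character(), score = character(),
    frame = character(), attrs = character(), translated = logical(),
    tgt_chrom = character(), tgt_start = integer(), tgt_end = integer(),
    tgt_strand = character(), p_value = numeric(), hop_failed = integer(),
    reason = character(), src_genome = character(), path_used = character())
  d <- withr::local_tempdir()
  files <- write_outputs(res, NULL, d)
  expect_match(readLines(files[["translated"]])[1L], "^##")
  fh <- read_gtf(files[["translated"]])
  expect_equal(nrow(fh$exons), 0L)
})

test_that("config files validate genomes and fill parameter defaults", {
  d <- withr::local_tempdir()
  cfgp <- file.path(d, "cfg.yaml")
  writeLines(c(
    "genomes:", "  A: a.fa", "  B: b.fa",
    "maps:",
    "  - source: A", "    target: B", "    path: ab.tsv",
    "    dialect: lastz_general",
    "params:", "  flank_nt: 20"), cfgp)
  cfg <- read_config(cfgp)
  expect_equal(cfg$params$flank_nt, 20L)
  expect_equal(cfg$params$block_log2, 14L)
  expect_equal(cfg$params$pvalue_threshold, 1e-4)
  writeLines(c(
    "genomes:", "  A: a.fa", "  B: b.fa",
    "maps:",
    "  - source: A", "    target: Z", "    path: az.tsv"), cfgp)
  expect_error(read_config(cfgp), "undeclared")
})
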