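# Deterministic genome-evolution simulator: an ancestral genome is
# evolved by inversions and tandem duplications (segment level), then
# small indels, then substitutions, into 2-4 descendant genomes along a
# star, chain or clade topology. Every step updates an exact coordinate
# map, so the simulator emits genomes, exact synteny anchors, planted
# multi-exon gene models and a ground-truth manifest.

#' Specify a genome-evolution simulation
#'
#' Defaults emulate a desk-scale version of a typical liftover
#' validation: ~1 Mb genomes, moderate substitution divergence, a
#' handful of rearrangements, and planted multi-exon gene models.
#'
#' @param ancestor_length total ancestor length, nt.
#' @param n_scaffolds number of scaffolds (ancestor split evenly).
#' @param n_genomes number of genomes including the root (2--4).
#' @param topology `"star"` (all leaves derived from genome 1),
#'   `"chain"` (each genome derived from the previous) or `"clade"`
#'   (two subtrees).
#' @param sub_rate per-site substitution probability per branch.
#' @param indel_rate per-site indel event probability per branch.
#' @param indel_mean_len mean indel length (geometric).
#' @param n_inversions inversions per branch.
#' @param inversion_size length-2 range of inversion sizes, nt.
#' @param n_duplications tandem duplications per branch.
#' @param duplication_size length-2 range of duplication sizes, nt.
#' @param n_genes planted multi-exon genes (in the root genome).
#' @param isoforms_max maximum isoforms per gene.
#' @param anchor_jitter trim/drop emitted anchors to mimic ragged real
#'   synteny maps (see [truth_to_anchors()]); off by default.
#' @param seed integer seed; fixes all outputs.
#' @return an object of class `evolution_spec`.
#' @export
evolution_spec <- function(ancestor_length = 1000000L, n_scaffolds = 2L,
                           n_genomes = 3L,
                           topology = c("chain", "star", "clade"),
                           sub_rate = 0.05, indel_rate = 2e-4,
                           indel_mean_len = 3,
                           n_inversions = 2L, inversion_size = c(5000L, 50000L),
                           n_duplications = 1L,
                           duplication_size = c(1000L, 10000L),
                           n_genes = 60L, isoforms_max = 3L,
                           anchor_jitter = FALSE, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_genomes >= 2L, n_genomes <= 4L,
            sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  structure(list(ancestor_length = as.integer(ancestor_length),
                 n_scaffolds = as.integer(n_scaffolds),
                 n_genomes = as.integer(n_genomes), topology = topology,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_mean_len = indel_mean_len,
                 n_inversions = as.integer(n_inversions),
                 inversion_size = as.integer(inversion_size),
                 n_duplications = as.integer(n_duplications),
                 duplication_size = as.integer(duplication_size),
                 n_genes = as.integer(n_genes),
                 isoforms_max = as.integer(isoforms_max),
                 anchor_jitter = isTRUE(anchor_jitter),
                 seed = as.integer(seed)),
            class = "evolution_spec")
}

# parent of each genome under the configured topology (root = genome 1)
fixture_parents <- function(n_genomes, topology) {
  nm <- LETTERS[seq_len(n_genomes)]
  parents <- switch(topology,
    star  = c(NA, rep(nm[1L], n_genomes - 1L)),
    chain = c(NA, nm[seq_len(n_genomes - 1L)]),
    clade = if (n_genomes < 4L) c(NA, rep(nm[1L], n_genomes - 1L)) else
      c(NA, "A", "A", "C"))
  names(parents) <- nm
  parents
}

# sample a scaffold proportional to (usable) length
sample_scaffold <- function(lens, min_len = 1L) {
  ok <- lens >= min_len
  if (!any(ok)) return(NA_character_)
  w <- ifelse(ok, as.numeric(lens), 0)
  sample(names(lens), 1L, prob = w / sum(w))
}

# one branch of evolution: parent genome_seq -> derived genome_seq plus
# the exact parent->derived truth_map and recorded substitution sites
evolve_branch <- function(parent, child_name, spec) {
  tm <- identity_truth(parent$name, child_name, scaffold_lengths(parent))
  # rearrangements first: coordinate bookkeeping stays layered
  for (i in seq_len(spec$n_inversions)) {
    lens <- vapply(names(parent$scaffolds), function(ch)
      tm_derived_length(tm, ch), integer(1L))
    size <- sample(seq(spec$inversion_size[1L], spec$inversion_size[2L]), 1L)
    ch <- sample_scaffold(lens, min_len = size + 2L)
    if (is.na(ch)) next
    a <- sample.int(lens[[ch]] - size, 1L)
    tm <- tm_apply_inversion(tm, ch, a, a + size)
  }
  for (i in seq_len(spec$n_duplications)) {
    lens <- vapply(names(parent$scaffolds), function(ch)
      tm_derived_length(tm, ch), integer(1L))
    size <- sample(seq(spec$duplication_size[1L], spec$duplication_size[2L]), 1L)
    ch <- sample_scaffold(lens, min_len = size + 2L)
    if (is.na(ch)) next
    a <- sample.int(lens[[ch]] - size, 1L)
    tm <- tm_apply_duplication(tm, ch, a, a + size)
  }
  # then indels
  if (spec$indel_rate > 0) {
    total <- sum(vapply(names(parent$scaffolds), function(ch)
      tm_derived_length(tm, ch), integer(1L)))
    n_ind <- rbinom(1L, total, spec$indel_rate)
    p_geom <- 1 / max(spec$indel_mean_len, 1)
    for (i in seq_len(n_ind)) {
      lens <- vapply(names(parent$scaffolds), function(ch)
        tm_derived_length(tm, ch), integer(1L))
      ch <- sample_scaffold(lens, min_len = 100L)
      len <- 1L + rgeom(1L, p_geom)
      if (runif(1L) < 0.5) {
        a <- sample.int(lens[[ch]] - len - 1L, 1L)
        tm <- tm_apply_deletion(tm, ch, a, a + len)
      } else {
        a <- sample.int(lens[[ch]] - 1L, 1L)
        tm <- tm_apply_insertion(tm, ch, a, len)
      }
    }
  }
  # build the derived sequence from the segment map
  scaffolds <- vapply(names(parent$scaffolds), function(ch) {
    segs <- tm$segs[tgt_chrom == ch][order(tgt_start)]
    if (nrow(segs) == 0L) return("")
    pieces <- vapply(seq_len(nrow(segs)), function(i) {
      r <- segs[i]
      if (r$type == "ins") return(rand_dna(r$tgt_end - r$tgt_start))
      s <- get_seq(parent, r$src_chrom, r$src_start, r$src_end)
      if (r$strand == "-") revcomp(s) else s
    }, character(1L))
    paste(pieces, collapse = "")
  }, character(1L))
  # finally substitutions, recorded per site
  subs <- list()
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (ch in names(scaffolds)) {
    len <- nchar(scaffolds[[ch]])
    k <- rbinom(1L, len, spec$sub_rate)
    if (k == 0L) { subs[[ch]] <- integer(0L); next }
    pos <- sort(sample.int(len, k))
    chars <- strsplit(scaffolds[[ch]], "", fixed = TRUE)[[1L]]
    pick <- sample.int(3L, k, replace = TRUE)
    chars[pos] <- mapply(function(b, j) alt[[b]][j], chars[pos], pick,
                         USE.NAMES = FALSE)
    scaffolds[[ch]] <- paste(chars, collapse = "")
    subs[[ch]] <- pos - 1L  # 0-based
  }
  list(genome = genome_seq(child_name, scaffolds), truth = tm, subs = subs)
}

# plant non-overlapping multi-exon gene models in the root genome
plant_genes <- function(root, spec) {
  lens <- scaffold_lengths(root)
  occupied <- lapply(lens, function(...) data.table::data.table(
    start = integer(), end = integer()))
  rows <- list()
  for (g in seq_len(spec$n_genes)) {
    placed <- FALSE
    for (try in 1:60) {
      n_ex <- sample(2:5, 1L)
      ex_len <- sample(80:300, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(200:1500, n_ex - 1L, replace = TRUE) else integer(0L)
      span <- sum(ex_len) + sum(in_len)
      ch <- sample_scaffold(lens, min_len = span + 2L)
      if (is.na(ch)) break
      gstart <- sample.int(lens[[ch]] - span, 1L)
      gend <- gstart + span
      occ <- occupied[[ch]]
      clash <- nrow(occ) > 0L &&
        occ[, any(end > gstart - 100L & start < gend + 100L)]
      if (clash) next
      occupied[[ch]] <- rbind(occ, data.table::data.table(
        start = gstart, end = gend))
      strand <- sample(c("+", "-"), 1L)
      ex_start <- gstart + c(0L, cumsum(ex_len[-n_ex] + in_len))
      gene_id <- sprintf("gene%03d", g)
      n_iso <- sample.int(spec$isoforms_max, 1L)
      for (iso in seq_len(n_iso)) {
        if (iso == 1L) idx <- seq_len(n_ex) else {
          k <- sample(2:n_ex, 1L)
          s0 <- sample.int(n_ex - k + 1L, 1L)
          idx <- seq(s0, s0 + k - 1L)
        }
        rows[[length(rows) + 1L]] <- data.table::data.table(
          gene_id = gene_id,
          transcript_id = sprintf("%s.t%d", gene_id, iso),
          exon_idx = seq_along(idx),
          chrom = ch, start = ex_start[idx], end = ex_start[idx] + ex_len[idx],
          strand = strand)
      }
      placed <- TRUE
      break
    }
  }
  data.table::rbindlist(rows)
}

#' Simulate genome evolution with exact ground truth
#'
#' Evolves the root genome into descendants per the spec's topology.
#' Mutation order per branch is fixed: rearrangements, then indels,
#' then substitutions, so the coordinate bookkeeping is layered and
#' auditable. Returns everything the rest of the package consumes:
#' genomes, per-edge exact anchor maps, planted gene models carried
#' through the truth map into every genome, and a manifest recording
#' every planted exon's true coordinates (or that it was lost).
#'
#' @param spec an [evolution_spec()].
#' @return an object of class `evolution_fixture` with elements
#'   `genomes` (named list of `genome_seq`), `parents`, `root_truth`
#'   (truth maps root -> genome), `branch` (per-branch truth/subs),
#'   `maps` (tree-edge `synteny_map`s), `genes` (root-coordinate exon
#'   table), `manifest` (per-genome true exon coordinates with status),
#'   and `spec`.
#' @export
evolve <- function(spec) {
  stopifnot(inherits(spec, "evolution_spec"))
  set.seed(spec$seed)
  nm <- LETTERS[seq_len(spec$n_genomes)]
  parents <- fixture_parents(spec$n_genomes, spec$topology)
  per_scaf <- spec$ancestor_length %/% spec$n_scaffolds
  scaffolds <- vapply(seq_len(spec$n_scaffolds), function(i) rand_dna(per_scaf),
                      character(1L))
  names(scaffolds) <- sprintf("s%d", seq_len(spec$n_scaffolds))
  genomes <- list()
  genomes[[nm[1L]]] <- genome_seq(nm[1L], scaffolds)
  genes <- plant_genes(genomes[[nm[1L]]], spec)
  branch <- list()
  for (g in nm[-1L]) {
    br <- evolve_branch(genomes[[parents[[g]]]], g, spec)
    genomes[[g]] <- br$genome
    branch[[g]] <- br
  }
  root_truth <- list()
  root_truth[[nm[1L]]] <- identity_truth(nm[1L], nm[1L],
                                         scaffold_lengths(genomes[[nm[1L]]]))
  for (g in nm[-1L]) {
    p <- parents[[g]]
    root_truth[[g]] <- if (p == nm[1L]) branch[[g]]$truth else
      compose_truth(root_truth[[p]], branch[[g]]$truth)
  }
  maps <- list()
  for (g in nm[-1L]) {
    maps[[paste0(parents[[g]], "-", g)]] <- truth_to_anchors(
      branch[[g]]$truth, jitter = spec$anchor_jitter)
  }
  manifest <- fixture_manifest(genes, root_truth, nm)
  structure(list(genomes = genomes, parents = parents,
                 root_truth = root_truth, branch = branch, maps = maps,
                 genes = genes, manifest = manifest, spec = spec),
            class = "evolution_fixture")
}

# carry each planted exon through the root->genome truth maps
fixture_manifest <- function(genes, root_truth, genome_names) {
  out <- list()
  for (g in genome_names) {
    tm <- root_truth[[g]]
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      r <- genes[i]
      m <- truth_map_interval(tm, r$chrom, r$start, r$end)
      if (is.null(m)) {
        data.table::data.table(genome = g, gene_id = r$gene_id,
          transcript_id = r$transcript_id, exon_idx = r$exon_idx,
          chrom = NA_character_, start = NA_integer_, end = NA_integer_,
          strand = NA_character_, status = "lost")
      } else {
        data.table::data.table(genome = g, gene_id = r$gene_id,
          transcript_id = r$transcript_id, exon_idx = r$exon_idx,
          chrom = m$chrom, start = m$start, end = m$end,
          strand = compose_orient(r$strand, m$strand),
          status = if (m$exact) "exact" else "approx")
      }
    })
    out[[g]] <- data.table::rbindlist(rows)
  }
  data.table::rbindlist(out)
}

#' @export
print.evolution_fixture <- function(x, ...) {
  cat("<evolution_fixture>", length(x$genomes), "genomes (",
      paste(names(x$genomes), collapse = ", "), "), topology",
      x$spec$topology, "-", nrow(x$genes), "planted exon rows\n")
  invisible(x)
}

#' Ground-truth map between any two fixture genomes
#'
#' Composes branch maps through the tree: `u -> root -> v`.
#'
#' @param fixture an `evolution_fixture`.
#' @param u,v genome names.
#' @return a `truth_map` from `u` to `v`.
#' @export
fixture_truth_between <- function(fixture, u, v) {
  root <- names(fixture$genomes)[1L]
  if (u == root) return(fixture$root_truth[[v]])
  if (v == root) return(invert_truth(fixture$root_truth[[u]]))
  compose_truth(invert_truth(fixture$root_truth[[u]]), fixture$root_truth[[v]])
}

#' Exact direct synteny map between any two fixture genomes
#'
#' Useful for direct-versus-indirect experiments: supplies the anchor
#' map a direct whole-genome alignment of `u` and `v` would give.
#'
#' @param fixture an `evolution_fixture`.
#' @param u,v genome names.
#' @param ... passed to [truth_to_anchors()].
#' @return a `synteny_map` from `u` to `v`.
#' @export
fixture_direct_map <- function(fixture, u, v, ...) {
  truth_to_anchors(fixture_truth_between(fixture, u, v), ...)
}

#' Native annotation of one fixture genome
#'
#' The planted gene models in that genome's own coordinates (lost exons
#' dropped; transcripts with no surviving exon dropped).
#'
#' @param fixture an `evolution_fixture`.
#' @param genome genome name.
#' @return a `feature_hierarchy`.
#' @export
fixture_annotation <- function(fixture, genome) {
  g_ <- genome
  m <- fixture$manifest[genome == g_ & status != "lost"]
  ex <- data.table::data.table(
    chrom = m$chrom, start = m$start, end = m$end, strand = m$strand,
    gene_id = m$gene_id, transcript_id = m$transcript_id,
    attrs = sprintf('gene_id "%s"; transcript_id "%s";',
                    m$gene_id, m$transcript_id))
  feature_hierarchy(ex)
}

#' Sample random blocks from a genome
#'
#' Uniform over all placements of `size`-nt windows across scaffolds
#' (scaffolds weighted by usable length); windows containing N are
#' rejected. Reproducible under `seed`.
#'
#' @param genome a `genome_seq`.
#' @param n number of blocks.
#' @param size block size, nt.
#' @param seed optional integer seed.
#' @return data.table with `chrom`, `start`, `end` (0-based half-open).
#' @export
sample_blocks <- function(genome, n, size = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- scaffold_lengths(genome)
  usable <- pmax(lens - size + 1L, 0L)
  if (all(usable == 0L)) stop("no scaffold long enough for blocks of ", size, " nt")
  out <- data.table::data.table(chrom = character(), start = integer())
  while (nrow(out) < n) {
    k <- n - nrow(out)
    ch <- sample(names(lens), k, replace = TRUE, prob = usable / sum(usable))
    st <- vapply(ch, function(c2) sample.int(usable[[c2]], 1L) - 1L, integer(1L))
    cand <- data.table::data.table(chrom = ch, start = st)
    ok <- vapply(seq_len(k), function(i)
      !grepl("N", get_seq(genome, cand$chrom[i], cand$start[i],
                          cand$start[i] + size), fixed = TRUE), logical(1L))
    out <- rbind(out, cand[ok])
  }
  out <- out[seq_len(n)]
  out[, end := start + as.integer(size)]
  out[]
}

#' Write a fixture to disk
#'
#' Emits FASTA genomes, tree-edge anchor maps in both dialects, a GTF
#' per genome, the run configuration, and the manifest as JSON.
#'
#' @param fixture an `evolution_fixture`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_genomes <- list()
  for (g in names(fixture$genomes)) {
    p <- file.path(dir, paste0(g, ".fa"))
    write_fasta(fixture$genomes[[g]], p)
    cfg_genomes[[g]] <- p
  }
  cfg_maps <- list()
  for (key in names(fixture$maps)) {
    m <- fixture$maps[[key]]
    p <- file.path(dir, paste0(key, ".lastz.tsv"))
    write_synteny_map(m, p, dialect = "lastz_general")
    write_synteny_map(m, file.path(dir, paste0(key, ".satsuma.tsv")),
                      dialect = "satsuma")
    cfg_maps[[length(cfg_maps) + 1L]] <- list(
      source = m$src_genome, target = m$tgt_genome, path = p,
      dialect = "lastz_general")
  }
  for (g in names(fixture$genomes)) {
    fh <- fixture_annotation(fixture, g)
    write_gtf_exons(fh$exons, file.path(dir, paste0(g, ".gtf")))
  }
  yaml::write_yaml(list(genomes = cfg_genomes, maps = cfg_maps),
                   file.path(dir, "config.yaml"))
  jsonlite::write_json(fixture$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}

# plain GTF emission of an exon table (1-based inclusive on disk)
write_gtf_exons <- function(exons, path) {
  lines <- sprintf("%s\tsyntrans\texon\t%d\t%d\t.\t%s\t.\t%s",
                   exons$chrom, exons$start + 1L, exons$end,
                   exons$strand, exons$attrs)
  writeLines(c("## syntrans fixture annotation", lines), path)
  invisible(path)
}
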