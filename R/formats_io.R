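# Readers/writers: FASTA genomes, synteny anchor maps (LASTZ-general and
# Satsuma dialects), GTF annotations, run configuration, report outputs.
# Internal coordinates are 0-based half-open everywhere; GTF and anchor
# files are 1-based inclusive at the boundary (single conversion point).

#' Read a FASTA genome
#'
#' Loads all records of a FASTA file into a [genome_seq()]. Sequences
#' are case-folded to upper case and symbols outside {A,C,G,T,N} are
#' mapped to N.
#'
#' @param path FASTA file.
#' @param genome_name identifier for the genome; defaults to the file
#'   name without extension.
#' @return a `genome_seq`.
#' @export
read_fasta <- function(path, genome_name = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no records in FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate scaffold name in ", path)
  seqs <- as.character(ss)
  names(seqs) <- nm
  genome_seq(genome_name %||% sub("\\.[^.]*$", "", basename(path)), seqs)
}

#' Write a genome to FASTA
#'
#' @param genome a `genome_seq`.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_seq"))
  ss <- Biostrings::DNAStringSet(genome$scaffolds)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct a synteny map
#'
#' A synteny map is a set of anchors: orthologous interval pairs between
#' a source and a target genome, each with an orientation. Anchors are
#' stored with ascending coordinates on both sides plus an orientation
#' flag, and indexed (sorted) in source coordinates for binary search.
#'
#' @param src_genome,tgt_genome genome identifiers.
#' @param anchors a data.frame/data.table with columns `src_chrom`,
#'   `src_start`, `src_end`, `tgt_chrom`, `tgt_start`, `tgt_end`,
#'   `orientation` ("+"/"-"); coordinates 0-based half-open.
#' @param weight optional non-negative genomic distance used as the
#'   graph edge weight.
#' @return an object of class `synteny_map`.
#' @export
synteny_map <- function(src_genome, tgt_genome, anchors, weight = NULL) {
  anchors <- data.table::as.data.table(anchors)
  need <- c("src_chrom", "src_start", "src_end",
            "tgt_chrom", "tgt_start", "tgt_end", "orientation")
  if (!all(need %in% names(anchors)))
    stop("anchors must have columns: ", paste(need, collapse = ", "))
  anchors <- anchors[, need, with = FALSE]
  anchors[, `:=`(src_start = as.integer(src_start), src_end = as.integer(src_end),
                 tgt_start = as.integer(tgt_start), tgt_end = as.integer(tgt_end))]
  if (anchors[, any(src_start >= src_end | tgt_start >= tgt_end)])
    stop("anchor with start >= end")
  if (!all(anchors$orientation %in% c("+", "-")))
    stop("orientation must be '+' or '-'")
  data.table::setorder(anchors, src_chrom, src_start, src_end)
  if (!is.null(weight) && (!is.numeric(weight) || weight < 0))
    stop("weight must be a non-negative number")
  structure(list(src_genome = src_genome, tgt_genome = tgt_genome,
                 anchors = anchors, weight = weight),
            class = "synteny_map")
}

#' @export
print.synteny_map <- function(x, ...) {
  cat("<synteny_map>", x$src_genome, "->", x$tgt_genome, ":",
      nrow(x$anchors), "anchors\n")
  invisible(x)
}

#' Read a synteny anchor map
#'
#' Two whitespace-separated dialects are supported; both list paired
#' intervals in 1-based inclusive coordinates, converted to internal
#' 0-based half-open on read.
#' \describe{
#'   \item{lastz_general}{`name1 start1 end1 name2 start2 end2 strand
#'     [extra columns ignored]`.}
#'   \item{satsuma}{same two triplets; the orientation is the first
#'     `+`/`-` token among the trailing columns (an identity column may
#'     precede it).}
#' }
#' Reverse-orientation rows whose target coordinates descend are
#' normalized to ascending coordinates plus the orientation flag.
#'
#' @param path anchor file.
#' @param src_genome,tgt_genome genome identifiers of the two sides.
#' @param dialect `"lastz_general"` or `"satsuma"`.
#' @param weight optional edge weight carried on the map.
#' @param skip_bad_rows if `TRUE`, malformed rows are skipped with a
#'   warning naming their line numbers; default aborts (silent
#'   coordinate corruption is the worst failure mode of a liftover
#'   tool).
#' @return a `synteny_map`.
#' @export
read_synteny_map <- function(path, src_genome, tgt_genome,
                             dialect = c("lastz_general", "satsuma"),
                             weight = NULL, skip_bad_rows = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("synteny map file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  parse_row <- function(tk) {
    if (length(tk) < 7L) return(NULL)
    s1 <- suppressWarnings(as.integer(tk[2:3]))
    s2 <- suppressWarnings(as.integer(tk[5:6]))
    if (anyNA(s1) || anyNA(s2)) return(NULL)
    ori <- if (dialect == "lastz_general") tk[7L] else {
      hits <- tk[-(1:6)][tk[-(1:6)] %in% c("+", "-")]
      if (length(hits) == 0L) NA_character_ else hits[1L]
    }
    if (is.na(ori) || !ori %in% c("+", "-")) return(NULL)
    # normalize descending reverse rows, then 1-based inclusive -> 0-based half-open
    if (s1[1L] > s1[2L]) s1 <- rev(s1)
    if (s2[1L] > s2[2L]) s2 <- rev(s2)
    if (s1[1L] < 1L || s2[1L] < 1L) return(NULL)
    list(src_chrom = tk[1L], src_start = s1[1L] - 1L, src_end = s1[2L],
         tgt_chrom = tk[4L], tgt_start = s2[1L] - 1L, tgt_end = s2[2L],
         orientation = ori)
  }
  rows <- lapply(toks, parse_row)
  bad <- vapply(rows, is.null, logical(1L))
  if (any(bad)) {
    msg <- paste0("malformed synteny map row(s) in ", path, " at line(s): ",
                  paste(head(lineno[bad], 10L), collapse = ", "))
    if (skip_bad_rows) warning(msg, " (", sum(bad), " skipped)") else stop(msg)
  }
  if (all(bad)) stop("no parseable anchors in ", path)
  anchors <- data.table::rbindlist(rows[!bad])
  synteny_map(src_genome, tgt_genome, anchors, weight = weight)
}

#' Write a synteny map
#'
#' Emits 1-based inclusive coordinates in the requested dialect (see
#' [read_synteny_map()] for the layouts).
#'
#' @param map a `synteny_map`.
#' @param path output file.
#' @param dialect `"lastz_general"` or `"satsuma"`.
#' @return `path`, invisibly.
#' @export
write_synteny_map <- function(map, path, dialect = c("lastz_general", "satsuma")) {
  dialect <- match.arg(dialect)
  a <- map$anchors
  if (dialect == "lastz_general") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
                     a$src_chrom, a$src_start + 1L, a$src_end,
                     a$tgt_chrom, a$tgt_start + 1L, a$tgt_end, a$orientation)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%.4f\t%s",
                     a$src_chrom, a$src_start + 1L, a$src_end,
                     a$tgt_chrom, a$tgt_start + 1L, a$tgt_end, 1, a$orientation)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Invert a synteny map
#'
#' Swaps the source and target sides of every anchor (orientation is
#' preserved: the relation is symmetric) and the genome identifiers,
#' supplying the map in the opposite direction. Involution:
#' `invert_map(invert_map(m))` equals `m` up to anchor order.
#'
#' @param map a `synteny_map`.
#' @return the inverted `synteny_map`.
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "synteny_map"))
  a <- map$anchors
  inv <- data.table::data.table(
    src_chrom = a$tgt_chrom, src_start = a$tgt_start, src_end = a$tgt_end,
    tgt_chrom = a$src_chrom, tgt_start = a$src_start, tgt_end = a$src_end,
    orientation = a$orientation)
  synteny_map(map$tgt_genome, map$src_genome, inv, weight = map$weight)
}

#' Read a GTF annotation into a feature hierarchy
#'
#' Keeps exon rows, converts 1-based inclusive coordinates to internal
#' 0-based half-open, and groups exons into transcripts into loci with
#' bidirectional ownership. The raw attribute string of every row is
#' retained so translated output can re-emit it verbatim.
#'
#' @param path GTF file.
#' @param scaffold_lens optional named vector of scaffold lengths; exon
#'   rows outside the declared scaffolds are skipped with a warning and
#'   counted in `attr(, "skipped")`.
#' @return a `feature_hierarchy`.
#' @export
read_gtf <- function(path, scaffold_lens = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L)
    return(feature_hierarchy(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), gene_id = character(), transcript_id = character(),
      source = character(), feature = character(), score = character(),
      frame = character(), attrs = character())))
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(parts) < 9L) stop("GTF rows must have 9 tab-separated fields: ", path)
  dt <- data.table::data.table(
    chrom = parts[[1L]], source = parts[[2L]], feature = parts[[3L]],
    start = as.integer(parts[[4L]]) - 1L, end = as.integer(parts[[5L]]),
    score = parts[[6L]], strand = parts[[7L]], frame = parts[[8L]],
    attrs = parts[[9L]])
  dt <- dt[feature == "exon"]
  get_attr <- function(attrs, key) {
    pat <- paste0(key, "\\s+\"([^\"]*)\"")
    m <- regexpr(pat, attrs)
    out <- rep(NA_character_, length(attrs))
    hit <- m > 0L
    out[hit] <- sub(pat, "\\1", regmatches(attrs, m))
    out
  }
  dt[, gene_id := get_attr(attrs, "gene_id")]
  dt[, transcript_id := get_attr(attrs, "transcript_id")]
  if (anyNA(dt$transcript_id) || anyNA(dt$gene_id))
    stop("exon row without gene_id/transcript_id attribute in ", path)
  skipped <- 0L
  if (!is.null(scaffold_lens)) {
    ok <- dt$chrom %in% names(scaffold_lens) &
      dt$start >= 0L & dt$end <= scaffold_lens[dt$chrom]
    skipped <- sum(!ok)
    if (skipped > 0L) {
      warning(skipped, " exon(s) outside declared scaffolds skipped")
      dt <- dt[ok]
    }
  }
  fh <- feature_hierarchy(dt)
  attr(fh, "skipped") <- skipped
  fh
}

#' Build a feature hierarchy from an exon table
#'
#' Exons are owned by transcripts, transcripts by loci; ownership is
#' navigable both ways (exon rows carry `transcript_id`/`gene_id`, the
#' per-level tables are sorted for efficient retrieval).
#'
#' @param exons data.table with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`, `transcript_id`, and optionally
#'   `source`, `feature`, `score`, `frame`, `attrs`.
#' @return an object of class `feature_hierarchy` with elements
#'   `exons`, `transcripts`, `loci` (data.tables).
#' @export
feature_hierarchy <- function(exons) {
  exons <- data.table::as.data.table(exons)
  for (col in c("source", "feature", "score", "frame", "attrs")) {
    if (is.null(exons[[col]]))
      exons[, (col) := if (col == "feature") "exon" else "."]
  }
  data.table::setorder(exons, chrom, start, end)
  exons[, exon_id := seq_len(.N)]
  if (nrow(exons) == 0L) {
    empty_tx <- data.table::data.table(
      transcript_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      n_exons = integer())
    empty_loci <- data.table::data.table(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), n_tx = integer())
    return(structure(list(exons = exons, transcripts = empty_tx,
                          loci = empty_loci), class = "feature_hierarchy"))
  }
  transcripts <- exons[, .(gene_id = gene_id[1L], chrom = chrom[1L],
                           start = min(start), end = max(end),
                           strand = strand[1L], n_exons = .N),
                       by = transcript_id]
  data.table::setorder(transcripts, chrom, start, end)
  loci <- transcripts[, .(chrom = chrom[1L], start = min(start), end = max(end),
                          strand = strand[1L], n_tx = .N),
                      by = gene_id]
  data.table::setorder(loci, chrom, start, end)
  structure(list(exons = exons, transcripts = transcripts, loci = loci),
            class = "feature_hierarchy")
}

#' @export
print.feature_hierarchy <- function(x, ...) {
  cat("<feature_hierarchy>", nrow(x$loci), "loci,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Exons of one transcript / transcripts of one locus
#'
#' Child lookup along the bidirectional ownership links.
#'
#' @param fh a `feature_hierarchy`.
#' @param id a `transcript_id` (for `exons_of`) or `gene_id` (for
#'   `transcripts_of`).
#' @return a data.table of the children, in coordinate order.
#' @export
exons_of <- function(fh, id) fh$exons[transcript_id == id][order(start)]

#' @rdname exons_of
#' @export
transcripts_of <- function(fh, id) fh$transcripts[gene_id == id][order(start)]

#' Write translation results as GTF plus relationship table
#'
#' The translated GTF re-emits every original attribute key/value
#' verbatim and appends provenance attributes (`src_genome`,
#' `translation_path`, `align_pvalue`). Untranslated features go to a
#' `.unmapped.gtf` with a `fail_reason` attribute. The relationship
#' table is a TSV with one row per (source transcript, target feature,
#' class).
#'
#' @param results data.table as produced by [run_translate()]
#'   (`$results`).
#' @param matches optional data.table of match records
#'   ([classify_overlaps()]).
#' @param out_dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the files written, invisibly.
#' @export
write_outputs <- function(results, matches = NULL, out_dir, prefix = "syntrans") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gtf_path <- file.path(out_dir, paste0(prefix, ".translated.gtf"))
  un_path <- file.path(out_dir, paste0(prefix, ".unmapped.gtf"))
  header <- paste0("## syntrans translated coordinates")
  fmt_row <- function(r, translated) {
    extra <- if (translated) {
      sprintf(' src_genome "%s"; translation_path "%s"; align_pvalue "%.3g";',
              r$src_genome, r$path_used, r$p_value)
    } else {
      sprintf(' src_genome "%s"; fail_reason "%s";', r$src_genome, r$reason)
    }
    base_attrs <- sub(";?\\s*$", ";", r$attrs)
    if (translated) {
      sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s%s",
              r$tgt_chrom, r$source, r$feature, r$tgt_start + 1L, r$tgt_end,
              r$score, r$tgt_strand, r$frame, base_attrs, extra)
    } else {
      sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s%s",
              r$chrom, r$source, r$feature, r$start + 1L, r$end,
              r$score, r$strand, r$frame, base_attrs, extra)
    }
  }
  ok <- results[translated == TRUE]
  bad <- results[translated == FALSE]
  writeLines(c(header, if (nrow(ok)) vapply(seq_len(nrow(ok)), function(i)
    fmt_row(ok[i], TRUE), character(1L))), gtf_path)
  writeLines(c("## syntrans unmapped features", if (nrow(bad))
    vapply(seq_len(nrow(bad)), function(i) fmt_row(bad[i], FALSE), character(1L))),
    un_path)
  files <- c(translated = gtf_path, unmapped = un_path)
  if (!is.null(matches)) {
    rel_path <- file.path(out_dir, paste0(prefix, ".relationships.tsv"))
    data.table::fwrite(matches, rel_path, sep = "\t")
    files <- c(files, relationships = rel_path)
  }
  invisible(files)
}

#' Read a run configuration file
#'
#' YAML file with three blocks:
#' \preformatted{
#' genomes:
#'   A: genomes/A.fa
#'   B: genomes/B.fa
#' maps:
#'   - source: A
#'     target: B
#'     path: maps/AB.tsv
#'     dialect: lastz_general   # or satsuma
#'     weight: 0.12             # optional genomic distance
#' params:                      # all optional
#'   flank_nt: 12
#'   block_log2: 14
#'   break_span_nt: 100000
#'   split_span_nt: 50000
#'   pvalue_threshold: 1.0e-4
#' }
#' Maps need to be given in one direction only; the loader supplies the
#' other direction by inversion in memory.
#'
#' @param path configuration file.
#' @return a list with elements `genomes` (named paths), `maps`
#'   (list of map entries) and `params` (defaults filled in).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$genomes) || length(cfg$genomes) < 2L)
    stop("config must declare at least two genomes")
  if (is.null(cfg$maps) || length(cfg$maps) == 0L)
    stop("config must declare at least one map")
  gnames <- names(cfg$genomes)
  for (m in cfg$maps) {
    if (is.null(m$source) || is.null(m$target) || is.null(m$path))
      stop("every map entry needs source, target and path")
    if (!m$source %in% gnames || !m$target %in% gnames)
      stop("map ", m$source, "-", m$target, " references an undeclared genome")
  }
  defaults <- list(flank_nt = 12L, block_log2 = 14L,
                   break_span_nt = 100000L, split_span_nt = 50000L,
                   pvalue_threshold = 1e-4)
  params <- utils::modifyList(defaults, cfg$params %||% list())
  list(genomes = unlist(cfg$genomes), maps = cfg$maps, params = params)
}

#' Default translation parameters
#'
#' @return named list of the tunable thresholds with their defaults:
#'   `flank_nt` 12, `block_log2` 14, `break_span_nt` 100000,
#'   `split_span_nt` 50000, `pvalue_threshold` 1e-4.
#' @export
default_params <- function() {
  list(flank_nt = 12L, block_log2 = 14L, break_span_nt = 100000L,
       split_span_nt = 50000L, pvalue_threshold = 1e-4)
}
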