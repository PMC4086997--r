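# Compare translated transcripts to annotations native to the target
# genome and classify each relationship: full/partial sense overlap,
# intronic (sense/antisense), antisense (full/partial), or none.

match_class_levels <- c("full_sense", "partial_sense", "intronic_sense",
                        "intronic_antisense", "antisense_full",
                        "antisense_partial", "none")

# precedence used when one transcript reports several records
class_rank <- function(cls) match(cls, match_class_levels)

#' Classify translated transcripts against a native annotation
#'
#' For each source transcript and each overlapping target feature, one
#' match record. Classes, in precedence order:
#' \describe{
#'   \item{full_sense}{every source exon overlaps some target exon and
#'     every target exon overlaps some source exon, same strand
#'     (bidirectional coverage).}
#'   \item{partial_sense}{at least one exon pair overlaps in sense, but
#'     not full.}
#'   \item{intronic_sense / intronic_antisense}{the source transcript
#'     falls within a target locus span but overlaps none of its exons.}
#'   \item{antisense_full / antisense_partial}{exon overlap on the
#'     opposite strand, full by the same bidirectional criterion.}
#'   \item{none}{no target locus overlap (a classification, not an
#'     error).}
#' }
#' Overlap means at least one shared nucleotide.
#'
#' @param source_fh `feature_hierarchy` of translated transcripts.
#' @param target_fh `feature_hierarchy` native to the target genome.
#' @return data.table with columns `src_transcript`, `tgt_id` (target
#'   transcript, locus for intronic records, or NA), `class`,
#'   `n_exons_overlap` (source exons overlapping a target exon),
#'   `overlap_nt`.
#' @export
classify_overlaps <- function(source_fh, target_fh) {
  stopifnot(inherits(source_fh, "feature_hierarchy"),
            inherits(target_fh, "feature_hierarchy"))
  se <- source_fh$exons; te <- target_fh$exons
  st <- source_fh$transcripts; tt <- target_fh$transcripts
  out <- list()
  if (nrow(se) && nrow(te)) {
    sgr <- GenomicRanges::GRanges(se$chrom,
             IRanges::IRanges(se$start + 1L, se$end))
    tgr <- GenomicRanges::GRanges(te$chrom,
             IRanges::IRanges(te$start + 1L, te$end))
    ov <- GenomicRanges::findOverlaps(sgr, tgr, ignore.strand = TRUE)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      pairs <- data.table::data.table(
        src_transcript = se$transcript_id[qh],
        tgt_transcript = te$transcript_id[sh],
        src_exon = se$exon_id[qh], tgt_exon = te$exon_id[sh],
        sense = se$strand[qh] == te$strand[sh],
        overlap_nt = pmin(se$end[qh], te$end[sh]) -
          pmax(se$start[qh], te$start[sh]))
      n_src <- st[, .(n_src = n_exons), by = transcript_id]
      n_tgt <- tt[, .(n_tgt = n_exons), by = transcript_id]
      agg <- pairs[, .(
        n_src_hit = data.table::uniqueN(src_exon),
        n_tgt_hit = data.table::uniqueN(tgt_exon),
        any_sense = any(sense), all_strand_pairs = .N,
        n_sense_pairs = sum(sense),
        overlap_nt = sum(overlap_nt)),
        by = .(src_transcript, tgt_transcript)]
      agg <- merge(agg, n_src, by.x = "src_transcript", by.y = "transcript_id")
      agg <- merge(agg, n_tgt, by.x = "tgt_transcript", by.y = "transcript_id")
      agg[, full_blind := n_src_hit == n_src & n_tgt_hit == n_tgt]
      agg[, class := ifelse(any_sense,
                            ifelse(full_blind, "full_sense", "partial_sense"),
                            ifelse(full_blind, "antisense_full",
                                   "antisense_partial"))]
      out[["exon"]] <- agg[, .(src_transcript, tgt_id = tgt_transcript, class,
                               n_exons_overlap = n_src_hit, overlap_nt)]
    }
  }
  # intronic: transcript overlaps a target locus span but none of its exons
  exon_hit_loci <- if (!is.null(out[["exon"]])) {
    tx2gene <- tt[, .(transcript_id, gene_id)]
    merge(out[["exon"]], tx2gene, by.x = "tgt_id", by.y = "transcript_id")[
      , .(src_transcript, gene_id)]
  } else data.table::data.table(src_transcript = character(),
                                gene_id = character())
  tl <- target_fh$loci
  if (nrow(st) && nrow(tl)) {
    sgr2 <- GenomicRanges::GRanges(st$chrom,
              IRanges::IRanges(st$start + 1L, st$end))
    lgr <- GenomicRanges::GRanges(tl$chrom,
             IRanges::IRanges(tl$start + 1L, tl$end))
    lov <- GenomicRanges::findOverlaps(sgr2, lgr, ignore.strand = TRUE)
    if (length(lov)) {
      qh <- S4Vectors::queryHits(lov); sh <- S4Vectors::subjectHits(lov)
      li <- data.table::data.table(
        src_transcript = st$transcript_id[qh], gene_id = tl$gene_id[sh],
        sense = st$strand[qh] == tl$strand[sh],
        overlap_nt = pmin(st$end[qh], tl$end[sh]) -
          pmax(st$start[qh], tl$start[sh]))
      li <- li[!exon_hit_loci, on = c("src_transcript", "gene_id")]
      if (nrow(li)) {
        li[, class := ifelse(sense, "intronic_sense", "intronic_antisense")]
        out[["intronic"]] <- li[, .(src_transcript, tgt_id = gene_id, class,
                                    n_exons_overlap = 0L, overlap_nt)]
      }
    }
  }
  res <- data.table::rbindlist(out, use.names = TRUE)
  # transcripts with no record at all -> none
  missing <- setdiff(st$transcript_id, res$src_transcript)
  if (length(missing))
    res <- rbind(res, data.table::data.table(
      src_transcript = missing, tgt_id = NA_character_, class = "none",
      n_exons_overlap = 0L, overlap_nt = 0L))
  data.table::setorder(res, src_transcript, class, tgt_id, na.last = TRUE)
  res[]
}

#' Best (maximal) match per source locus
#'
#' Among all isoform pairs of a source locus, keeps the pair with the
#' largest number of overlapping exons; ties broken by overlap
#' nucleotides, then lexicographically smallest target id.
#'
#' @param matches match records from [classify_overlaps()].
#' @param source_fh the source `feature_hierarchy` (supplies the
#'   transcript-to-locus ownership).
#' @return one row per source locus that has an exon-overlap record.
#' @export
maximal_match <- function(matches, source_fh) {
  tx2gene <- source_fh$transcripts[, .(transcript_id, gene_id)]
  m <- merge(matches[n_exons_overlap > 0L], tx2gene,
             by.x = "src_transcript", by.y = "transcript_id")
  if (nrow(m) == 0L) return(m)
  data.table::setorder(m, gene_id, -n_exons_overlap, -overlap_nt, tgt_id)
  m[, .SD[1L], by = gene_id]
}

#' Summarize match records
#'
#' Pairwise mode: counts and percentages of transcripts translated and,
#' of those, the fraction with sense exon overlap (best class per
#' transcript; sense = full or partial). Multiway mode: per-region
#' counts of a 3-set Venn over one-to-one maximal matches, where
#' transcripts of the three genomes are linked by their maximal matches
#' and each connected component is counted once for the set of genomes
#' it spans.
#'
#' @param matches pairwise mode: match records from
#'   [classify_overlaps()].
#' @param n_total total source transcripts attempted.
#' @param n_translated source transcripts translated.
#' @param mode `"pairwise"` or `"multiway"`.
#' @param links multiway mode: named list of three data.tables of
#'   one-to-one links, names like `"A-B"`, each with columns `src`
#'   (transcript id in the first genome) and `tgt` (in the second).
#' @return a data.table; pairwise: one row of counts/percentages;
#'   multiway: one row per Venn region (`genomes`, `count`).
#' @export
summarize_matches <- function(matches = NULL, n_total = NA_integer_,
                              n_translated = NA_integer_,
                              mode = c("pairwise", "multiway"),
                              links = NULL) {
  mode <- match.arg(mode)
  if (mode == "pairwise") {
    sense <- 0L
    if (!is.null(matches) && nrow(matches)) {
      best <- matches[, .(class = class[which.min(class_rank(class))]),
                      by = src_transcript]
      sense <- best[class %in% c("full_sense", "partial_sense"), .N]
    }
    return(data.table::data.table(
      transcripts_total = n_total, transcripts_mapped = n_translated,
      pct_mapped = if (is.na(n_total) || n_total == 0) NA_real_ else
        100 * n_translated / n_total,
      with_overlap = sense,
      pct_with_overlap = if (is.na(n_translated) || n_translated == 0)
        NA_real_ else 100 * sense / n_translated))
  }
  if (is.null(links) || length(links) != 3L)
    stop("multiway mode needs exactly 3 pairwise link tables")
  gpairs <- strsplit(names(links), "-", fixed = TRUE)
  gset <- sort(unique(unlist(gpairs)))
  if (length(gset) != 3L) stop("multiway mode needs exactly 3 genomes")
  edges <- data.table::rbindlist(lapply(seq_along(links), function(i) {
    l <- links[[i]]
    data.table::data.table(from = paste0(gpairs[[i]][1L], ":", l$src),
                           to = paste0(gpairs[[i]][2L], ":", l$tgt))
  }))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  member_genome <- sub(":.*$", "", names(comp$membership))
  span <- tapply(member_genome, comp$membership,
                 function(gs) paste(sort(unique(gs)), collapse = "&"))
  tab <- table(factor(span, levels = c(gset,
    paste(gset[1], gset[2], sep = "&"), paste(gset[1], gset[3], sep = "&"),
    paste(gset[2], gset[3], sep = "&"), paste(gset, collapse = "&"))))
  data.table::data.table(genomes = names(tab), count = as.integer(tab))
}

#' Signed per-boundary differences between matched exons
#'
#' For every sense exon pair, the signed nt difference at each boundary
#' (source minus target), enabling the mod-3 periodicity check for
#' coding exons.
#'
#' @param source_fh,target_fh `feature_hierarchy` objects.
#' @return data.table with `src_transcript`, `tgt_transcript`,
#'   `start_diff`, `end_diff`.
#' @export
boundary_differences <- function(source_fh, target_fh) {
  se <- source_fh$exons; te <- target_fh$exons
  if (!nrow(se) || !nrow(te))
    return(data.table::data.table(src_transcript = character(),
      tgt_transcript = character(), start_diff = integer(),
      end_diff = integer()))
  sgr <- GenomicRanges::GRanges(se$chrom, IRanges::IRanges(se$start + 1L, se$end))
  tgr <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start + 1L, te$end))
  ov <- GenomicRanges::findOverlaps(sgr, tgr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  sense <- se$strand[qh] == te$strand[sh]
  data.table::data.table(
    src_transcript = se$transcript_id[qh][sense],
    tgt_transcript = te$transcript_id[sh][sense],
    start_diff = (se$start[qh] - te$start[sh])[sense],
    end_diff = (se$end[qh] - te$end[sh])[sense])
}
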