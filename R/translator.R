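# Coordinate translation along the fixed path: binary search of the
# source position among the map's anchors, linear interpolation inside
# an anchor, widening to the flanking anchors between anchors, and
# splitting at syntenic breaks.

# sorted per-chromosome anchor view (binary-search substrate)
anchors_on <- function(map, chrom) {
  a <- map$anchors[src_chrom == chrom]
  if (nrow(a)) data.table::setorder(a, src_start)
  a
}

# target base position of source base p inside anchor row r (proportional
# offset: anchors may differ in source/target length)
interp_anchor <- function(r, p) {
  off <- p - r$src_start
  sl <- r$src_end - r$src_start
  tl <- r$tgt_end - r$tgt_start
  # (off * tl) %/% sl is exact in doubles for genomic magnitudes;
  # off * (tl / sl) is not
  toff <- as.integer((as.numeric(off) * tl) %/% sl)
  if (r$orientation == "+") r$tgt_start + toff else r$tgt_end - 1L - toff
}

# resolve one source base position against the anchor set:
# returns list(chrom, lo, hi, orient, widened) - the target-space
# uncertainty interval for that base
resolve_pos <- function(anch, p, split_span, tgt_lens = NULL) {
  n <- nrow(anch)
  i <- findInterval(p, anch$src_start)
  if (i >= 1L && p < anch$src_end[i]) {
    r <- anch[i]
    t <- interp_anchor(r, p)
    return(list(chrom = r$tgt_chrom, lo = t, hi = t + 1L,
                orient = r$orientation, widened = FALSE))
  }
  left <- if (i >= 1L) anch[i] else NULL
  right <- if (i < n) anch[i + 1L] else NULL
  inner_bound <- function(r, side) {
    # target-space bound of the anchor on the side facing the gap
    if (side == "left")  { if (r$orientation == "+") r$tgt_end else r$tgt_start }
    else                 { if (r$orientation == "+") r$tgt_start else r$tgt_end }
  }
  cap <- function(chrom, x) {
    if (is.null(tgt_lens) || !chrom %in% names(tgt_lens)) return(max(0L, x))
    max(0L, min(as.integer(tgt_lens[[chrom]]), x))
  }
  if (!is.null(left) && !is.null(right) && left$tgt_chrom == right$tgt_chrom) {
    bl <- inner_bound(left, "left"); br <- inner_bound(right, "right")
    return(list(chrom = left$tgt_chrom, lo = min(bl, br), hi = max(bl, br),
                orient = if (left$orientation == right$orientation)
                  left$orientation else NA_character_,
                widened = TRUE))
  }
  # single-sided (scaffold end) or cross-scaffold gap: use the nearer
  # anchor, open bound extended outward by split_span
  if (is.null(left)) { use <- right; side <- "right" }
  else if (is.null(right)) { use <- left; side <- "left" }
  else if ((p - left$src_end) <= (right$src_start - p)) { use <- left; side <- "left" }
  else { use <- right; side <- "right" }
  b <- inner_bound(use, side)
  outward_hi <- (side == "left") == (use$orientation == "+")
  lo <- if (outward_hi) b else cap(use$tgt_chrom, b - as.integer(split_span))
  hi <- if (outward_hi) cap(use$tgt_chrom, b + as.integer(split_span)) else b
  if (lo >= hi) { lo <- max(0L, b - 1L); hi <- b + 1L }
  list(chrom = use$tgt_chrom, lo = lo, hi = hi,
       orient = use$orientation, widened = TRUE)
}

#' Translate one interval through a single synteny map
#'
#' Looks up the lower bound of the start and the higher bound of the end
#' position among the map's anchors (binary search over the
#' source-sorted index). Positions inside an anchor are linearly
#' interpolated; positions between anchors widen the candidate to the
#' flanking anchors' target bounds.
#'
#' @param map a `synteny_map` (anchors indexed in source coordinates).
#' @param chrom,start,end source interval, 0-based half-open.
#' @param split_span_nt cap, in nt, on how far a candidate extends past
#'   the outermost anchor of a scaffold.
#' @param tgt_lens optional named scaffold lengths of the target genome
#'   for clipping.
#' @return a `candidate_interval`: list with `genome`, `chrom`, `start`,
#'   `end`, `orientation`, `consistent`, `cross_scaffold`, `widened`,
#'   `bounds` (the two per-position resolutions) and `split_side`
#'   (`"none"` here); or a list with `ok = FALSE` and `reason` when no
#'   anchor exists on the source scaffold.
#' @export
locate_bounds <- function(map, chrom, start, end,
                          split_span_nt = 50000L, tgt_lens = NULL) {
  stopifnot(start < end)
  anch <- anchors_on(map, chrom)
  if (nrow(anch) == 0L)
    return(list(ok = FALSE, reason = "no-anchor",
                detail = paste0("no anchor on source scaffold ", chrom)))
  b1 <- resolve_pos(anch, start, split_span_nt, tgt_lens)
  b2 <- resolve_pos(anch, end - 1L, split_span_nt, tgt_lens)
  cross <- b1$chrom != b2$chrom
  orients <- c(b1$orient, b2$orient)
  orients <- orients[!is.na(orients)]
  consistent <- !cross && length(unique(orients)) <= 1L
  orientation <- if (length(orients)) orients[1L] else "+"
  out <- list(ok = TRUE, genome = map$tgt_genome,
              chrom = if (cross) NA_character_ else b1$chrom,
              start = if (cross) NA_integer_ else min(b1$lo, b2$lo),
              end = if (cross) NA_integer_ else max(b1$hi, b2$hi),
              orientation = orientation, consistent = consistent,
              cross_scaffold = cross,
              widened = b1$widened || b2$widened,
              bounds = list(b1, b2), split_side = "none")
  class(out) <- "candidate_interval"
  out
}

#' Split a candidate at syntenic breaks
#'
#' A candidate passes through unchanged when both bounds fall on the
#' same target scaffold with consistent orientation and the span is at
#' most `break_span_nt`. Otherwise it is split into two candidates of
#' `split_span_nt` each, one anchored at each bound, to allow searching
#' the boundaries of the syntenic break.
#'
#' @param cand a `candidate_interval` from [locate_bounds()].
#' @param break_span_nt maximum un-split span (default 100000).
#' @param split_span_nt size of each split side (default 50000).
#' @param tgt_lens optional named target scaffold lengths for clipping.
#' @return list of one or two `candidate_interval`s.
#' @export
check_and_split <- function(cand, break_span_nt = 100000L,
                            split_span_nt = 50000L, tgt_lens = NULL) {
  stopifnot(inherits(cand, "candidate_interval"))
  span_ok <- !cand$cross_scaffold && (cand$end - cand$start) <= break_span_nt
  if (span_ok && cand$consistent && cand$split_side == "none")
    return(list(cand))
  if (span_ok && cand$consistent)  # already a split side within budget
    return(list(cand))
  clipfun <- function(chrom, s, e) {
    if (!is.null(tgt_lens) && chrom %in% names(tgt_lens)) {
      s <- max(0L, s); e <- min(as.integer(tgt_lens[[chrom]]), e)
    } else s <- max(0L, s)
    c(s, e)
  }
  b1 <- cand$bounds[[1L]]; b2 <- cand$bounds[[2L]]
  mk <- function(b, side) {
    if (side == "left") { s <- b$lo; e <- b$lo + as.integer(split_span_nt) }
    else { s <- b$hi - as.integer(split_span_nt); e <- b$hi }
    se <- clipfun(b$chrom, s, e)
    out <- cand
    out$chrom <- b$chrom; out$start <- se[1L]; out$end <- se[2L]
    out$orientation <- if (is.na(b$orient)) "+" else b$orient
    out$consistent <- TRUE; out$cross_scaffold <- FALSE
    out$split_side <- side
    out$bounds <- list(b, b)
    out
  }
  # a candidate that is already one side of a split keeps only its side
  if (cand$split_side == "left") return(list(mk(b1, "left")))
  if (cand$split_side == "right") return(list(mk(b2, "right")))
  list(mk(b1, "left"), mk(b2, "right"))
}

#' Translate an interval along a multi-hop path
#'
#' Applies [locate_bounds()] hop by hop, each hop's candidate becoming
#' the next hop's query; orientations compose across hops (reverse of
#' reverse is forward). [check_and_split()] is applied after every hop
#' so candidates cannot grow past the break span. Failure at any hop is
#' reported with the hop index and reason.
#'
#' @param graph a `synteny_graph`.
#' @param path a `translation_path`.
#' @param chrom,start,end source interval, 0-based half-open.
#' @param params parameter list (see [default_params()]).
#' @param genomes optional named list of `genome_seq` for scaffold-end
#'   clipping.
#' @return list with `ok`; on success `candidates` (one or two
#'   `candidate_interval`s in target-genome coordinates); on failure
#'   `hop` (1-based failing hop) and `reason`.
#' @export
translate_through_path <- function(graph, path, chrom, start, end,
                                   params = default_params(),
                                   genomes = NULL) {
  stopifnot(inherits(path, "translation_path"))
  cands <- list(structure(list(
    ok = TRUE, genome = path$genomes[1L], chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    orientation = "+", consistent = TRUE, cross_scaffold = FALSE,
    widened = FALSE,
    bounds = list(list(chrom = chrom, lo = as.integer(start),
                       hi = as.integer(start) + 1L, orient = "+", widened = FALSE),
                  list(chrom = chrom, lo = as.integer(end) - 1L,
                       hi = as.integer(end), orient = "+", widened = FALSE)),
    split_side = "none"), class = "candidate_interval"))
  n_hops <- length(path$genomes) - 1L
  for (h in seq_len(n_hops)) {
    from <- path$genomes[h]; to <- path$genomes[h + 1L]
    map <- hop_map(graph, from, to)
    tgt_lens <- if (!is.null(genomes) && to %in% names(genomes))
      scaffold_lengths(genomes[[to]]) else NULL
    nxt <- list()
    for (cand in cands) {
      res <- locate_bounds(map, cand$chrom, cand$start, cand$end,
                           split_span_nt = params$split_span_nt,
                           tgt_lens = tgt_lens)
      if (!isTRUE(res$ok)) next
      res$orientation <- compose_orient(cand$orientation, res$orientation)
      if (!is.na(res$bounds[[1L]]$orient))
        res$bounds[[1L]]$orient <- compose_orient(cand$orientation,
                                                  res$bounds[[1L]]$orient)
      if (!is.na(res$bounds[[2L]]$orient))
        res$bounds[[2L]]$orient <- compose_orient(cand$orientation,
                                                  res$bounds[[2L]]$orient)
      res$split_side <- cand$split_side
      # a reverse-orientation hop mirrors which source bound is leftmost
      pieces <- check_and_split(res, break_span_nt = params$break_span_nt,
                                split_span_nt = params$split_span_nt,
                                tgt_lens = tgt_lens)
      nxt <- c(nxt, pieces)
    }
    if (length(nxt) == 0L)
      return(list(ok = FALSE, hop = h,
                  reason = sprintf("no-anchor at hop %d (%s->%s)", h, from, to)))
    if (length(nxt) > 2L) nxt <- nxt[seq_len(2L)]
    cands <- nxt
  }
  list(ok = TRUE, candidates = cands)
}
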