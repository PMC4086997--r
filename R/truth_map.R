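# Piecewise-monotone coordinate maps between a parent genome and a
# derived genome, maintained exactly while the simulator applies
# inversions, tandem duplications and indels. A map is a segment table:
# every derived position belongs to exactly one segment; block segments
# carry the parent interval of equal length and an orientation,
# insertion segments are derived-only, duplicate copies are marked and
# excluded from the canonical parent->derived function.

new_truth_map <- function(src, tgt, segs) {
  segs <- data.table::as.data.table(segs)
  data.table::setorder(segs, tgt_chrom, tgt_start)
  structure(list(src = src, tgt = tgt, segs = segs), class = "truth_map")
}

#' Identity ground-truth map
#'
#' @param src,tgt genome identifiers.
#' @param scaffold_lens named vector of scaffold lengths.
#' @return a `truth_map` mapping every scaffold to itself.
#' @export
identity_truth <- function(src, tgt, scaffold_lens) {
  segs <- data.table::data.table(
    src_chrom = names(scaffold_lens), src_start = 0L,
    src_end = as.integer(scaffold_lens),
    tgt_chrom = names(scaffold_lens), tgt_start = 0L,
    tgt_end = as.integer(scaffold_lens),
    strand = "+", type = "block", is_dup = FALSE)
  new_truth_map(src, tgt, segs)
}

#' @export
print.truth_map <- function(x, ...) {
  cat("<truth_map>", x$src, "->", x$tgt, ":", nrow(x$segs), "segments\n")
  invisible(x)
}

# ensure a segment boundary exists at derived position `pos` on `chrom`
tm_split_at <- function(segs, chrom, pos) {
  i <- segs[, which(tgt_chrom == chrom & tgt_start < pos & tgt_end > pos)]
  if (length(i) == 0L) return(segs)
  r <- segs[i]
  l1 <- pos - r$tgt_start
  left <- data.table::copy(r); right <- data.table::copy(r)
  left$tgt_end <- pos; right$tgt_start <- pos
  if (r$type != "ins") {
    if (r$strand == "+") {
      left$src_end <- r$src_start + l1
      right$src_start <- r$src_start + l1
    } else {
      left$src_start <- r$src_end - l1
      right$src_end <- r$src_end - l1
    }
  }
  out <- rbind(segs[-i], left, right)
  data.table::setorder(out, tgt_chrom, tgt_start)
  out
}

# derived length of one scaffold
tm_derived_length <- function(tm, chrom) {
  tm$segs[tgt_chrom == chrom, if (.N) max(tgt_end) else 0L]
}

#' Apply an inversion to a truth map (derived coordinates)
#'
#' Segments inside `[a, b)` are reversed in order and flipped in
#' orientation; parent coordinates are untouched.
#'
#' @param tm a `truth_map`.
#' @param chrom derived scaffold.
#' @param a,b 0-based half-open derived interval.
#' @return the updated `truth_map`.
#' @export
tm_apply_inversion <- function(tm, chrom, a, b) {
  stopifnot(a < b)
  segs <- tm_split_at(tm_split_at(tm$segs, chrom, a), chrom, b)
  inside <- segs[, which(tgt_chrom == chrom & tgt_start >= a & tgt_end <= b)]
  if (length(inside) == 0L) return(tm)
  inv <- segs[rev(inside)]
  inv[, strand := ifelse(strand == "+", "-", "+")]
  lens <- inv$tgt_end - inv$tgt_start
  inv[, tgt_start := a + c(0L, cumsum(head(lens, -1L)))]
  inv[, tgt_end := tgt_start + lens]
  out <- rbind(segs[-inside], inv)
  new_truth_map(tm$src, tm$tgt, out)
}

#' Apply a tandem duplication to a truth map
#'
#' The derived interval `[a, b)` is copied in place directly after `b`;
#' copies are flagged `is_dup` and excluded from the canonical
#' parent-to-derived function (orthology keeps the original copy).
#'
#' @inheritParams tm_apply_inversion
#' @return the updated `truth_map`.
#' @export
tm_apply_duplication <- function(tm, chrom, a, b) {
  stopifnot(a < b)
  len <- b - a
  segs <- tm_split_at(tm_split_at(tm$segs, chrom, a), chrom, b)
  inside <- segs[, which(tgt_chrom == chrom & tgt_start >= a & tgt_end <= b)]
  copies <- data.table::copy(segs[inside])
  copies[, `:=`(tgt_start = tgt_start + len, tgt_end = tgt_end + len,
                is_dup = TRUE)]
  segs[tgt_chrom == chrom & tgt_start >= b,
       `:=`(tgt_start = tgt_start + len, tgt_end = tgt_end + len)]
  new_truth_map(tm$src, tm$tgt, rbind(segs, copies))
}

#' Apply a deletion to a truth map
#'
#' @inheritParams tm_apply_inversion
#' @return the updated `truth_map`.
#' @export
tm_apply_deletion <- function(tm, chrom, a, b) {
  stopifnot(a < b)
  len <- b - a
  segs <- tm_split_at(tm_split_at(tm$segs, chrom, a), chrom, b)
  inside <- segs[, which(tgt_chrom == chrom & tgt_start >= a & tgt_end <= b)]
  if (length(inside)) segs <- segs[-inside]
  segs[tgt_chrom == chrom & tgt_start >= b,
       `:=`(tgt_start = tgt_start - len, tgt_end = tgt_end - len)]
  new_truth_map(tm$src, tm$tgt, segs)
}

#' Apply an insertion to a truth map
#'
#' Inserts `len` derived-only nucleotides at derived position `a`.
#'
#' @param tm a `truth_map`.
#' @param chrom derived scaffold.
#' @param a 0-based derived position.
#' @param len insertion length.
#' @return the updated `truth_map`.
#' @export
tm_apply_insertion <- function(tm, chrom, a, len) {
  stopifnot(len > 0L)
  segs <- tm_split_at(tm$segs, chrom, a)
  segs[tgt_chrom == chrom & tgt_start >= a,
       `:=`(tgt_start = tgt_start + len, tgt_end = tgt_end + len)]
  ins <- data.table::data.table(
    src_chrom = NA_character_, src_start = NA_integer_, src_end = NA_integer_,
    tgt_chrom = chrom, tgt_start = as.integer(a), tgt_end = as.integer(a + len),
    strand = "+", type = "ins", is_dup = FALSE)
  new_truth_map(tm$src, tm$tgt, rbind(segs, ins))
}

#' Map a parent position to its derived position
#'
#' Uses the canonical function (duplicate copies and insertions
#' excluded). Returns `NULL` when the position was deleted.
#'
#' @param tm a `truth_map`.
#' @param chrom parent scaffold.
#' @param p 0-based parent position.
#' @return `NULL`, or a list with `chrom`, `pos`, `strand`.
#' @export
truth_map_point <- function(tm, chrom, p) {
  seg <- tm$segs[type == "block" & !is_dup & src_chrom == chrom &
                   src_start <= p & src_end > p]
  if (nrow(seg) == 0L) return(NULL)
  seg <- seg[1L]
  pos <- if (seg$strand == "+") seg$tgt_start + (p - seg$src_start) else
    seg$tgt_end - 1L - (p - seg$src_start)
  list(chrom = seg$tgt_chrom, pos = pos, strand = seg$strand)
}

#' Map a parent interval to derived coordinates
#'
#' Maps both end bases through the canonical function. `exact` is
#' `TRUE` when the image has the same length and a single consistent
#' orientation (no indel or breakpoint inside the interval).
#'
#' @param tm a `truth_map`.
#' @param chrom parent scaffold.
#' @param s,e 0-based half-open parent interval.
#' @return `NULL` (an end base deleted or ends on different derived
#'   scaffolds), or a list with `chrom`, `start`, `end`, `strand`,
#'   `exact`.
#' @export
truth_map_interval <- function(tm, chrom, s, e) {
  stopifnot(s < e)
  p1 <- truth_map_point(tm, chrom, s)
  p2 <- truth_map_point(tm, chrom, e - 1L)
  if (is.null(p1) || is.null(p2) || p1$chrom != p2$chrom) return(NULL)
  start <- min(p1$pos, p2$pos); end <- max(p1$pos, p2$pos) + 1L
  exact <- (end - start == e - s) && p1$strand == p2$strand
  list(chrom = p1$chrom, start = start, end = end,
       strand = p1$strand, exact = exact)
}

#' Invert a truth map
#'
#' The inverse maps derived coordinates back to the parent. Insertions
#' become unmapped; duplicate copies are kept (every derived position,
#' original or copy, has a parent origin).
#'
#' @param tm a `truth_map`.
#' @return the inverted `truth_map`.
#' @export
invert_truth <- function(tm) {
  b <- tm$segs[type == "block"]
  segs <- data.table::data.table(
    src_chrom = b$tgt_chrom, src_start = b$tgt_start, src_end = b$tgt_end,
    tgt_chrom = b$src_chrom, tgt_start = b$src_start, tgt_end = b$src_end,
    strand = b$strand, type = "block", is_dup = FALSE)
  new_truth_map(tm$tgt, tm$src, segs)
}

#' Compose two truth maps
#'
#' `compose_truth(m1, m2)` with `m1: X -> Y` and `m2: Y -> Z` yields the
#' canonical `X -> Z` map by intersecting segments in Y coordinates.
#'
#' @param m1,m2 `truth_map` objects with `m1$tgt == m2$src`.
#' @return the composed `truth_map`.
#' @export
compose_truth <- function(m1, m2) {
  if (m1$tgt != m2$src)
    stop("cannot compose: ", m1$tgt, " != ", m2$src)
  a <- m1$segs[type == "block" & !is_dup]
  b <- m2$segs[type == "block" & !is_dup]
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(new_truth_map(m1$src, m2$tgt, a[0L]))
  a2 <- data.table::data.table(chrom = a$tgt_chrom, start = a$tgt_start,
                               end = a$tgt_end, ai = seq_len(nrow(a)))
  b2 <- data.table::data.table(chrom = b$src_chrom, start = b$src_start,
                               end = b$src_end, bi = seq_len(nrow(b)))
  data.table::setkey(b2, chrom, start, end)
  ov <- data.table::foverlaps(a2, b2, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L)
    return(new_truth_map(m1$src, m2$tgt, a[0L]))
  rows <- lapply(seq_len(nrow(ov)), function(k) {
    ra <- a[ov$ai[k]]; rb <- b[ov$bi[k]]
    y1 <- max(ra$tgt_start, rb$src_start)
    y2 <- min(ra$tgt_end, rb$src_end)
    if (y1 >= y2) return(NULL)
    if (ra$strand == "+") {
      xs <- ra$src_start + (y1 - ra$tgt_start); xe <- ra$src_start + (y2 - ra$tgt_start)
    } else {
      xs <- ra$src_end - (y2 - ra$tgt_start); xe <- ra$src_end - (y1 - ra$tgt_start)
    }
    if (rb$strand == "+") {
      zs <- rb$tgt_start + (y1 - rb$src_start); ze <- rb$tgt_start + (y2 - rb$src_start)
    } else {
      zs <- rb$tgt_end - (y2 - rb$src_start); ze <- rb$tgt_end - (y1 - rb$src_start)
    }
    data.table::data.table(
      src_chrom = ra$src_chrom, src_start = xs, src_end = xe,
      tgt_chrom = rb$tgt_chrom, tgt_start = zs, tgt_end = ze,
      strand = compose_orient(ra$strand, rb$strand),
      type = "block", is_dup = FALSE)
  })
  new_truth_map(m1$src, m2$tgt, data.table::rbindlist(rows))
}

#' Which ground-truth segment contains a derived position
#'
#' @param tm a `truth_map`.
#' @param chrom derived scaffold.
#' @param pos 0-based derived position.
#' @return the row index into `tm$segs`, or `NA` if unmapped.
#' @export
truth_segment_of <- function(tm, chrom, pos) {
  i <- tm$segs[, which(tgt_chrom == chrom & tgt_start <= pos & tgt_end > pos)]
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' Emit exact synteny anchors from a truth map
#'
#' Block segments (duplicate copies excluded) of at least `min_len`
#' become anchors. With `jitter = TRUE` anchor ends are trimmed by
#' uniform 0--`max_trim` nt and `drop_frac` of anchors are dropped, to
#' mimic the raggedness of real synteny maps and exercise the widening
#' and splitting logic.
#'
#' @param tm a `truth_map`.
#' @param min_len minimum anchor length, nt.
#' @param jitter logical; default off (exact anchors).
#' @param max_trim maximum trim per end when jittering.
#' @param drop_frac fraction of anchors dropped when jittering.
#' @param weight optional edge weight for the resulting map.
#' @return a `synteny_map` from the parent genome to the derived genome.
#' @export
truth_to_anchors <- function(tm, min_len = 30L, jitter = FALSE,
                             max_trim = 20L, drop_frac = 0.05, weight = NULL) {
  segs <- tm$segs[type == "block" & !is_dup &
                    (src_end - src_start) >= min_len]
  anchors <- data.table::data.table(
    src_chrom = segs$src_chrom, src_start = segs$src_start,
    src_end = segs$src_end,
    tgt_chrom = segs$tgt_chrom, tgt_start = segs$tgt_start,
    tgt_end = segs$tgt_end, orientation = segs$strand)
  if (jitter && nrow(anchors) > 0L) {
    keep <- runif(nrow(anchors)) >= drop_frac
    anchors <- anchors[keep | seq_len(nrow(anchors)) <= 2L]  # never drop everything
    len <- anchors$src_end - anchors$src_start
    can_trim <- len > (2L * max_trim + 10L)
    t1 <- ifelse(can_trim, sample.int(max_trim + 1L, nrow(anchors), replace = TRUE) - 1L, 0L)
    t2 <- ifelse(can_trim, sample.int(max_trim + 1L, nrow(anchors), replace = TRUE) - 1L, 0L)
    anchors[, src_start := src_start + t1]
    anchors[, src_end := src_end - t2]
    fwd <- anchors$orientation == "+"
    anchors[, tgt_start := tgt_start + ifelse(fwd, t1, t2)]
    anchors[, tgt_end := tgt_end - ifelse(fwd, t2, t1)]
  }
  synteny_map(tm$src, tm$tgt, anchors, weight = weight)
}
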