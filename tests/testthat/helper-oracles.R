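# Independent oracles used across the suite. Each one is a
# straightforward, unoptimized re-derivation of the quantity it checks
# (linear scans, full DP matrices, quadratic loops), deliberately
# sharing no code with the implementation under test.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- linear-scan anchor lookup ---------------------------------------

# target base position of a source base inside an anchor, by direct
# proportional arithmetic
oracle_interp <- function(anc, p) {
  off <- p - anc$src_start
  toff <- floor(off * (anc$tgt_end - anc$tgt_start) /
                  (anc$src_end - anc$src_start))
  if (anc$orientation == "+") anc$tgt_start + toff else anc$tgt_end - 1L - toff
}

# resolve a source base position by scanning every anchor
oracle_resolve <- function(anchors, chrom, p, split_span = 50000L) {
  a <- anchors[anchors$src_chrom == chrom, ]
  a <- a[order(a$src_start), ]
  if (nrow(a) == 0L) return(NULL)
  for (i in seq_len(nrow(a))) {
    if (a$src_start[i] <= p && p < a$src_end[i]) {
      t <- oracle_interp(a[i, ], p)
      return(list(chrom = a$tgt_chrom[i], lo = t, hi = t + 1L,
                  orient = a$orientation[i]))
    }
  }
  before <- a[a$src_end <= p, ]
  after <- a[a$src_start > p, ]
  left <- if (nrow(before)) before[nrow(before), ] else NULL
  right <- if (nrow(after)) after[1L, ] else NULL
  inner <- function(r, side) {
    if (side == "left") { if (r$orientation == "+") r$tgt_end else r$tgt_start }
    else { if (r$orientation == "+") r$tgt_start else r$tgt_end }
  }
  if (!is.null(left) && !is.null(right) && left$tgt_chrom == right$tgt_chrom) {
    b <- c(inner(left, "left"), inner(right, "right"))
    return(list(chrom = left$tgt_chrom, lo = min(b), hi = max(b),
                orient = if (left$orientation == right$orientation)
                  left$orientation else NA_character_))
  }
  if (is.null(left) && is.null(right)) return(NULL)
  if (is.null(left)) { use <- right; side <- "right" }
  else if (is.null(right)) { use <- left; side <- "left" }
  else if ((p - left$src_end) <= (right$src_start - p)) { use <- left; side <- "left" }
  else { use <- right; side <- "right" }
  b <- inner(use, side)
  outward_hi <- (side == "left") == (use$orientation == "+")
  lo <- if (outward_hi) b else max(0L, b - split_span)
  hi <- if (outward_hi) b + split_span else b
  if (lo >= hi) { lo <- max(0L, b - 1L); hi <- b + 1L }
  list(chrom = use$tgt_chrom, lo = lo, hi = hi, orient = use$orientation)
}

# ---- naive sliding-window cross-correlation --------------------------

oracle_correlation <- function(src_mat, tgt_mat) {
  m <- nrow(src_mat); n <- nrow(tgt_mat)
  vapply(0:(n - m), function(lag)
    sum(src_mat * tgt_mat[lag + seq_len(m), , drop = FALSE]), numeric(1L))
}

# ---- full-matrix Gotoh local alignment (score only) ------------------

# unbanded three-state local Gotoh; rows vectorized, the in-row gap
# state folded in with the cummax identity
# E[j] = go + ge*j + max_{k<j} (M[k] - ge*k)
oracle_gotoh_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -3, gap_extend = -1) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  m <- length(av); n <- length(bv)
  Hprev <- numeric(n + 1L)
  Fprev <- rep(-Inf, n + 1L)
  best <- 0
  ge <- gap_extend; go <- gap_open
  for (i in seq_len(m)) {
    s <- ifelse(bv == av[i], match, mismatch)
    Fcur <- pmax(Fprev + ge, Hprev + go + ge)
    M <- pmax(0, c(0, Hprev[seq_len(n)] + s), c(-Inf, Fcur[-1L]))
    M[1L] <- 0
    A <- M - ge * (0:n)
    cmax <- cummax(A)
    E <- c(-Inf, go + ge * (1:n) + cmax[seq_len(n)])
    Hcur <- pmax(M, E)
    best <- max(best, max(Hcur))
    Hprev <- Hcur; Fprev <- Fcur
  }
  best
}

# ---- quadratic transcript-pair classifier ----------------------------

# classify one (source transcript, target transcript/locus) pair by
# looping over every exon pair; exons are data.frames with start, end,
# strand (0-based half-open)
oracle_classify_pair <- function(src_ex, tgt_ex, tgt_locus_span = NULL) {
  sense <- src_ex$strand[1L] == tgt_ex$strand[1L]
  hit_src <- rep(FALSE, nrow(src_ex)); hit_tgt <- rep(FALSE, nrow(tgt_ex))
  ov_nt <- 0L
  for (i in seq_len(nrow(src_ex))) for (j in seq_len(nrow(tgt_ex))) {
    o <- min(src_ex$end[i], tgt_ex$end[j]) - max(src_ex$start[i], tgt_ex$start[j])
    if (o > 0L) { hit_src[i] <- TRUE; hit_tgt[j] <- TRUE; ov_nt <- ov_nt + o }
  }
  if (any(hit_src)) {
    full <- all(hit_src) && all(hit_tgt)
    cls <- if (sense) { if (full) "full_sense" else "partial_sense" }
    else { if (full) "antisense_full" else "antisense_partial" }
    return(list(class = cls, n_overlap = sum(hit_src), overlap_nt = ov_nt))
  }
  span <- tgt_locus_span %||% c(min(tgt_ex$start), max(tgt_ex$end))
  tx_span <- c(min(src_ex$start), max(src_ex$end))
  if (min(tx_span[2L], span[2L]) - max(tx_span[1L], span[1L]) > 0L)
    return(list(class = if (sense) "intronic_sense" else "intronic_antisense",
                n_overlap = 0L, overlap_nt = 0L))
  list(class = "none", n_overlap = 0L, overlap_nt = 0L)
}

# ---- exhaustive shortest path ----------------------------------------

# minimum cost over all simple paths, by depth-first enumeration
oracle_shortest_path <- function(edges, from, to, weighted = TRUE) {
  best <- Inf
  recurse <- function(node, visited, cost) {
    if (cost >= best) return()
    if (node == to) { best <<- cost; return() }
    for (i in seq_len(nrow(edges))) {
      u <- edges$from[i]; v <- edges$to[i]
      nxt <- if (u == node) v else if (v == node) u else next
      if (nxt %in% visited) next
      recurse(nxt, c(visited, nxt), cost + if (weighted) edges$weight[i] else 1)
    }
  }
  recurse(from, from, 0)
  best
}

# ---- random transcript universes for classifier tests ----------------

# n isolated windows, each with one source and one target transcript;
# returns the two hierarchies plus per-window ids
make_tx_universe <- function(n_pairs, seed, window = 6000L) {
  set.seed(seed)
  mk_tx <- function(base, id, gid) {
    n_ex <- sample(1:4, 1L)
    starts <- sort(sample.int(window - 600L, n_ex))
    lens <- sample(50:200, n_ex, replace = TRUE)
    # enforce non-overlapping exons
    starts <- starts + cumsum(c(0L, rep(250L, n_ex - 1L)))
    data.table::data.table(
      chrom = "w", start = base + starts, end = base + starts + lens,
      strand = sample(c("+", "-"), 1L), gene_id = gid, transcript_id = id)
  }
  src <- list(); tgt <- list()
  for (i in seq_len(n_pairs)) {
    base <- (i - 1L) * window * 2L
    src[[i]] <- mk_tx(base, sprintf("s%06d", i), sprintf("sg%06d", i))
    tgt[[i]] <- mk_tx(base + sample(-400L:400L, 1L), sprintf("t%06d", i),
                      sprintf("tg%06d", i))
  }
  list(src = feature_hierarchy(data.table::rbindlist(src)),
       tgt = feature_hierarchy(data.table::rbindlist(tgt)),
       n = n_pairs)
}

# compare classify_overlaps() to the quadratic oracle over a universe;
# returns the number of disagreements
classifier_disagreements <- function(uni) {
  res <- classify_overlaps(uni$src, uni$tgt)
  bad <- 0L
  for (i in seq_len(uni$n)) {
    sid <- sprintf("s%06d", i); tid <- sprintf("t%06d", i)
    se <- as.data.frame(exons_of(uni$src, sid))
    te <- as.data.frame(exons_of(uni$tgt, tid))
    want <- oracle_classify_pair(se, te)
    rows <- res[res$src_transcript == sid]
    got <- if (want$class %in% c("intronic_sense", "intronic_antisense")) {
      r <- rows[rows$tgt_id == sprintf("tg%06d", i)]
      if (nrow(r)) r$class[1L] else "none"
    } else if (want$class == "none") {
      if (nrow(rows) == 1L && rows$class[1L] == "none") "none" else
        rows$class[1L]
    } else {
      r <- rows[rows$tgt_id == tid]
      if (nrow(r)) r$class[1L] else "none"
    }
    if (!identical(got, want$class)) bad <- bad + 1L
  }
  bad
}
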