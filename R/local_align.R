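# Exact target coordinates by banded gap-affine local alignment of the
# source sequence (or its 100 nt end chunks) against the
# cross-correlation candidate region, with binomial-tail significance.

#' Alignment scoring scheme
#'
#' Conventional nucleotide parameters; penalties are non-positive and a
#' gap of length L costs `gap_open + gap_extend * L`.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch penalty (<= 0, >= gap_open).
#' @param gap_open gap opening penalty (<= mismatch).
#' @param gap_extend gap extension penalty (<= 0).
#' @param band_halfwidth half-width of the alignment band, nt; must be
#'   at least the rapid-alignment flank so the band covers every
#'   placement the candidate region allows.
#' @param pvalue_threshold acceptance threshold on the binomial-tail
#'   p-value (default 1e-4).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -3,
                           gap_extend = -1, band_halfwidth = 16L,
                           pvalue_threshold = 1e-4) {
  if (!(gap_open <= mismatch && mismatch <= 0 && 0 < match))
    stop("need gap_open <= mismatch <= 0 < match")
  if (gap_extend > 0) stop("gap_extend must be non-positive")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 band_halfwidth = as.integer(band_halfwidth),
                 pvalue_threshold = pvalue_threshold),
            class = "scoring_scheme")
}

#' Banded gap-affine local alignment
#'
#' Three-state Gotoh dynamic program restricted to a diagonal band
#' around `band_center` (default: centered on the expected offset
#' `(|target| - |source|) / 2`, which for candidate regions of size
#' `|source| + 2*flank` is the flank). Alignments are local: they need
#' not cover the entire source, and the unaligned source offsets at
#' each end are reported as `k_start` / `k_end`. For acceptance, the
#' binomial trial count is the alignment length or the source length,
#' whichever is larger, so soft-clipped source bases count against
#' significance and a chance micro-alignment inside a long probe
#' cannot reach it.
#'
#' @param source_seq,target_seq nucleotide strings.
#' @param scheme a [scoring_scheme()].
#' @param band_center expected diagonal (target offset minus source
#'   offset).
#' @return an `alignment_result`: list with `score`, `src_start`,
#'   `src_end`, `tgt_start`, `tgt_end` (0-based half-open, local),
#'   `k_start`, `k_end`, `matches`, `length`, `p_value`, `accepted`.
#' @export
banded_affine_align <- function(source_seq, target_seq, scheme = scoring_scheme(),
                                band_center = NULL) {
  m <- nchar(source_seq); n <- nchar(target_seq)
  if (m == 0L || n == 0L) stop("empty sequence")
  if (is.null(band_center)) band_center <- (n - m) %/% 2L
  r <- .banded_align_cpp(source_seq, target_seq,
                         scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend,
                         as.integer(band_center), scheme$band_halfwidth)
  # trial count: at least the source length, so soft-clipped source
  # bases count as non-matches and a chance micro-alignment inside a
  # long probe cannot reach significance
  p <- alignment_pvalue(r$matches, max(r$length, m))
  structure(list(score = r$score,
                 src_start = r$src_start, src_end = r$src_end,
                 tgt_start = r$tgt_start, tgt_end = r$tgt_end,
                 k_start = r$src_start, k_end = m - r$src_end,
                 matches = r$matches, length = r$length,
                 p_value = p, accepted = p <= scheme$pvalue_threshold),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score=%g src=[%d,%d) tgt=[%d,%d) %d/%d matches p=%.3g %s\n",
              x$score, x$src_start, x$src_end, x$tgt_start, x$tgt_end,
              x$matches, x$length, x$p_value,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Binomial-tail significance of an alignment
#'
#' The p-value is the chance that a random alignment of the same length
#' achieves at least as many matches under a uniform 0.25 background:
#' `P(X >= matches)` for `X ~ Binomial(length, 0.25)`.
#'
#' @param matches number of matching columns.
#' @param length alignment length (columns, gaps included).
#' @return the p-value in (0, 1].
#' @export
alignment_pvalue <- function(matches, length) {
  if (length <= 0L || matches <= 0L) return(1)
  stats::pbinom(matches - 1L, length, 0.25, lower.tail = FALSE)
}

# mirror an interval within a region of length L (reverse-complement space)
mirror_interval <- function(s, e, L) c(L - e, L - s)

#' Refine a candidate interval to exact target coordinates
#'
#' Extracts the candidate region from the target genome (reverse
#' complement when the expected orientation is reverse), runs the
#' cross-correlation scan to find the tight sub-region, and aligns.
#' Sources of at most 100 nt are aligned whole; longer sources are
#' split into two 100 nt chunks at each end, aligned independently
#' against the corresponding ends of the candidate region. When an
#' alignment starts at offset k into the source, the target start is
#' adjusted by -k nucleotides (and symmetrically at the stop), so
#' translated boundaries remain exact even when terminal mismatches are
#' soft-clipped. Both chunks must be accepted and yield
#' `tgt_start < tgt_end` on one scaffold.
#'
#' @param source_seq the source feature's nucleotide sequence (source
#'   strand).
#' @param candidates list of one or two `candidate_interval`s
#'   ([translate_through_path()]).
#' @param target_genome the target `genome_seq`.
#' @param scheme a [scoring_scheme()].
#' @param flank_nt rapid-alignment flank (default 12).
#' @param block_log2 rapid-alignment block size exponent (default 14).
#' @param chunk_nt end-chunk size for long sources (default 100).
#' @return list with `ok`; on success `chrom`, `start`, `end` (target,
#'   0-based half-open), `orientation`, `p_value`, `score`,
#'   `k_start`, `k_end`; on failure `reason`.
#' @export
refine_feature <- function(source_seq, candidates, target_genome,
                           scheme = scoring_scheme(), flank_nt = 12L,
                           block_log2 = 14L, chunk_nt = 100L) {
  m <- nchar(source_seq)
  lens <- scaffold_lengths(target_genome)
  ori <- candidates[[1L]]$orientation

  # oriented region extraction: sequence as read along the source strand
  region_seq <- function(cand) {
    if (is.na(cand$chrom) || !cand$chrom %in% names(lens)) return(NULL)
    se <- clip_interval(cand$start, cand$end, lens[[cand$chrom]])
    if (is.null(se)) return(NULL)
    s <- get_seq(target_genome, cand$chrom, se[1L], se[2L])
    list(seq = if (ori == "-") revcomp(s) else s,
         start = se[1L], end = se[2L], len = se[2L] - se[1L])
  }
  # genome coordinates of an oriented-space interval within a region
  to_genome <- function(reg, s_rel, e_rel) {
    s_rel <- max(0L, s_rel); e_rel <- min(reg$len, e_rel)
    if (ori == "-") {
      mi <- mirror_interval(s_rel, e_rel, reg$len)
      c(reg$start + mi[1L], reg$start + mi[2L])
    } else c(reg$start + s_rel, reg$start + e_rel)
  }
  scan_then_align <- function(probe, reg) {
    if (nchar(probe) > reg$len) return(NULL)
    hit <- scan_blocks(probe, reg$seq, block_log2 = block_log2,
                       flank_nt = flank_nt)
    sub <- substr(reg$seq, hit$region_start + 1L, hit$region_end)
    aln <- banded_affine_align(probe, sub, scheme,
                               band_center = hit$offset - hit$region_start)
    aln$rel_start <- hit$region_start + aln$tgt_start - aln$k_start
    aln$rel_end <- hit$region_start + aln$tgt_end + aln$k_end
    aln
  }

  if (length(candidates) == 1L && m <= chunk_nt) {
    reg <- region_seq(candidates[[1L]])
    if (is.null(reg)) return(list(ok = FALSE, reason = "empty-region"))
    aln <- scan_then_align(source_seq, reg)
    if (is.null(aln)) return(list(ok = FALSE, reason = "region-too-short"))
    if (!aln$accepted)
      return(list(ok = FALSE, reason = "alignment-rejected",
                  p_value = aln$p_value))
    ge <- to_genome(reg, aln$rel_start, aln$rel_end)
    return(list(ok = TRUE, chrom = candidates[[1L]]$chrom,
                start = ge[1L], end = ge[2L], orientation = ori,
                p_value = aln$p_value, score = aln$score,
                k_start = aln$k_start, k_end = aln$k_end))
  }

  # long source and/or split candidate: align the two end chunks
  head_probe <- substr(source_seq, 1L, min(chunk_nt, m))
  tail_probe <- substr(source_seq, max(1L, m - chunk_nt + 1L), m)
  sub_len <- nchar(head_probe) + 2L * flank_nt
  # one oriented point -> genome position (clamped into the region)
  point_to_genome <- function(reg, x) {
    x <- max(0L, min(reg$len, as.integer(x)))
    if (ori == "-") reg$start + (reg$len - x) else reg$start + x
  }
  if (length(candidates) == 1L) {
    reg <- region_seq(candidates[[1L]])
    if (is.null(reg)) return(list(ok = FALSE, reason = "empty-region"))
    # localize the whole source first, then chunk the tight region's ends
    if (m <= 2L^block_log2 && m <= reg$len) {
      hit <- scan_blocks(source_seq, reg$seq, block_log2 = block_log2,
                         flank_nt = flank_nt)
      t0 <- hit$region_start; t1 <- hit$region_end
    } else { t0 <- 0L; t1 <- reg$len }
    toff <- max(t0, t1 - sub_len)
    parts <- list(
      head = list(seq = substr(reg$seq, t0 + 1L, min(t0 + sub_len, t1)),
                  off = t0, reg = reg),
      tail = list(seq = substr(reg$seq, toff + 1L, t1),
                  off = toff, reg = reg))
    chroms <- rep(candidates[[1L]]$chrom, 2L)
  } else {
    # split candidates: the chunk nearest each target bound goes to its
    # side; under reverse orientation the source head sits at the right
    sides <- vapply(candidates, `[[`, "", "split_side")
    if (!all(c("left", "right") %in% sides))
      return(list(ok = FALSE, reason = "split-side-missing"))
    left <- candidates[[match("left", sides)]]
    right <- candidates[[match("right", sides)]]
    head_cand <- if (ori == "+") left else right
    tail_cand <- if (ori == "+") right else left
    reg_h <- region_seq(head_cand); reg_t <- region_seq(tail_cand)
    if (is.null(reg_h) || is.null(reg_t))
      return(list(ok = FALSE, reason = "empty-region"))
    parts <- list(head = list(seq = reg_h$seq, off = 0L, reg = reg_h),
                  tail = list(seq = reg_t$seq, off = 0L, reg = reg_t))
    chroms <- c(head_cand$chrom, tail_cand$chrom)
    if (chroms[1L] != chroms[2L])
      return(list(ok = FALSE, reason = "split-sides-on-different-scaffolds"))
  }

  align_chunk <- function(probe, part) {
    if (nchar(probe) > nchar(part$seq)) return(NULL)
    hit <- scan_blocks(probe, part$seq, block_log2 = block_log2,
                       flank_nt = flank_nt)
    sub <- substr(part$seq, hit$region_start + 1L, hit$region_end)
    aln <- banded_affine_align(probe, sub, scheme,
                               band_center = hit$offset - hit$region_start)
    aln$rel_start <- part$off + hit$region_start + aln$tgt_start - aln$k_start
    aln$rel_end <- part$off + hit$region_start + aln$tgt_end + aln$k_end
    aln
  }
  ah <- align_chunk(head_probe, parts$head)
  at <- align_chunk(tail_probe, parts$tail)
  if (is.null(ah) || !ah$accepted)
    return(list(ok = FALSE, reason = "start-chunk-rejected",
                p_value = if (!is.null(ah)) ah$p_value else NA_real_))
  if (is.null(at) || !at$accepted)
    return(list(ok = FALSE, reason = "end-chunk-rejected",
                p_value = if (!is.null(at)) at$p_value else NA_real_))
  # oriented-space feature bounds: head start, tail end; map each
  # through its own region and order genomically
  p1 <- point_to_genome(parts$head$reg, ah$rel_start)
  p2 <- point_to_genome(parts$tail$reg, at$rel_end)
  start_g <- min(p1, p2); end_g <- max(p1, p2)
  if (start_g >= end_g)
    return(list(ok = FALSE, reason = "chunks-disagree"))
  list(ok = TRUE, chrom = chroms[1L], start = start_g, end = end_g,
       orientation = ori, p_value = max(ah$p_value, at$p_value),
       score = ah$score + at$score, k_start = ah$k_start, k_end = at$k_end)
}
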