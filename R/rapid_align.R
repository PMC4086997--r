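# Blockwise FFT cross-correlation search: locate the source sequence
# within a (possibly large) candidate target interval and emit a tight
# sub-region (|source| + 2*flank) for exact alignment.

#' One-hot encode a nucleotide sequence
#'
#' One indicator channel per base (A, C, G, T); N contributes zero to
#' all channels. Optionally mean-centered per channel, which removes
#' composition-bias spikes from the correlation.
#'
#' @param seq nucleotide string over {A,C,G,T,N}.
#' @param center subtract the per-channel mean.
#' @return numeric matrix, `nchar(seq)` rows by 4 columns (A,C,G,T).
#' @export
encode_sequence <- function(seq, center = TRUE) {
  r <- charToRaw(seq)
  m <- cbind(A = as.numeric(r == as.raw(65L)),
             C = as.numeric(r == as.raw(67L)),
             G = as.numeric(r == as.raw(71L)),
             T = as.numeric(r == as.raw(84L)))
  if (center) m <- sweep(m, 2L, colMeans(m))
  m
}

# summed per-channel linear cross-correlation via zero-padded FFT.
# Returns the correlation at lags 0..(nrow(tgt_mat) - nrow(src_mat)).
fft_cross_correlation <- function(src_mat, tgt_mat) {
  m <- nrow(src_mat); n <- nrow(tgt_mat)
  stopifnot(m <= n)
  P <- 2L^ceiling(log2(n + m))  # zero-padding kills circular wrap-around
  acc <- numeric(P)
  for (ch in 1:4) {
    s <- c(src_mat[, ch], numeric(P - m))
    t <- c(tgt_mat[, ch], numeric(P - n))
    acc <- acc + Re(fft(fft(t) * Conj(fft(s)), inverse = TRUE)) / P
  }
  acc[seq_len(n - m + 1L)]
}

#' Locate a source sequence in a target interval by cross-correlation
#'
#' The target is broken into overlapping blocks of `2^block_log2`
#' nucleotides (overlap `|source| + 2*flank_nt`, so every full-length
#' placement lies wholly within some block); the source is
#' cross-correlated against each block via FFT, and the block with the
#' highest absolute correlation peak is kept. The candidate region is
#' the best offset widened by `flank_nt` on each end. Targets shorter
#' than a block are correlated directly as a single block.
#'
#' @param source_seq source nucleotide string (at most `2^block_log2`
#'   nt).
#' @param target_seq target interval nucleotide string.
#' @param block_log2 log2 of the block size (default 14).
#' @param flank_nt flank on each end of the candidate region (default
#'   12).
#' @return a `correlation_hit`: list with `offset` (0-based placement of
#'   the source within the target interval), `peak` (absolute
#'   correlation), `block` (1-based best block index), `region_start`,
#'   `region_end` (candidate sub-interval of the target, clipped).
#' @export
scan_blocks <- function(source_seq, target_seq, block_log2 = 14L,
                        flank_nt = 12L) {
  m <- nchar(source_seq); n <- nchar(target_seq)
  B <- 2L^block_log2
  if (m > B)
    stop("source (", m, " nt) exceeds the block size 2^", block_log2)
  if (m > n)
    stop("target interval (", n, " nt) shorter than source (", m, " nt)")
  overlap <- m + 2L * flank_nt
  starts <- if (n <= B) 0L else {
    st <- seq.int(0L, n - 1L, by = max(B - overlap, 1L))
    st <- st[st + m <= n]
    unique(pmin(st, n - B))
  }
  src_mat <- encode_sequence(source_seq, center = TRUE)
  best <- list(peak = -Inf)
  for (bi in seq_along(starts)) {
    bs <- starts[bi]
    be <- min(n, bs + B)
    tgt_mat <- encode_sequence(substr(target_seq, bs + 1L, be), center = TRUE)
    cc <- fft_cross_correlation(src_mat, tgt_mat)
    k <- which.max(abs(cc))
    if (abs(cc[k]) > best$peak)
      best <- list(peak = abs(cc[k]), offset = bs + k - 1L, block = bi)
  }
  region <- c(max(0L, best$offset - flank_nt),
              min(n, best$offset + m + flank_nt))
  structure(list(offset = best$offset, peak = best$peak, block = best$block,
                 region_start = region[1L], region_end = region[2L]),
            class = "correlation_hit")
}
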