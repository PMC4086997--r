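`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of nucleotide strings
#'
#' @param seq character vector of sequences over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))))
}

#' Random DNA string
#'
#' Draws uniformly over {A,C,G,T}. Uses the current RNG state; callers
#' set the seed.
#'
#' @param n length in nucleotides.
#' @return a single string of length `n`.
#' @export
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Construct a genome sequence object
#'
#' A genome is a named set of scaffold sequences, case-folded to upper
#' with non-ACGTN symbols mapped to N.
#'
#' @param name genome identifier.
#' @param scaffolds named character vector, scaffold name -> sequence.
#' @return an object of class `genome_seq`.
#' @export
genome_seq <- function(name, scaffolds) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.character(scaffolds), length(scaffolds) >= 1L)
  if (is.null(names(scaffolds)) || anyNA(names(scaffolds)) || any(names(scaffolds) == ""))
    stop("every scaffold needs a name")
  if (anyDuplicated(names(scaffolds)))
    stop("duplicate scaffold name in genome '", name, "'")
  if (any(nchar(scaffolds) == 0L))
    stop("empty scaffold sequence in genome '", name, "'")
  scaffolds <- toupper(scaffolds)
  scaffolds <- vapply(scaffolds, function(s) gsub("[^ACGTN]", "N", s), character(1L))
  structure(list(name = name, scaffolds = scaffolds), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq>", x$name, "-", length(x$scaffolds), "scaffold(s),",
      sum(nchar(x$scaffolds)), "nt total\n")
  invisible(x)
}

#' Scaffold lengths of a genome
#'
#' @param genome a `genome_seq`.
#' @return named integer vector of scaffold lengths.
#' @export
scaffold_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  vapply(genome$scaffolds, nchar, integer(1L))
}

#' Extract a scaffold slice (0-based half-open)
#'
#' @param genome a `genome_seq`.
#' @param chrom scaffold name.
#' @param start,end 0-based half-open coordinates.
#' @return the nucleotide substring.
#' @export
get_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_seq"))
  s <- genome$scaffolds[[chrom]]
  if (is.null(s)) stop("scaffold '", chrom, "' not in genome '", genome$name, "'")
  if (start < 0 || end > nchar(s) || start >= end)
    stop(sprintf("slice [%d,%d) out of bounds for scaffold '%s' (length %d)",
                 start, end, chrom, nchar(s)))
  substr(s, start + 1L, end)
}

# clip an interval to [0, len); returns c(start, end) or NULL when empty
clip_interval <- function(start, end, len) {
  s <- max(0L, as.integer(start)); e <- min(as.integer(len), as.integer(end))
  if (s >= e) return(NULL)
  c(s, e)
}

# compose two orientation flags ("+"/"-"): reverse of reverse is forward
compose_orient <- function(a, b) ifelse(a == b, "+", "-")
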