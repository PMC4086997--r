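# End-to-end orchestration: load config, fix the translation path,
# translate every feature source -> target (anchor lookup, FFT scan,
# banded alignment), optionally match against native annotation, and
# report.

#' Translate one interval end to end
#'
#' Convenience wrapper: path lookup through the graph, candidate
#' translation, cross-correlation scan and banded refinement.
#'
#' @param graph a `synteny_graph`.
#' @param path a fixed `translation_path`.
#' @param genomes named list of `genome_seq` (must include source and
#'   target).
#' @param chrom,start,end source interval, 0-based half-open.
#' @param params parameter list ([default_params()]).
#' @param scheme a [scoring_scheme()].
#' @return list with `ok`; on success `chrom`, `start`, `end`,
#'   `orientation`, `p_value`; on failure `reason` (and `hop` when a
#'   path hop failed).
#' @export
translate_interval <- function(graph, path, genomes, chrom, start, end,
                               params = default_params(),
                               scheme = scoring_scheme()) {
  src_genome <- genomes[[path$genomes[1L]]]
  tgt_genome <- genomes[[path$genomes[length(path$genomes)]]]
  tr <- translate_through_path(graph, path, chrom, start, end,
                               params = params, genomes = genomes)
  if (!isTRUE(tr$ok)) return(tr)
  source_seq <- get_seq(src_genome, chrom, start, end)
  refine_feature(source_seq, tr$candidates, tgt_genome, scheme = scheme,
                 flank_nt = params$flank_nt, block_log2 = params$block_log2)
}

#' Run a full translation of a feature set
#'
#' Every feature (exon row) is attempted; untranslated features are
#' results, not failures. When `out_dir` is given, writes the
#' translated GTF (original attributes preserved verbatim plus
#' provenance), the `.unmapped.gtf` with failure reasons, the
#' relationship TSV (when `target_annotation` is given) and a JSON run
#' report.
#'
#' @param genomes named list of `genome_seq`.
#' @param graph a `synteny_graph` over those genomes.
#' @param features a `feature_hierarchy` (from [read_gtf()]) or a
#'   data.table of intervals with columns `chrom`, `start`, `end` and
#'   optionally `strand`, `transcript_id`, `gene_id`.
#' @param source,target genome names.
#' @param params parameter list ([default_params()]).
#' @param scheme a [scoring_scheme()].
#' @param path_mode `"hops"` or `"distance"`.
#' @param target_annotation optional native `feature_hierarchy` of the
#'   target genome for classification.
#' @param out_dir optional output directory.
#' @return list with `results` (per-feature data.table), `matches`
#'   (or NULL), `report` (totals, per-hop failure counts, path used).
#' @export
run_translate <- function(genomes, graph, features, source, target,
                          params = default_params(),
                          scheme = scoring_scheme(),
                          path_mode = c("hops", "distance"),
                          target_annotation = NULL, out_dir = NULL) {
  path_mode <- match.arg(path_mode)
  t0 <- Sys.time()
  path <- translation_path(graph, source, target, mode = path_mode)
  feats <- if (inherits(features, "feature_hierarchy")) features$exons else
    data.table::as.data.table(features)
  if (is.null(feats$strand)) feats[, strand := "+"]
  if (is.null(feats$transcript_id))
    feats[, transcript_id := sprintf("feat%06d", seq_len(.N))]
  if (is.null(feats$gene_id)) feats[, gene_id := transcript_id]
  for (col in c("source", "feature", "score", "frame"))
    if (is.null(feats[[col]]))
      feats[, (col) := if (col == "feature") "exon" else "."]
  if (is.null(feats$attrs))
    feats[, attrs := sprintf('gene_id "%s"; transcript_id "%s";',
                             gene_id, transcript_id)]
  path_str <- paste(path$genomes, collapse = "->")
  n <- nrow(feats)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    f <- feats[i]
    r <- translate_interval(graph, path, genomes, f$chrom, f$start, f$end,
                            params = params, scheme = scheme)
    res[[i]] <- if (isTRUE(r$ok)) {
      data.table::data.table(
        translated = TRUE, tgt_chrom = r$chrom, tgt_start = r$start,
        tgt_end = r$end,
        tgt_strand = compose_orient(f$strand, r$orientation),
        p_value = r$p_value, hop_failed = NA_integer_,
        reason = NA_character_)
    } else {
      data.table::data.table(
        translated = FALSE, tgt_chrom = NA_character_,
        tgt_start = NA_integer_, tgt_end = NA_integer_,
        tgt_strand = NA_character_, p_value = NA_real_,
        hop_failed = if (is.null(r$hop)) NA_integer_ else r$hop,
        reason = r$reason %||% "unknown")
    }
  }
  results <- cbind(feats, data.table::rbindlist(res))
  src_name <- source  # avoid capture of the GTF "source" column in j
  results[, `:=`(src_genome = src_name, path_used = path_str)]
  matches <- NULL
  if (!is.null(target_annotation)) {
    ok <- results[translated == TRUE]
    if (nrow(ok)) {
      trans_fh <- feature_hierarchy(data.table::data.table(
        chrom = ok$tgt_chrom, start = ok$tgt_start, end = ok$tgt_end,
        strand = ok$tgt_strand, gene_id = ok$gene_id,
        transcript_id = ok$transcript_id, attrs = ok$attrs))
      matches <- classify_overlaps(trans_fh, target_annotation)
    }
  }
  hop_fail <- results[translated == FALSE & !is.na(hop_failed),
                      .N, by = hop_failed]
  report <- list(
    source = source, target = target, path = path_str,
    path_mode = path_mode,
    total_features = n,
    translated = results[, sum(translated)],
    failed = results[, sum(!translated)],
    per_hop_failures = if (nrow(hop_fail))
      stats::setNames(as.list(hop_fail$N),
                      paste0("hop", hop_fail$hop_failed)) else list(),
    with_overlap = if (!is.null(matches))
      summarize_matches(matches, n, results[, sum(translated)],
                        mode = "pairwise")$with_overlap else NA_integer_,
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  stopifnot(report$translated + report$failed == report$total_features)
  if (!is.null(out_dir)) {
    files <- write_outputs(results, matches, out_dir,
                           prefix = paste0(source, "_to_", target))
    jsonlite::write_json(report,
                         file.path(out_dir, paste0(source, "_to_", target,
                                                   ".report.json")),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(results = results, matches = matches, report = report)
}

#' Evaluate translation results against a fixture manifest
#'
#' Joins per-feature results to the ground-truth coordinates and
#' reports the fraction translated, the fraction landing exactly on
#' the truth at both boundaries, and at least one boundary.
#'
#' @param manifest fixture manifest rows for the target genome
#'   (columns `transcript_id`, `exon_idx`, `chrom`, `start`, `end`,
#'   `status`).
#' @param results `$results` from [run_translate()] (needs
#'   `transcript_id`, `exon_idx` or per-row order matching the
#'   manifest).
#' @param by join columns (default `c("transcript_id", "exon_idx")`).
#' @return list of fractions: `translated`, `exact_both`, `exact_one`
#'   (computed over translated features), plus counts.
#' @export
run_evaluate <- function(manifest, results, by = c("transcript_id", "exon_idx")) {
  manifest <- data.table::as.data.table(manifest)
  results <- data.table::as.data.table(results)
  if (!all(by %in% names(results)) || !all(by %in% names(manifest)))
    stop("join columns missing: ", paste(by, collapse = ", "))
  j <- merge(results, manifest, by = by, suffixes = c("", ".truth"))
  if (nrow(j) == 0L) stop("no feature ids shared between manifest and results")
  n <- nrow(j)
  tr <- j[translated == TRUE & status != "lost"]
  exact_start <- tr$tgt_chrom == tr$chrom.truth & tr$tgt_start == tr$start.truth
  exact_end <- tr$tgt_chrom == tr$chrom.truth & tr$tgt_end == tr$end.truth
  list(total = n,
       translated_n = nrow(tr),
       translated = nrow(tr) / n,
       exact_both = if (nrow(tr)) mean(exact_start & exact_end) else NA_real_,
       exact_one = if (nrow(tr)) mean(exact_start | exact_end) else NA_real_)
}
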