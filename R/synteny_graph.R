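# Genomes as nodes, pairwise synteny maps as undirected edges. The
# translation path between any two genomes is fixed before any feature
# is translated, minimizing either hop count or accumulated genomic
# distance.

#' Build the synteny graph
#'
#' One node per declared genome, one undirected edge per configured map.
#' Unweighted edges (maps without a configured genomic distance) get
#' weight 1. Both directions of every map are materialized in memory
#' by inversion, so each map file needs to be supplied in one direction
#' only.
#'
#' @param genomes character vector of genome identifiers.
#' @param maps list of `synteny_map` objects; each endpoint must appear
#'   in `genomes`, and at most one map per genome pair is allowed.
#' @return an object of class `synteny_graph`.
#' @export
build_graph <- function(genomes, maps) {
  stopifnot(is.character(genomes), length(genomes) >= 1L)
  if (anyDuplicated(genomes)) stop("duplicate genome identifier")
  edges <- data.table::data.table(from = character(), to = character(),
                                  weight = numeric())
  directed <- new.env(parent = emptyenv())
  for (m in maps) {
    stopifnot(inherits(m, "synteny_map"))
    if (!m$src_genome %in% genomes || !m$tgt_genome %in% genomes)
      stop("map ", m$src_genome, "-", m$tgt_genome,
           " references an undeclared genome")
    if (m$src_genome == m$tgt_genome)
      stop("self-map for genome ", m$src_genome)
    key <- paste(sort(c(m$src_genome, m$tgt_genome)), collapse = "|")
    if (key %in% edges[, paste(pmin(from, to), pmax(from, to), sep = "|")])
      stop("duplicate map for genome pair ", key)
    edges <- rbind(edges, data.table::data.table(
      from = m$src_genome, to = m$tgt_genome,
      weight = as.numeric(m$weight %||% 1)))
    assign(paste0(m$src_genome, "->", m$tgt_genome), m, envir = directed)
    assign(paste0(m$tgt_genome, "->", m$src_genome), invert_map(m),
           envir = directed)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genomes))
  structure(list(genomes = genomes, edges = edges, directed = directed,
                 igraph = g),
            class = "synteny_graph")
}

#' @export
print.synteny_graph <- function(x, ...) {
  cat("<synteny_graph>", length(x$genomes), "genomes,", nrow(x$edges),
      "maps\n")
  invisible(x)
}

#' Fetch the directed map for one hop
#'
#' @param graph a `synteny_graph`.
#' @param from,to adjacent genomes.
#' @return the `synteny_map` oriented `from -> to`.
#' @export
hop_map <- function(graph, from, to) {
  m <- get0(paste0(from, "->", to), envir = graph$directed)
  if (is.null(m)) stop("no map between adjacent genomes ", from, " and ", to)
  m
}

#' Fix the translation path between two genomes
#'
#' Shortest path in the synteny graph: `mode = "hops"` minimizes the
#' number of indirect mappings, `mode = "distance"` minimizes the
#' accumulated genomic distances (edge weights). Ties are broken by
#' fewer hops first, then the lexicographically smallest sequence of
#' genome names, so runs are reproducible. The path is determined prior
#' to coordinate translation and fixed from there on.
#'
#' @param graph a `synteny_graph`.
#' @param source,target distinct genomes in the graph.
#' @param mode `"hops"` or `"distance"`.
#' @return an object of class `translation_path`: list with `genomes`
#'   (ordered identifiers, length >= 2) and `cost`.
#' @export
translation_path <- function(graph, source, target,
                             mode = c("hops", "distance")) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "synteny_graph"))
  if (!source %in% graph$genomes) stop("unknown genome: ", source)
  if (!target %in% graph$genomes) stop("unknown genome: ", target)
  if (source == target) stop("source and target are the same genome")
  w <- if (mode == "hops") rep(1, igraph::ecount(graph$igraph)) else
    igraph::E(graph$igraph)$weight
  sp <- suppressWarnings(igraph::all_shortest_paths(
    graph$igraph, from = source, to = target, weights = w))
  if (length(sp$res) == 0L)
    stop("no translation path between genomes '", source, "' and '",
         target, "': the synteny graph does not connect them")
  seqs <- lapply(sp$res, function(p) igraph::as_ids(p))
  lens <- lengths(seqs)
  seqs <- seqs[lens == min(lens)]
  keys <- vapply(seqs, paste, character(1L), collapse = "\x01")
  best <- seqs[[order(keys)[1L]]]
  cost <- if (mode == "hops") length(best) - 1 else {
    sum(vapply(seq_len(length(best) - 1L), function(i) {
      eid <- igraph::get_edge_ids(graph$igraph, c(best[i], best[i + 1L]))
      igraph::E(graph$igraph)$weight[eid]
    }, numeric(1L)))
  }
  structure(list(genomes = best, mode = mode, cost = cost),
            class = "translation_path")
}

#' @export
print.translation_path <- function(x, ...) {
  cat("<translation_path>", paste(x$genomes, collapse = " -> "),
      sprintf("(mode=%s, cost=%g)\n", x$mode, x$cost))
  invisible(x)
}

#' Precompute all pairwise translation paths
#'
#' @param graph a `synteny_graph`.
#' @param mode `"hops"` or `"distance"`.
#' @return named list of `translation_path` objects keyed
#'   `"<source>-><target>"`, covering every connected ordered pair.
#' @export
all_translation_paths <- function(graph, mode = c("hops", "distance")) {
  mode <- match.arg(mode)
  out <- list()
  for (u in graph$genomes) for (v in graph$genomes) {
    if (u == v) next
    p <- tryCatch(translation_path(graph, u, v, mode), error = function(e) NULL)
    if (!is.null(p)) out[[paste0(u, "->", v)]] <- p
  }
  out
}
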