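#' Build the k-dimensional de Bruijn graph over the DNA alphabet
#'
#' Vertices are all `4^k` DNA k-mers; there is a directed edge (u, v)
#' whenever the length-(k-1) suffix of `u` equals the length-(k-1) prefix of
#' `v`.  Every vertex therefore has out-degree 4, homopolymers carry a
#' self-loop, and the graph has exactly `4^(k+1)` edges.  Self-loops are
#' counted in the edge set but are ignored by all downstream connectivity
#' and path-spelling operations (a self-loop neither connects a vertex to a
#' neighbour nor extends a spelled path).
#'
#' @param k k-mer length; `1 <= k <= 12`.
#' @return An object of class `debruijn_graph` with elements `k`,
#'   `vertices` (all k-mers, lexicographic) and `n_edges`.
#' @examples
#' g <- build_debruijn(2)
#' length(g$vertices)  # 16
#' g$n_edges           # 64
#' @export
build_debruijn <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k != as.integer(k) || k < 1 || k > 12) {
    abort_param("k must be a single integer in [1, 12]")
  }
  k <- as.integer(k)
  structure(
    list(k = k, vertices = all_kmers(k), n_edges = 4^(k + 1)),
    class = "debruijn_graph"
  )
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf(
    "<debruijn_graph> k = %d: %d vertices, %d edges\n",
    x$k, length(x$vertices), x$n_edges
  ))
  invisible(x)
}

#' Successors of k-mers in a de Bruijn graph
#'
#' @param kmers character vector of k-mers.
#' @return Character matrix, one row per input k-mer, columns the four
#'   successors obtained by shifting one base (includes the self-loop
#'   successor for homopolymers).
#' @keywords internal
#' @noRd
debruijn_successors <- function(kmers, k = nchar(kmers[1])) {
  suf <- substr(kmers, 2L, k)
  matrix(
    paste0(rep(suf, times = 4), rep(DNA_BASES, each = length(kmers))),
    nrow = length(kmers)
  )
}

#' Test de Bruijn adjacency between two k-mers
#' @noRd
is_debruijn_edge <- function(u, v) {
  k <- nchar(u)
  substr(u, 2L, k) == substr(v, 1L, k - 1L)
}

#' Directed edge list of the de Bruijn graph restricted to a vertex set
#'
#' Returns the vertex-induced edge set (including self-loops) as a tibble
#' with columns `from` and `to`.
#' @noRd
induced_edges <- function(vertices, k = nchar(vertices[1])) {
  if (length(vertices) == 0) {
    return(tibble::tibble(from = character(0), to = character(0)))
  }
  succ <- debruijn_successors(vertices, k)
  from <- rep(vertices, times = 4)
  to <- as.vector(succ)
  keep <- to %in% vertices
  tibble::tibble(from = from[keep], to = to[keep]) |>
    dplyr::arrange(.data$from, .data$to)
}

#' Undirected adjacency list over a vertex set, self-loops dropped
#'
#' Neighbour relation used for cohesive-subgraph growth and connectivity:
#' u ~ v iff (u,v) or (v,u) is a de Bruijn edge and u != v.
#'
#' @return Named list mapping each vertex to an integer vector of neighbour
#'   indices (into `vertices`).
#' @noRd
undirected_adjacency <- function(vertices, k = nchar(vertices[1])) {
  n <- length(vertices)
  adj <- vector("list", n)
  if (n == 0) return(adj)
  edges <- induced_edges(vertices, k)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  fi <- match(edges$from, vertices)
  ti <- match(edges$to, vertices)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(edges)) {
    pairs <- unique(rbind(cbind(fi, ti), cbind(ti, fi)))
    sp <- split(pairs[, 2], pairs[, 1])
    for (key in names(sp)) adj[[as.integer(key)]] <- sort(unique(sp[[key]]))
  }
  names(adj) <- vertices
  adj
}

#' Induce an enhancer or silencer SRE graph from ranked k-mers
#'
#' Takes the `R` best-ranked k-mers (`side = "top"`, the enhancer graph) or
#' the `R` worst-ranked k-mers (`side = "bottom"`, the silencer graph) from
#' a ranking produced by [rank_kmers()], and induces the de Bruijn subgraph
#' on them.
#'
#' @param debruijn a [build_debruijn()] graph.
#' @param ranked tibble of ranked k-mer records from [rank_kmers()].
#' @param R number of vertices to keep; `1 <= R <= 4^k`.
#' @param side `"top"` (highest-scoring R k-mers, enhancer graph) or
#'   `"bottom"` (lowest-scoring R, silencer graph).
#' @return An object of class `sre_graph`: list with `element_type`
#'   (`"enhancer"` or `"silencer"`), `k`, `vertices` (sorted), `edges`
#'   (induced directed edge tibble, self-loops included) and `ranked`
#'   (the rows of `ranked` retained, for inspection/export).
#' @examples
#' g <- build_debruijn(2)
#' scores <- tibble::tibble(
#'   kmer = g$vertices,
#'   score = seq_along(g$vertices),
#'   label = "N"
#' )
#' sre_graph <- build_sre_graph(g, rank_kmers(scores, 2), R = 4, side = "top")
#' sre_graph$vertices
#' @export
build_sre_graph <- function(debruijn, ranked, R, side = c("top", "bottom")) {
  side <- match.arg(side)
  stopifnot(inherits(debruijn, "debruijn_graph"))
  n <- length(debruijn$vertices)
  if (!is.numeric(R) || length(R) != 1 || R != as.integer(R) || R < 1 || R > n) {
    abort_param(sprintf("R must be a single integer in [1, %d]", n))
  }
  R <- as.integer(R)
  keep_ranks <- if (side == "top") seq_len(R) else seq(n - R + 1L, n)
  kept <- ranked[ranked$rank %in% keep_ranks, , drop = FALSE]
  vertices <- sort(kept$kmer)
  structure(
    list(
      element_type = if (side == "top") "enhancer" else "silencer",
      k = debruijn$k,
      vertices = vertices,
      edges = induced_edges(vertices, debruijn$k),
      ranked = dplyr::arrange(kept, .data$rank)
    ),
    class = "sre_graph"
  )
}

#' @export
print.sre_graph <- function(x, ...) {
  cat(sprintf(
    "<sre_graph> %s: %d vertices, %d induced edges (k = %d)\n",
    x$element_type, length(x$vertices), nrow(x$edges), x$k
  ))
  invisible(x)
}

#' Export an SRE graph as edge-list and vertex-list TSVs
#'
#' @param graph an `sre_graph`.
#' @param edge_path,vertex_path output TSV paths.
#' @return `graph`, invisibly.
#' @export
write_sre_graph <- function(graph, edge_path, vertex_path) {
  stopifnot(inherits(graph, "sre_graph"))
  readr::write_tsv(graph$edges, edge_path)
  readr::write_tsv(
    dplyr::select(graph$ranked, "kmer", "rank", "score", "label"),
    vertex_path
  )
  invisible(graph)
}
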