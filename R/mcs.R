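#' Mine maximal alpha-cohesive connected subgraphs (MCSs)
#'
#' First mining level.  A connected induced subgraph of the SRE graph is
#' alpha-cohesive when its vertices co-occur in at least `alpha` exon
#' windows; it is maximal when no adjacent vertex can be added without the
#' shared-exon count dropping below `alpha`.  Every distinct maximal
#' alpha-cohesive connected subgraph is returned exactly once, together
#' with its shared exon set.  Overlapping subgraphs with common vertices
#' are all retained; by anti-monotonicity of the shared-exon operator no
#' returned vertex set can be a strict subset of another.
#'
#' Search: vertices with support below `alpha` are pruned up front, then
#' each surviving vertex seeds a depth-first growth over (undirected)
#' neighbours, with a canonical-form memo so no vertex set is expanded
#' twice.  Connectivity ignores edge direction and self-loops.
#'
#' @param graph an `sre_graph` from [build_sre_graph()].
#' @param matrix an `sre_profile` whose rows cover the graph's vertices.
#' @param alpha minimum number of shared exons, `>= 1`.
#' @return Tibble with one row per MCS: `mcs_id` (assigned after mining by
#'   sorting vertex sets lexicographically, so IDs are stable across runs),
#'   `element_type`, `kmers` (list-column of sorted k-mer sets), `n_exons`
#'   and `exons` (list-column of exon-ID sets).
#' @export
mine_mcs <- function(graph, matrix, alpha) {
  stopifnot(inherits(graph, "sre_graph"), inherits(matrix, "sre_profile"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 1) {
    abort_param("alpha must be a single integer >= 1")
  }
  alpha <- as.integer(alpha)
  missing <- setdiff(graph$vertices, matrix$kmers)
  if (length(missing)) {
    abort_input("profile rows must cover all SRE graph vertices")
  }

  # initial pruning: drop every vertex whose own support is below alpha
  vertices <- graph$vertices[
    vapply(graph$vertices, function(v) length(matrix$support[[v]]), 0L) >= alpha
  ]
  results <- new.env(parent = emptyenv())
  if (length(vertices)) {
    adj <- undirected_adjacency(vertices, graph$k)
    supports <- matrix$support[vertices]
    seen <- new.env(parent = emptyenv())

    grow <- function(members, tset) {
      key <- paste(members, collapse = " ")
      if (!is.null(seen[[key]])) return(invisible(NULL))
      seen[[key]] <- TRUE
      nbrs <- setdiff(sort(unique(unlist(adj[members]))), members)
      extended <- FALSE
      for (u in nbrs) {
        tu <- intersect(tset, supports[[u]])
        if (length(tu) >= alpha) {
          extended <- TRUE
          grow(sort(c(members, u)), tu)
        }
      }
      if (!extended) {
        # maximal: every adjacent extension violates alpha
        results[[key]] <- list(members = members, tset = tset)
      }
      invisible(NULL)
    }

    for (i in seq_along(vertices)) grow(i, supports[[i]])
  }

  found <- as.list(results)
  if (length(found) == 0) {
    return(tibble::tibble(
      mcs_id = integer(0),
      element_type = character(0),
      kmers = list(),
      n_exons = integer(0),
      exons = list()
    ))
  }
  kmer_sets <- unname(lapply(found, function(r) vertices[r$members]))
  exon_sets <- unname(lapply(found, function(r) sort(matrix$exons[r$tset])))
  ord <- order(vapply(kmer_sets, join_set, ""))
  tibble::tibble(
    mcs_id = seq_along(ord),
    element_type = graph$element_type,
    kmers = kmer_sets[ord],
    n_exons = lengths(exon_sets)[ord],
    exons = exon_sets[ord]
  )
}

#' Write an MCS table to TSV
#'
#' Columns: `mcs_id  element_type  kmers  n_exons  exon_ids`, with k-mer and
#' exon sets comma-joined.  Round-trips losslessly through
#' [read_mcs_table()].
#'
#' @param mcss MCS tibble from [mine_mcs()] (or a row-bound union of the
#'   enhancer and silencer runs, re-identified with [combine_mcs()]).
#' @param path output TSV path.
#' @return `mcss`, invisibly.
#' @export
write_mcs_table <- function(mcss, path) {
  if (anyDuplicated(mcss$mcs_id)) {
    rlang::abort("duplicate MCS ids", class = "sremine_internal_error")
  }
  tbl <- tibble::tibble(
    mcs_id = mcss$mcs_id,
    element_type = mcss$element_type,
    kmers = vapply(mcss$kmers, join_set, ""),
    n_exons = mcss$n_exons,
    exon_ids = vapply(mcss$exons, join_set, "")
  )
  readr::write_tsv(tbl, path)
  invisible(mcss)
}

#' Read an MCS table written by [write_mcs_table()]
#'
#' @param path TSV path.
#' @return MCS tibble with list-columns `kmers` and `exons`.
#' @export
read_mcs_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      mcs_id = readr::col_integer(),
      element_type = readr::col_character(),
      kmers = readr::col_character(),
      n_exons = readr::col_integer(),
      exon_ids = readr::col_character()
    )
  )
  tibble::tibble(
    mcs_id = tbl$mcs_id,
    element_type = tbl$element_type,
    kmers = split_set(tbl$kmers),
    n_exons = tbl$n_exons,
    exons = split_set(tbl$exon_ids)
  )
}

#' Combine enhancer and silencer MCS tables into one ID space
#'
#' The second mining level runs over the union of the two per-type MCS
#' tables; IDs are reassigned deterministically (enhancers first, each
#' block keeping its lexicographic vertex-set order).
#'
#' @param ... MCS tibbles from [mine_mcs()].
#' @return One MCS tibble with `mcs_id` = 1..n.
#' @export
combine_mcs <- function(...) {
  tbl <- dplyr::bind_rows(...)
  ord <- order(
    match(tbl$element_type, c("enhancer", "silencer")),
    vapply(tbl$kmers, join_set, "")
  )
  tbl <- tbl[ord, , drop = FALSE]
  tbl$mcs_id <- seq_len(nrow(tbl))
  tbl
}
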