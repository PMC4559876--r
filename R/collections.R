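#' Enumerate MCS collections sharing at least theta exons
#'
#' Second mining level.  A collection is a set of at least `beta` MCSs
#' (enhancers and silencers may mix) whose exon sets intersect in at least
#' `theta` exons.  Enumeration is exact: it walks the ordered
#' set-enumeration tree over MCS IDs (each member added must have a larger
#' ID than the current maximum, so every subset is generated exactly once)
#' and prunes a branch as soon as the shared-exon count drops below
#' `theta` — by anti-monotonicity of intersection no superset can recover,
#' so pruning never loses a qualifying collection.
#'
#' @param mcs_table MCS tibble ([mine_mcs()] / [combine_mcs()]).
#' @param theta minimum number of shared exons, `>= 1`.
#' @param beta minimum number of member MCSs, `>= 1`.
#' @param maximal_only if `TRUE`, keep only collections with no qualifying
#'   strict superset (default `FALSE`: every qualifying collection is
#'   reported).
#' @return Tibble with one row per collection: `collection_id`, `mcs_ids`
#'   (list-column, strictly increasing member IDs), `element_types`
#'   (list-column, matched to members), `n_shared_exons` and
#'   `shared_exons` (list-column), sorted by `n_shared_exons` descending
#'   then members lexicographically.
#' @export
enumerate_collections <- function(mcs_table, theta, beta, maximal_only = FALSE) {
  for (p in c(theta, beta)) {
    if (!is.numeric(p) || length(p) != 1 || p < 1) {
      abort_param("theta and beta must be single integers >= 1")
    }
  }
  theta <- as.integer(theta)
  beta <- as.integer(beta)
  empty <- tibble::tibble(
    collection_id = integer(0),
    mcs_ids = list(),
    element_types = list(),
    n_shared_exons = integer(0),
    shared_exons = list()
  )
  if (nrow(mcs_table) == 0) return(empty)

  ids <- mcs_table$mcs_id
  exon_sets <- mcs_table$exons
  n <- length(ids)
  acc <- vector("list", 0)

  descend <- function(members, tset, next_from) {
    if (length(members) >= beta) {
      acc[[length(acc) + 1L]] <<- list(members = ids[members], tset = tset)
    }
    if (next_from > n) return(invisible(NULL))
    for (j in next_from:n) {
      # the root carries the full exon universe, so the first member's
      # shared set is simply its own exon set
      tj <- if (is.null(tset)) exon_sets[[j]] else intersect(tset, exon_sets[[j]])
      if (length(tj) >= theta) descend(c(members, j), tj, j + 1L)
    }
    invisible(NULL)
  }
  descend(integer(0), NULL, 1L)
  if (length(acc) == 0) return(empty)

  member_sets <- lapply(acc, `[[`, "members")
  tsets <- lapply(acc, function(a) sort(a$tset))
  if (maximal_only) {
    keys <- lapply(member_sets, identity)
    is_max <- vapply(seq_along(keys), function(i) {
      !any(vapply(seq_along(keys), function(j) {
        j != i && length(keys[[j]]) > length(keys[[i]]) &&
          all(keys[[i]] %in% keys[[j]])
      }, logical(1)))
    }, logical(1))
    member_sets <- member_sets[is_max]
    tsets <- tsets[is_max]
  }
  ord <- order(
    -lengths(tsets),
    vapply(member_sets, function(m) paste(sprintf("%09d", m), collapse = " "), "")
  )
  member_sets <- member_sets[ord]
  tsets <- tsets[ord]
  type_of <- stats::setNames(mcs_table$element_type, ids)
  tibble::tibble(
    collection_id = seq_along(member_sets),
    mcs_ids = member_sets,
    element_types = lapply(member_sets, function(m) unname(type_of[as.character(m)])),
    n_shared_exons = lengths(tsets),
    shared_exons = tsets
  )
}

#' Tabulate collections for export
#'
#' One row per collection with comma-joined member IDs, element types,
#' member k-mer sets (when `mcs_table` is supplied) and shared exon IDs.
#'
#' @param collections tibble from [enumerate_collections()].
#' @param mcs_table optional MCS tibble used to spell out member k-mers.
#' @return Flat tibble ready for [readr::write_tsv()].
#' @export
collection_report <- function(collections, mcs_table = NULL) {
  out <- tibble::tibble(
    collection_id = collections$collection_id,
    mcs_ids = vapply(collections$mcs_ids, function(m) join_set(as.character(m)), ""),
    element_types = vapply(collections$element_types, join_set, ""),
    n_shared_exons = collections$n_shared_exons,
    shared_exon_ids = vapply(collections$shared_exons, join_set, "")
  )
  if (!is.null(mcs_table)) {
    kmers_of <- stats::setNames(
      vapply(mcs_table$kmers, join_set, ""),
      mcs_table$mcs_id
    )
    out <- dplyr::mutate(
      out,
      member_kmers = vapply(
        collections$mcs_ids,
        function(m) paste(kmers_of[as.character(m)], collapse = ";"),
        ""
      ),
      .after = "element_types"
    )
  }
  out
}

#' Read a collections TSV back into list-column form
#'
#' Inverse of `collection_report()` + `readr::write_tsv()`.
#'
#' @param path TSV path.
#' @return Collections tibble as from [enumerate_collections()].
#' @export
read_collection_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      collection_id = readr::col_integer(),
      mcs_ids = readr::col_character(),
      element_types = readr::col_character(),
      n_shared_exons = readr::col_integer(),
      shared_exon_ids = readr::col_character(),
      .default = readr::col_character()
    )
  )
  tibble::tibble(
    collection_id = tbl$collection_id,
    mcs_ids = lapply(split_set(tbl$mcs_ids), as.integer),
    element_types = split_set(tbl$element_types),
    n_shared_exons = tbl$n_shared_exons,
    shared_exons = split_set(tbl$shared_exon_ids)
  )
}
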