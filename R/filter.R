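#' Merge per-exon occurrences and emit combinatorial SRE sets
#'
#' Sequence-level filtering of one MCS collection.  Each member subgraph is
#' spelled ([spell_mcs()]), the spelled elements are located in every exon
#' window of the collection's shared exon set, and within each exon
#' occurrences of the same element type that overlap by at least one
#' nucleotide are transitively merged into a single longer element (its
#' sequence read off the exon itself).  Enhancer and silencer occurrences
#' may overlap and are both kept.  The resulting per-exon element multiset
#' is that exon's candidate set; identical candidate sets are aggregated
#' across exons, and a set is emitted when it is supported by at least
#' `theta` exons and still holds at least two elements (a collection whose
#' occurrences always collapse into one long element is dropped — it is a
#' single longer SRE, not a combinatorial set).
#'
#' With `merge_same_type = FALSE` the unmerged reading is emitted instead:
#' overlapping same-type elements are treated as distinct co-occurring
#' elements and no merging takes place.
#'
#' @param collection one-row slice of an [enumerate_collections()] tibble.
#' @param mcs_table the MCS tibble the collection indexes into.
#' @param windows [window_exons()] tibble covering the shared exons.
#' @param theta minimum supporting-exon count (same threshold as the
#'   collection mining stage).
#' @param merge_same_type merge overlapping same-type occurrences
#'   (default `TRUE`).
#' @return Tibble with one row per emitted SRE set: `elements`
#'   (list-column of element sequences), `element_types` (list-column,
#'   matched), `n_supporting_exons`, `supporting_exons` (list-column) and
#'   `source_collection`.  Sorted by support descending, then elements.
#' @export
merge_and_emit <- function(collection, mcs_table, windows, theta,
                           merge_same_type = TRUE) {
  stopifnot(is.data.frame(collection), nrow(collection) == 1)
  spelled <- spell_collection(collection, mcs_table)
  emit_sre_sets(
    spelled,
    shared = collection$shared_exons[[1]],
    windows = windows,
    theta = theta,
    merge_same_type = merge_same_type,
    source_collection = collection$collection_id[[1]]
  )
}

#' Spelled sequences of a collection's member subgraphs
#' @return Tibble `sequence`, `element_type`, `source_mcs`.
#' @noRd
spell_collection <- function(collection, mcs_table) {
  members <- collection$mcs_ids[[1]]
  rows <- match(members, mcs_table$mcs_id)
  if (anyNA(rows)) abort_input("collection references MCS ids not in mcs_table")
  purrr::map2_dfr(rows, members, function(r, id) {
    tibble::tibble(
      sequence = spell_mcs(mcs_table$kmers[[r]]),
      element_type = mcs_table$element_type[[r]],
      source_mcs = id
    )
  })
}

#' Shared emission machinery (exposed for the worked merge examples)
#' @noRd
emit_sre_sets <- function(spelled, shared, windows, theta, merge_same_type,
                          source_collection = NA_integer_) {
  empty <- tibble::tibble(
    elements = list(),
    element_types = list(),
    n_supporting_exons = integer(0),
    supporting_exons = list(),
    source_collection = integer(0)
  )
  if (nrow(spelled) == 0 || length(shared) == 0) return(empty)
  win <- windows[match(shared, windows$exon_id), , drop = FALSE]
  if (anyNA(win$exon_id)) abort_input("windows must cover the shared exon set")

  per_exon <- lapply(seq_along(shared), function(j) {
    layout <- exon_layout(
      spelled, win$sequence[[j]],
      merge_same_type = merge_same_type
    )
    if (nrow(layout) == 0) return(NULL)
    # candidate-set identity: order-insensitive multiset of (sequence, type)
    key_tbl <- dplyr::arrange(layout, .data$element_type, .data$sequence)
    tibble::tibble(
      exon_id = shared[j],
      key = paste(
        paste(key_tbl$element_type, key_tbl$sequence, sep = ":"),
        collapse = "|"
      ),
      layout = list(key_tbl)
    )
  })
  cand <- dplyr::bind_rows(per_exon)
  if (nrow(cand) == 0) return(empty)

  agg <- cand |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      layout = .data$layout[1],
      supporting_exons = list(sort(.data$exon_id)),
      n_supporting_exons = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(
      .data$n_supporting_exons >= theta,
      vapply(.data$layout, nrow, 0L) >= 2L
    )
  if (nrow(agg) == 0) return(empty)
  out <- tibble::tibble(
    elements = lapply(agg$layout, function(l) l$sequence),
    element_types = lapply(agg$layout, function(l) l$element_type),
    n_supporting_exons = as.integer(agg$n_supporting_exons),
    supporting_exons = agg$supporting_exons,
    source_collection = as.integer(source_collection)
  )
  ord <- order(
    -out$n_supporting_exons,
    vapply(out$elements, join_set, "")
  )
  out[ord, , drop = FALSE]
}

#' Witnessed element layout of one exon window
#'
#' Locates typed element sequences in a window and applies the same-type
#' overlap merge, returning the final per-exon layout: one row per element
#' actually present, with 1-based inclusive coordinates.  This is the
#' per-exon witness view behind [merge_and_emit()]: merged elements span
#' `[min(start), max(end)]` of the occurrences they absorb and their
#' sequence is read off the window itself.
#'
#' @param sequences character vector of element sequences.
#' @param types matching element types (`"enhancer"`/`"silencer"`).
#' @param window a single window sequence (or one-row [window_exons()]
#'   slice).
#' @param merge_same_type merge overlapping same-type occurrences
#'   (default `TRUE`).
#' @return Tibble `sequence`, `element_type`, `start`, `end`.
#' @examples
#' merge_occurrences(
#'   c("CCCGGA", "CCGGAG"), c("enhancer", "enhancer"),
#'   "TTCCCGGAGTT"
#' )
#' @export
merge_occurrences <- function(sequences, types, window,
                              merge_same_type = TRUE) {
  stopifnot(length(sequences) == length(types))
  if (is.data.frame(window)) {
    stopifnot(nrow(window) == 1)
    window <- window$sequence[[1]]
  }
  exon_layout(
    tibble::tibble(
      sequence = sequences,
      element_type = types,
      source_mcs = seq_along(sequences)
    ),
    window,
    merge_same_type = merge_same_type
  )
}

#' Per-exon witnessed layout: occurrences merged within one window
#'
#' All occurrences of all spelled elements are located in the window; runs
#' of same-type occurrences that overlap by >= 1 nt are transitively merged
#' into one element whose sequence is the window substring spanning the
#' run.  Different-type overlaps are left intact.
#'
#' @return Tibble `sequence`, `element_type`, `start`, `end` (1-based
#'   inclusive window coordinates of each final element).
#' @noRd
exon_layout <- function(spelled, window, merge_same_type = TRUE) {
  occ <- locate_occurrences(spelled$sequence, window)
  if (nrow(occ) == 0) {
    return(tibble::tibble(
      sequence = character(0), element_type = character(0),
      start = integer(0), end = integer(0)
    ))
  }
  occ$element_type <- spelled$element_type[occ$seq_index]
  merged <- lapply(split(occ, occ$element_type), function(grp) {
    if (!merge_same_type) {
      return(grp[c("sequence", "start", "end")])
    }
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    # transitive interval merge: extend the current run while the next
    # occurrence starts at or before the running end
    starts <- integer(0)
    ends <- integer(0)
    cur_s <- grp$start[1]
    cur_e <- grp$end[1]
    for (i in seq_len(nrow(grp))[-1]) {
      if (grp$start[i] <= cur_e) {
        cur_e <- max(cur_e, grp$end[i])
      } else {
        starts <- c(starts, cur_s)
        ends <- c(ends, cur_e)
        cur_s <- grp$start[i]
        cur_e <- grp$end[i]
      }
    }
    starts <- c(starts, cur_s)
    ends <- c(ends, cur_e)
    tibble::tibble(
      sequence = substring(window, starts, ends),
      start = starts,
      end = ends
    )
  })
  out <- dplyr::bind_rows(merged, .id = "element_type")
  dplyr::arrange(
    out[c("sequence", "element_type", "start", "end")],
    .data$start, .data$element_type
  )
}

#' Filter every collection of a run and bind the emitted SRE sets
#'
#' Convenience wrapper applying [merge_and_emit()] across a collections
#' table.  Duplicate emitted sets arising from different collections are
#' kept (each carries its `source_collection`).
#'
#' @inheritParams merge_and_emit
#' @param collections full [enumerate_collections()] tibble.
#' @return Row-bound SRE-set tibble (possibly zero rows).
#' @export
filter_collections <- function(collections, mcs_table, windows, theta,
                               merge_same_type = TRUE) {
  sets <- lapply(seq_len(nrow(collections)), function(i) {
    merge_and_emit(
      collections[i, , drop = FALSE], mcs_table, windows, theta,
      merge_same_type = merge_same_type
    )
  })
  out <- dplyr::bind_rows(sets)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      elements = list(),
      element_types = list(),
      n_supporting_exons = integer(0),
      supporting_exons = list(),
      source_collection = integer(0)
    ))
  }
  out
}

#' Write an SRE-set table to TSV
#'
#' Columns `sre_set  element_types  n_exons  source_collection`, with the
#' element sequences and their types comma-joined in matching order.
#'
#' @param sre_sets tibble from [filter_collections()] / [merge_and_emit()].
#' @param path output TSV path.
#' @return `sre_sets`, invisibly.
#' @export
write_sre_sets <- function(sre_sets, path) {
  tbl <- tibble::tibble(
    sre_set = vapply(sre_sets$elements, join_set, ""),
    element_types = vapply(sre_sets$element_types, join_set, ""),
    n_exons = sre_sets$n_supporting_exons,
    source_collection = sre_sets$source_collection
  )
  readr::write_tsv(tbl, path)
  invisible(sre_sets)
}
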