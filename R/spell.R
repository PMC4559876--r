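#' Spell the sequences of an MCS
#'
#' Maps a maximal cohesive subgraph back to nucleotide sequences: every
#' maximal simple path through the induced (directed) de Bruijn subgraph is
#' spelled by overlapping its k-mers, so a chain of m consecutive k-mers
#' yields one (m + k - 1)-mer.  Spellings that are substrings of another
#' spelling for the same subgraph are dropped; a single vertex spells
#' itself; self-loops never extend a path.
#'
#' @param kmers character vector of the MCS's k-mers (a `vertex_set`), or a
#'   one-row slice of a [mine_mcs()] tibble.
#' @return Character vector of spelled sequences, sorted, each of length
#'   `>= k`.
#' @examples
#' spell_mcs(c("GTCATC", "TCATCC"))  # "GTCATCC"
#' @export
spell_mcs <- function(kmers) {
  if (is.data.frame(kmers)) {
    stopifnot(nrow(kmers) == 1)
    kmers <- kmers$kmers[[1]]
  }
  kmers <- unique(as.character(kmers))
  if (length(kmers) == 0) return(character(0))
  check_kmers(kmers)
  k <- nchar(kmers[[1]])
  n <- length(kmers)

  # directed successors within the vertex set, self-loops excluded
  succ <- lapply(seq_len(n), function(i) {
    which(vapply(kmers, is_debruijn_edge, u = kmers[i], logical(1)) &
      seq_len(n) != i)
  })

  paths <- list()
  walk <- function(path) {
    nxt <- setdiff(succ[[path[length(path)]]], path)
    if (length(nxt) == 0) {
      paths[[length(paths) + 1L]] <<- path
    } else {
      for (u in nxt) walk(c(path, u))
    }
    invisible(NULL)
  }
  for (i in seq_len(n)) walk(i)

  spelled <- vapply(paths, function(p) {
    paste0(kmers[p[1]], paste(substr(kmers[p[-1]], k, k), collapse = ""))
  }, "")
  spelled <- unique(spelled)
  # drop spellings subsumed as substrings of longer spellings
  keep <- vapply(seq_along(spelled), function(i) {
    !any(vapply(seq_along(spelled), function(j) {
      j != i && nchar(spelled[j]) > nchar(spelled[i]) &&
        grepl(spelled[i], spelled[j], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  sort(spelled[keep])
}

#' Locate element sequences in an exon window
#'
#' Finds every exact occurrence (all offsets, overlapping allowed) of each
#' query sequence in a window.  Coordinates are 1-based inclusive.
#'
#' @param sequences character vector of element sequences.
#' @param window a single window sequence, or a one-row slice of a
#'   [window_exons()] tibble.
#' @return Tibble with columns `seq_index`, `sequence`, `start`, `end`.
#' @export
locate_occurrences <- function(sequences, window) {
  if (is.data.frame(window)) {
    stopifnot(nrow(window) == 1)
    window <- window$sequence[[1]]
  }
  stopifnot(is.character(window), length(window) == 1)
  n <- nchar(window)
  out <- lapply(seq_along(sequences), function(i) {
    len <- nchar(sequences[i])
    if (len == 0 || len > n) return(NULL)
    starts <- seq_len(n - len + 1L)
    hit <- substring(window, starts, starts + len - 1L) == sequences[i]
    if (!any(hit)) return(NULL)
    tibble::tibble(
      seq_index = i,
      sequence = sequences[i],
      start = starts[hit],
      end = starts[hit] + len - 1L
    )
  })
  found <- dplyr::bind_rows(out)
  if (nrow(found) == 0) {
    return(tibble::tibble(
      seq_index = integer(0), sequence = character(0),
      start = integer(0), end = integer(0)
    ))
  }
  dplyr::arrange(found, .data$start, .data$seq_index)
}
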