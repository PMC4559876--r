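#' Extract the fixed analysis window from exon sequences
#'
#' Takes the first (or last) `W` nucleotides of each exon; exons shorter
#' than `W` contribute their whole sequence.  Element occurrence downstream
#' is always evaluated on these windows, never on the full exon.
#'
#' @param records exon sequences: a `Biostrings::DNAStringSet` (as returned
#'   by [read_exon_fasta()]), a named character vector, or a data frame with
#'   columns `exon_id` and `sequence`.
#' @param W window length in nucleotides (default 50).
#' @param end `"first"` to take the leading window, `"last"` the trailing
#'   window.
#' @return Tibble with columns `exon_id`, `sequence` (the uppercased
#'   window), `window_used` and `full_length`.
#' @examples
#' window_exons(c(ex1 = "acgtacgtacgt"), W = 8)
#' @export
window_exons <- function(records, W = 50, end = c("first", "last")) {
  end <- match.arg(end)
  if (!is.numeric(W) || length(W) != 1 || W < 1) {
    abort_param("W must be a single positive integer")
  }
  W <- as.integer(W)
  if (inherits(records, "DNAStringSet")) {
    records <- stats::setNames(as.character(records), names(records))
  }
  if (is.character(records)) {
    if (is.null(names(records)) || any(names(records) == "")) {
      abort_input("exon sequences must be named by exon_id")
    }
    records <- tibble::tibble(
      exon_id = names(records),
      sequence = unname(records)
    )
  }
  stopifnot(is.data.frame(records))
  if (!all(c("exon_id", "sequence") %in% names(records))) {
    abort_input("exon records need columns exon_id and sequence")
  }
  if (nrow(records) == 0) abort_input("no exon records supplied")
  ids <- sub("\\s.*$", "", as.character(records$exon_id))
  if (anyDuplicated(ids)) abort_input("duplicate exon IDs in input")
  seqs <- toupper(as.character(records$sequence))
  full <- nchar(seqs)
  win <- if (end == "first") {
    substr(seqs, 1L, pmin(W, full))
  } else {
    substr(seqs, pmax(1L, full - W + 1L), full)
  }
  tibble::tibble(
    exon_id = ids,
    sequence = win,
    window_used = end,
    full_length = full
  )
}

#' Read exon sequences from FASTA
#'
#' The exon ID is the first whitespace-delimited token of each header.
#' Duplicate IDs are an error: exon supports are sets of IDs.
#'
#' @param path FASTA path.
#' @return Named character vector of uppercased sequences.
#' @export
read_exon_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort_input("empty FASTA input")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) abort_input("duplicate exon IDs in FASTA")
  stats::setNames(toupper(as.character(seqs)), ids)
}

#' Build the sparse k-mer-by-exon occurrence profile
#'
#' For each k-mer of an SRE graph's vertex set, records which exon windows
#' contain it at least once as an exact substring (overlapping occurrences
#' allowed; presence is binary).  Windows may contain ambiguity codes; a
#' position overlapping any non-ACGT character never matches.
#'
#' @param sre_vertices character vector of k-mers (all the same length), or
#'   an `sre_graph` whose vertex set is used.
#' @param windows tibble from [window_exons()].
#' @return An object of class `sre_profile`: list with `kmers`, `exons`
#'   (the exon_id universe, in input order), `k`, and `support`, a named
#'   list mapping each k-mer to the sorted integer indices (into `exons`)
#'   of the windows containing it.
#' @examples
#' w <- window_exons(c(e1 = "AAGTCATCAA", e2 = "TTTTTTTTTT"), W = 10)
#' p <- build_profile("GTCATC", w)
#' shared_exons(p, "GTCATC")
#' @export
build_profile <- function(sre_vertices, windows) {
  if (inherits(sre_vertices, "sre_graph")) sre_vertices <- sre_vertices$vertices
  sre_vertices <- unique(as.character(sre_vertices))
  stopifnot(is.data.frame(windows), all(c("exon_id", "sequence") %in% names(windows)))
  support <- list()
  k <- NA_integer_
  if (length(sre_vertices)) {
    check_kmers(sre_vertices)
    k <- nchar(sre_vertices[[1]])
    hits <- vector("list", nrow(windows))
    for (j in seq_len(nrow(windows))) {
      found <- intersect(window_kmers(windows$sequence[[j]], k), sre_vertices)
      hits[[j]] <- found
    }
    pair_kmer <- unlist(hits, use.names = FALSE)
    pair_exon <- rep(seq_len(nrow(windows)), lengths(hits))
    support <- split(pair_exon, factor(pair_kmer, levels = sre_vertices))
    support <- lapply(support, function(x) sort(unique(x)))
  }
  structure(
    list(
      kmers = sre_vertices,
      exons = windows$exon_id,
      k = k,
      support = support
    ),
    class = "sre_profile"
  )
}

#' Distinct ACGT-only k-mers occurring in one window
#' @noRd
window_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  unique(kmers[!grepl("[^ACGT]", kmers)])
}

#' @export
print.sre_profile <- function(x, ...) {
  cat(sprintf(
    "<sre_profile> %d k-mers x %d exons, %d presence entries\n",
    length(x$kmers), length(x$exons), sum(lengths(x$support))
  ))
  invisible(x)
}

#' Exons shared by a set of k-mers
#'
#' Returns the intersection of the per-k-mer exon supports, i.e. the set of
#' exons whose windows contain every queried k-mer.  The empty query
#' returns the full exon universe (the neutral element of intersection).
#'
#' @param matrix an `sre_profile` from [build_profile()].
#' @param kmers character vector of k-mers, all rows of the profile.
#' @return Character vector of exon IDs.
#' @export
shared_exons <- function(matrix, kmers) {
  stopifnot(inherits(matrix, "sre_profile"))
  kmers <- unique(as.character(kmers))
  if (length(kmers) == 0) return(matrix$exons)
  unknown <- setdiff(kmers, matrix$kmers)
  if (length(unknown)) {
    abort_query(sprintf(
      "k-mer(s) not in profile: %s", paste(unknown, collapse = ", ")
    ))
  }
  idx <- Reduce(intersect, matrix$support[kmers])
  matrix$exons[idx]
}

#' Integer-index support intersection (mining hot path)
#' @noRd
support_intersection <- function(profile, kmers) {
  Reduce(intersect, profile$support[kmers])
}

#' Write a sparse profile as presence triplets
#'
#' One row per (k-mer, exon) presence pair, TSV with header
#' `kmer  exon_id`.
#'
#' @param profile an `sre_profile`.
#' @param path output TSV path.
#' @return `profile`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sre_profile"))
  tbl <- tibble::tibble(
    kmer = rep(profile$kmers, lengths(profile$support[profile$kmers])),
    exon_id = profile$exons[unlist(profile$support[profile$kmers], use.names = FALSE)]
  )
  readr::write_tsv(tbl, path)
  invisible(profile)
}
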