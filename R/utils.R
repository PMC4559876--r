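DNA_BASES <- c("A", "C", "G", "T")

#' Enumerate all k-mers over the DNA alphabet
#'
#' @param k k-mer length.
#' @return Character vector of all `4^k` k-mers in lexicographic order
#'   (A < C < G < T).
#' @keywords internal
#' @noRd
all_kmers <- function(k) {
  stopifnot(k >= 1)
  out <- DNA_BASES
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      out <- as.vector(outer(out, DNA_BASES, paste0))
    }
  }
  sort(out)
}

abort_param <- function(msg) rlang::abort(msg, class = "sremine_parameter_error")
abort_input <- function(msg) rlang::abort(msg, class = "sremine_input_error")
abort_query <- function(msg) rlang::abort(msg, class = "sremine_query_error")

check_kmers <- function(kmers, k = NULL) {
  if (length(kmers) == 0) return(invisible(kmers))
  if (is.null(k)) k <- nchar(kmers[[1]])
  if (any(nchar(kmers) != k)) {
    abort_input(sprintf("all k-mers must have length %d", k))
  }
  if (any(grepl("[^ACGT]", kmers))) {
    abort_input("k-mers must use the alphabet {A,C,G,T} only")
  }
  invisible(kmers)
}

#' Comma-join a character vector (set serialisation used in all TSV outputs)
#' @noRd
join_set <- function(x) paste(x, collapse = ",")

split_set <- function(x) {
  ifelse_empty <- function(v) if (length(v) == 1 && v == "") character(0) else v
  lapply(strsplit(x, ",", fixed = TRUE), ifelse_empty)
}
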