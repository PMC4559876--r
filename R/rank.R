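#' Rank k-mers by enrichment score
#'
#' Orders all `4^k` k-mers by score in descending order and assigns ranks
#' 1..`4^k`.  Neutral k-mers are forced to score 0 before ranking (a k-mer
#' without enhancing or silencing evidence carries no signal).  Ties are
#' broken by lexicographic k-mer order (A < C < G < T) so ranking is
#' deterministic.
#'
#' @param scores data frame with columns `kmer`, `score` and `label`; labels
#'   are `"E"`/`"enhancer"`, `"S"`/`"silencer"` or `"N"`/`"neutral"`.
#'   K-mers absent from the table are filled in as neutral with score 0.
#' @param k k-mer length; every `kmer` must have this length.
#' @return Tibble with columns `kmer`, `score`, `label`
#'   (`enhancer`/`silencer`/`neutral`) and `rank`, sorted by rank.  Rank 1
#'   is the strongest enhancer evidence; rank `4^k` the strongest silencer
#'   evidence.
#' @examples
#' scores <- tibble::tibble(
#'   kmer = c("AA", "AC", "AG"),
#'   score = c(1.2, -0.5, 0.3),
#'   label = c("E", "S", "E")
#' )
#' rank_kmers(scores, k = 2)
#' @export
rank_kmers <- function(scores, k) {
  stopifnot(is.data.frame(scores))
  req <- c("kmer", "score", "label")
  if (!all(req %in% names(scores))) {
    abort_input("score table must have columns kmer, score, label")
  }
  scores <- tibble::as_tibble(scores)[req]
  scores$kmer <- toupper(scores$kmer)
  check_kmers(scores$kmer, k)
  if (anyDuplicated(scores$kmer)) {
    abort_input("duplicate k-mer rows in score table")
  }
  scores$label <- normalize_label(scores$label)
  scores$score <- as.numeric(scores$score)
  if (anyNA(scores$score)) abort_input("scores must be numeric and non-missing")
  # neutral evidence means no measured effect: score is defined to be zero
  scores$score[scores$label == "neutral"] <- 0

  universe <- all_kmers(k)
  missing <- setdiff(universe, scores$kmer)
  if (length(missing)) {
    scores <- dplyr::bind_rows(
      scores,
      tibble::tibble(kmer = missing, score = 0, label = "neutral")
    )
  }
  scores <- dplyr::arrange(scores, dplyr::desc(.data$score), .data$kmer)
  scores$rank <- seq_len(nrow(scores))
  scores
}

normalize_label <- function(label) {
  lab <- tolower(as.character(label))
  out <- dplyr::case_match(
    lab,
    c("e", "enhancer", "ese") ~ "enhancer",
    c("s", "silencer", "ess") ~ "silencer",
    c("n", "neutral") ~ "neutral",
    .default = NA_character_
  )
  if (anyNA(out)) {
    abort_input("labels must be one of E/S/N (enhancer/silencer/neutral)")
  }
  out
}

#' Read a k-mer score table from TSV
#'
#' Expects a header `kmer  score  label` with one row per k-mer and labels
#' in {E, S, N}.
#'
#' @param path TSV path.
#' @return Tibble with columns `kmer`, `score`, `label`.
#' @export
read_score_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      kmer = readr::col_character(),
      score = readr::col_double(),
      label = readr::col_character()
    )
  )
  if (!all(c("kmer", "score", "label") %in% names(tbl))) {
    abort_input("score TSV must have header: kmer score label")
  }
  tbl
}

#' Write a k-mer score table to TSV
#'
#' @param scores tibble with columns `kmer`, `score`, `label`.
#' @param path output TSV path.
#' @return `scores`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  readr::write_tsv(scores[c("kmer", "score", "label")], path)
  invisible(scores)
}
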