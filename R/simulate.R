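#' Simulate a k-mer enrichment score table
#'
#' Generates a full `4^k`-row score table emulating a hexamer
#' enrichment-score screen: `n_enh` k-mers are labelled enhancers with
#' positive scores, `n_sil` silencers with negative scores, and the rest
#' are neutral with score 0.  The defaults (`n_enh = 1182`,
#' `n_sil = 1090`) match the size of the published hexamer screen this
#' emulates.  K-mers listed in `boost_kmers` are forced to the extreme of
#' their type's score range, so they are guaranteed to fall inside the
#' top-R (enhancer) or bottom-R (silencer) region of the ranking for any
#' `R >=` the number of boosted k-mers of that type.
#'
#' @param seed integer seed; the table is fully reproducible from it.
#' @param k k-mer length (default 6).
#' @param n_enh,n_sil number of enhancer- and silencer-labelled k-mers.
#' @param boost_kmers optional data frame with columns `kmer` and `label`
#'   (`E`/`S`) naming k-mers to pin to the extremes, or a character vector
#'   (treated as enhancers).
#' @return Score tibble (`kmer`, `score`, `label`) suitable for
#'   [rank_kmers()] and [write_score_table()].
#' @export
gen_score_table <- function(seed, k = 6, n_enh = 1182, n_sil = 1090,
                            boost_kmers = NULL) {
  stopifnot(k >= 1, k <= 12)
  universe <- all_kmers(k)
  n <- length(universe)
  if (n_enh + n_sil > n) abort_param("n_enh + n_sil must be <= 4^k")
  boost <- normalise_boost(boost_kmers, k)

  withr::with_seed(as.integer(seed), {
    scores <- rep(0, n)
    labels <- rep("N", n)
    names(scores) <- names(labels) <- universe

    boost_e <- boost$kmer[boost$label == "E"]
    boost_s <- boost$kmer[boost$label == "S"]
    free <- setdiff(universe, boost$kmer)
    enh <- c(boost_e, sample(free, max(0, n_enh - length(boost_e))))
    free <- setdiff(free, enh)
    sil <- c(boost_s, sample(free, max(0, n_sil - length(boost_s))))

    # log-enrichment-like magnitudes; boosted k-mers pinned beyond the rest
    labels[enh] <- "E"
    labels[sil] <- "S"
    scores[enh] <- abs(stats::rnorm(length(enh), mean = 1, sd = 0.5))
    scores[sil] <- -abs(stats::rnorm(length(sil), mean = 1, sd = 0.5))
    if (length(boost_e)) scores[boost_e] <- max(scores) + seq_along(boost_e)
    if (length(boost_s)) scores[boost_s] <- min(scores) - seq_along(boost_s)

    tibble::tibble(kmer = universe, score = unname(scores), label = unname(labels))
  })
}

normalise_boost <- function(boost_kmers, k) {
  if (is.null(boost_kmers)) {
    return(tibble::tibble(kmer = character(0), label = character(0)))
  }
  if (is.character(boost_kmers)) {
    boost_kmers <- tibble::tibble(kmer = boost_kmers, label = "E")
  }
  stopifnot(all(c("kmer", "label") %in% names(boost_kmers)))
  out <- tibble::tibble(
    kmer = toupper(boost_kmers$kmer),
    label = toupper(substr(boost_kmers$label, 1, 1))
  )
  if (any(nchar(out$kmer) != k) || any(grepl("[^ACGT]", out$kmer))) {
    abort_input(sprintf("boost k-mers must be ACGT strings of length %d", k))
  }
  stopifnot(all(out$label %in% c("E", "S")))
  dplyr::distinct(out)
}

#' Simulate exon windows with planted co-occurring motifs
#'
#' Generates `n_exons` random sequences of `background_length` nt with
#' uniform base composition, then plants each motif set into
#' `co_occurrence_count` exons: every chosen exon receives one copy of
#' every motif of the set at non-overlapping random positions.  Placements
#' are rejection-sampled so that no exon outside a set's chosen exons
#' contains all of that set's motifs — the planting contract is exact and
#' directly verifiable by scanning.  With no motif sets the output is a
#' pure random negative control.
#'
#' @param n_exons number of exons.
#' @param background_length exon (window) length in nt (default 50).
#' @param motif_sets list of motif sets; each set is a data frame with
#'   columns `sequence` and `label` (`E`/`S`), or a character vector.
#' @param co_occurrence_count exons carrying each complete set (recycled
#'   across sets); must be `<= n_exons`.
#' @param seed integer seed; output is byte-reproducible from it.
#' @return Tibble with columns `exon_id` (`exon00001`, ...) and `sequence`.
#' @export
gen_exons <- function(n_exons, background_length = 50, motif_sets = list(),
                      co_occurrence_count = 0, seed = 1) {
  stopifnot(n_exons >= 1, background_length >= 1)
  motif_sets <- lapply(motif_sets, function(s) {
    if (is.character(s)) s <- tibble::tibble(sequence = s, label = "E")
    stopifnot(all(c("sequence", "label") %in% names(s)))
    s$sequence <- toupper(s$sequence)
    if (any(grepl("[^ACGT]", s$sequence))) {
      abort_input("planted motifs must use {A,C,G,T}")
    }
    s
  })
  counts <- rep_len(as.integer(co_occurrence_count), length(motif_sets))
  if (any(counts > n_exons)) {
    abort_param("co_occurrence_count must be <= n_exons")
  }
  for (i in seq_along(motif_sets)) {
    if (sum(nchar(motif_sets[[i]]$sequence)) > background_length) {
      rlang::abort(
        "motifs cannot be placed without overlap in background_length",
        class = "sremine_generation_error"
      )
    }
  }

  withr::with_seed(as.integer(seed), {
    seqs <- random_dna(n_exons, background_length)
    carriers <- vector("list", length(motif_sets))
    pool <- seq_len(n_exons)
    for (i in seq_along(motif_sets)) {
      chosen <- sort(sample(pool, counts[i]))
      pool <- setdiff(pool, chosen)  # sets planted in disjoint exons
      carriers[[i]] <- chosen
      for (j in chosen) {
        seqs[j] <- plant_motifs(
          seqs[j], motif_sets[[i]]$sequence, background_length
        )
      }
    }
    # enforce the exact-count contract: resample any non-carrier exon that
    # happens to contain a complete motif set by chance
    for (i in seq_along(motif_sets)) {
      motifs <- motif_sets[[i]]$sequence
      others <- setdiff(seq_len(n_exons), carriers[[i]])
      for (j in others) {
        tries <- 0
        while (contains_all(seqs[j], motifs) && tries < 1000) {
          seqs[j] <- random_dna(1, background_length)
          tries <- tries + 1
        }
        if (contains_all(seqs[j], motifs)) {
          rlang::abort(
            "could not keep planted sets out of background exons",
            class = "sremine_generation_error"
          )
        }
      }
    }
    tibble::tibble(
      exon_id = sprintf("exon%05d", seq_len(n_exons)),
      sequence = seqs
    )
  })
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, "")
}

contains_all <- function(seq, motifs) {
  all(vapply(motifs, function(m) grepl(m, seq, fixed = TRUE), logical(1)))
}

#' Place motifs at non-overlapping random positions in one sequence
#' @noRd
plant_motifs <- function(seq, motifs, len) {
  for (attempt in seq_len(1000)) {
    s <- seq
    taken <- list()
    ok <- TRUE
    for (m in sample(motifs)) {
      lm <- nchar(m)
      open <- setdiff(seq_len(len - lm + 1L), unlist(lapply(taken, function(t) {
        seq(max(1L, t[1] - lm + 1L), t[2])
      })))
      open <- open[open >= 1]
      if (length(open) == 0) {
        ok <- FALSE
        break
      }
      pos <- if (length(open) == 1) open else sample(open, 1)
      substr(s, pos, pos + lm - 1L) <- m
      taken <- c(taken, list(c(pos, pos + lm - 1L)))
    }
    if (ok) return(s)
  }
  rlang::abort(
    "motifs cannot be placed without overlap",
    class = "sremine_generation_error"
  )
}

#' Write exon sequences to FASTA
#'
#' @param exons tibble with `exon_id` and `sequence` (e.g. [gen_exons()]).
#' @param path output FASTA path.
#' @return `exons`, invisibly.
#' @export
write_exon_fasta <- function(exons, path) {
  set <- Biostrings::DNAStringSet(stats::setNames(exons$sequence, exons$exon_id))
  Biostrings::writeXStringSet(set, path)
  invisible(exons)
}
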