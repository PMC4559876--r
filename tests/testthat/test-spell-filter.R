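spelled_tbl <- function(seqs, types) {
  tibble::tibble(
    sequence = seqs,
    element_type = types,
    source_mcs = seq_along(seqs)
  )
}

test_that("two overlapping 6-mers spell one 7-mer", {
  expect_identical(spell_mcs(c("GTCATC", "TCATCC")), "GTCATCC")
  expect_identical(nchar(spell_mcs(c("GTCATC", "TCATCC"))), 7L)
})

test_that("a single vertex spells itself; chains spell (m + k - 1)-mers", {
  expect_identical(spell_mcs("AGAGGA"), "AGAGGA")
  chain <- c("CCCGGA", "CCGGAG", "CGGAGC", "GGAGCC")
  expect_identical(spell_mcs(chain), "CCCGGAGCC")
  expect_identical(nchar(spell_mcs(chain)), 4L + 6L - 1L)
  # general chain law on random simple paths
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    m <- sample(2:6, 1)
    s <- paste(sample(c("A", "C", "G", "T"), m + k - 1, replace = TRUE),
               collapse = "")
    kmers <- unique(substring(s, 1:m, k:(m + k - 1)))
    got <- spell_mcs(kmers)
    expect_true(s %in% got) # the planted path is spelled
  }
})

test_that("branching subgraphs spell all maximal paths, subsumed ones dropped", {
  # AAC feeds both ACA and ACC: two maximal paths, no substring subsumption
  got <- spell_mcs(c("AAC", "ACA", "ACC"))
  expect_setequal(got, c("AACA", "AACC"))
  # self-loops never extend a path
  expect_identical(spell_mcs(c("AAA")), "AAA")
  expect_setequal(spell_mcs(c("AAA", "AAC")), "AAAC")
})

test_that("occurrence location finds every offset, overlapping included", {
  hits <- locate_occurrences("GGGAGG", "AAGGGAGGAC")
  expect_identical(hits$start, 3L)
  expect_identical(hits$end, 8L)
  none <- locate_occurrences("TTTTTT", "AAGGGAGGAC")
  expect_identical(nrow(none), 0L)
  # overlapping occurrences of a periodic pattern
  ov <- locate_occurrences("AAA", "AAAAA")
  expect_identical(ov$start, 1:3)
  # brute-force oracle on random inputs
  set.seed(31)
  for (rep in 1:20) {
    win <- paste(sample(c("A", "C", "G"), 40, replace = TRUE), collapse = "")
    pats <- vapply(1:8, function(i) {
      paste(sample(c("A", "C", "G"), sample(2:5, 1), replace = TRUE),
            collapse = "")
    }, "")
    got <- locate_occurrences(pats, win)
    for (i in seq_along(pats)) {
      len <- nchar(pats[i])
      starts <- which(vapply(
        seq_len(40 - len + 1),
        function(s) substr(win, s, s + len - 1) == pats[i],
        logical(1)
      ))
      expect_identical(got$start[got$seq_index == i], as.integer(starts))
    }
  }
})

test_that("four chained same-type occurrences merge to one 9-mer and drop the set", {
  chain <- c("CCCGGA", "CCGGAG", "CGGAGC", "GGAGCC")
  window <- paste0("TTTTT", "CCCGGAGCC", "TTTTT") # all four occur, overlapping
  layout <- sremine:::exon_layout(
    spelled_tbl(chain, rep("enhancer", 4)), window
  )
  expect_identical(nrow(layout), 1L)
  expect_identical(layout$sequence, "CCCGGAGCC")
  expect_identical(nchar(layout$sequence), 9L)
  # the merged span covers positions 6..14 of the window
  expect_identical(c(layout$start, layout$end), c(6L, 14L))
})

test_that("partial overlap yields the 8-mer paired with the separate element", {
  chain <- c("CCCGGA", "CCGGAG", "CGGAGC", "GGAGCC")
  window <- paste0("CCCGGAGC", "TTTTT", "GGAGCC") # first three chained only
  layout <- sremine:::exon_layout(
    spelled_tbl(chain, rep("enhancer", 4)), window
  )
  expect_setequal(layout$sequence, c("CCCGGAGC", "GGAGCC"))
  expect_identical(sort(nchar(layout$sequence)), c(6L, 8L))
})

test_that("merge span law holds and merging is transitive", {
  set.seed(41)
  for (rep in 1:25) {
    win <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    # random same-type elements taken from the window so they all occur
    n <- sample(2:5, 1)
    pieces <- lapply(seq_len(n), function(i) {
      s <- sample(1:50, 1)
      e <- min(60, s + sample(4:9, 1))
      c(s, e)
    })
    seqs <- vapply(pieces, function(p) substr(win, p[1], p[2]), "")
    layout <- sremine:::exon_layout(
      spelled_tbl(unique(seqs), rep("enhancer", length(unique(seqs)))), win
    )
    # every merged element's span equals [min start, max end] of the
    # occurrences it absorbed, and distinct elements never overlap
    if (nrow(layout) > 1) {
      spans <- layout[order(layout$start), ]
      expect_true(all(spans$start[-1] > spans$end[-nrow(spans)]))
    }
    expect_true(all(
      layout$sequence == substring(win, layout$start, layout$end)
    ))
  }
})

test_that("different-type overlaps are kept unmerged", {
  window <- "AAGGGAGGACTT" # GGGAGG (E) and GAGGAC (S) overlap by 3 nt
  layout <- sremine:::exon_layout(
    spelled_tbl(c("GGGAGG", "GAGGAC"), c("enhancer", "silencer")), window
  )
  expect_identical(nrow(layout), 2L)
  expect_setequal(layout$sequence, c("GGGAGG", "GAGGAC"))
})

test_that("merge_and_emit aggregates per-exon candidate sets at threshold theta", {
  # collection of two single-vertex MCSs, one enhancer + one silencer
  mcs <- tibble::tibble(
    mcs_id = 1:2,
    element_type = c("enhancer", "silencer"),
    kmers = list("GGGAGG", "CATCAT"),
    n_exons = c(4L, 4L),
    exons = list(sprintf("e%d", 1:4), sprintf("e%d", 1:4))
  )
  windows <- window_exons(c(
    e1 = "AAGGGAGGAACATCATAAAA",
    e2 = "GGGAGGTTTTCATCATTTTT",
    e3 = "TTGGGAGGTTTTTTCATCAT",
    e4 = "GGGAGGCATCATAAAAAAAA",
    e5 = "AAAAAAAAAAAAAAAAAAAA"
  ), W = 50)
  coll <- enumerate_collections(mcs, theta = 4, beta = 2)
  out <- merge_and_emit(coll[1, ], mcs, windows, theta = 4)
  expect_identical(nrow(out), 1L)
  expect_setequal(out$elements[[1]], c("GGGAGG", "CATCAT"))
  expect_identical(out$n_supporting_exons, 4L)
  expect_setequal(out$supporting_exons[[1]], sprintf("e%d", 1:4))
  # supporting exons always within the collection's shared exons
  expect_true(all(out$supporting_exons[[1]] %in% coll$shared_exons[[1]]))
  # raising theta beyond the support empties the result
  expect_identical(nrow(merge_and_emit(coll[1, ], mcs, windows, theta = 5)), 0L)
})

test_that("same-type collapse to one long element eliminates the set", {
  mcs <- tibble::tibble(
    mcs_id = 1:2,
    element_type = c("enhancer", "enhancer"),
    kmers = list("CCCGGA", "GGAGCC"),
    n_exons = c(2L, 2L),
    exons = list(c("e1", "e2"), c("e1", "e2"))
  )
  windows <- window_exons(c(
    e1 = paste0("TT", "CCCGGAGCC", "TTTTTTTTT"), # overlapping -> one element
    e2 = paste0("CCCGGA", "TTTT", "GGAGCC", "TT") # separate -> a true pair
  ), W = 50)
  coll <- enumerate_collections(mcs, theta = 2, beta = 2)
  merged <- merge_and_emit(coll[1, ], mcs, windows, theta = 1)
  # e1 collapses to the single 9-mer (set dropped); e2 emits the pair
  expect_identical(nrow(merged), 1L)
  expect_setequal(merged$elements[[1]], c("CCCGGA", "GGAGCC"))
  expect_identical(merged$supporting_exons[[1]], "e2")

  # with merging off, e1's overlapping pair survives as two elements
  unmerged <- merge_and_emit(coll[1, ], mcs, windows, theta = 1,
                             merge_same_type = FALSE)
  expect_identical(nrow(unmerged), 1L)
  expect_setequal(unmerged$elements[[1]], c("CCCGGA", "GGAGCC"))
  expect_identical(unmerged$n_supporting_exons, 2L)
})

test_that("with merging off and no overlaps, sets equal the spelled sequences", {
  mcs <- tibble::tibble(
    mcs_id = 1:2,
    element_type = c("enhancer", "silencer"),
    kmers = list("AAACCC", "GGGTTT"),
    n_exons = c(2L, 2L),
    exons = list(c("e1", "e2"), c("e1", "e2"))
  )
  windows <- window_exons(c(
    e1 = "AAACCCTTTTGGGTTTTTTT",
    e2 = "TTGGGTTTTTTTTAAACCCT"
  ), W = 50)
  coll <- enumerate_collections(mcs, theta = 2, beta = 2)
  for (flag in c(TRUE, FALSE)) {
    out <- merge_and_emit(coll[1, ], mcs, windows, theta = 2,
                          merge_same_type = flag)
    expect_identical(nrow(out), 1L)
    expect_setequal(out$elements[[1]], c("AAACCC", "GGGTTT"))
  }
})

test_that("SRE-set table writes the documented schema", {
  sets <- tibble::tibble(
    elements = list(c("GGGAGG", "GAGGAC")),
    element_types = list(c("enhancer", "silencer")),
    n_supporting_exons = 5L,
    supporting_exons = list(sprintf("e%d", 1:5)),
    source_collection = 3L
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sre_sets(sets, path)
  tbl <- readr::read_tsv(path, col_types = readr::cols())
  expect_identical(names(tbl),
                   c("sre_set", "element_types", "n_exons", "source_collection"))
  expect_identical(tbl$sre_set, "GGGAGG,GAGGAC")
  expect_equal(tbl$n_exons, 5)
})
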