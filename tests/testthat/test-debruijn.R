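test_that("de Bruijn graph has 4^k vertices and 4^(k+1) edges, by enumeration", {
  for (k in 1:8) {
    g <- build_debruijn(k)
    expect_length(g$vertices, 4^k)
    expect_identical(g$n_edges, 4^(k + 1))
  }
  # enumerate the edges explicitly for small k and count
  for (k in 1:4) {
    g <- build_debruijn(k)
    edges <- sremine:::induced_edges(g$vertices, k)
    expect_identical(nrow(edges), as.integer(4^(k + 1)))
    # every enumerated pair satisfies the suffix/prefix overlap rule
    expect_true(all(
      substr(edges$from, 2, k) == substr(edges$to, 1, k - 1)
    ))
  }
})

test_that("k = 2 adjacency matches the overlap rule on named examples", {
  g <- build_debruijn(2)
  edges <- sremine:::induced_edges(g$vertices, 2)
  keys <- paste(edges$from, edges$to)
  expect_true("AC CG" %in% keys)
  expect_false("AC GG" %in% keys)
  expect_true("AA AA" %in% keys) # homopolymer self-loop
})

test_that("k out of range is a parameter error", {
  expect_error(build_debruijn(0), class = "sremine_parameter_error")
  expect_error(build_debruijn(13), class = "sremine_parameter_error")
  expect_error(build_debruijn(2.5), class = "sremine_parameter_error")
})

test_that("ranking is descending, complete, and deterministic under ties", {
  k <- 3
  universe <- sremine:::all_kmers(k)
  set.seed(42)
  scores <- tibble::tibble(
    kmer = sample(universe),
    score = round(stats::rnorm(length(universe)), 1), # forces ties
    label = sample(c("E", "S", "N"), length(universe), replace = TRUE)
  )
  r1 <- rank_kmers(scores, k)
  r2 <- rank_kmers(scores[sample(nrow(scores)), ], k)
  expect_identical(r1, r2) # input order and tie handling cannot matter
  expect_identical(r1$rank, seq_len(4^k))
  expect_true(all(diff(r1$score) <= 0))
  # ties broken lexicographically
  tied <- r1[r1$score == r1$score[which.max(duplicated(r1$score))], ]
  expect_identical(tied$kmer, sort(tied$kmer))
  # neutral k-mers carry score zero regardless of the supplied value
  neutral_nonzero <- tibble::tibble(kmer = universe, score = 5, label = "N")
  rn <- rank_kmers(neutral_nonzero, k)
  expect_true(all(rn$score == 0))
})

test_that("rank_kmers rejects malformed tables and fills missing as neutral", {
  expect_error(
    rank_kmers(tibble::tibble(kmer = c("AA", "AA"), score = 1, label = "E"), 2),
    class = "sremine_input_error"
  )
  expect_error(
    rank_kmers(tibble::tibble(kmer = "AN", score = 1, label = "E"), 2),
    class = "sremine_input_error"
  )
  partial <- tibble::tibble(kmer = c("AA", "TT"), score = c(2, -2),
                            label = c("E", "S"))
  r <- rank_kmers(partial, 2)
  expect_identical(nrow(r), 16L)
  expect_identical(r$kmer[r$rank == 1], "AA")
  expect_identical(r$kmer[r$rank == 16], "TT")
  expect_true(all(r$label[!r$kmer %in% c("AA", "TT")] == "neutral"))
})

test_that("SRE graph induction is exact, idempotent, and respects R", {
  k <- 3
  g <- build_debruijn(k)
  set.seed(7)
  scores <- tibble::tibble(
    kmer = g$vertices,
    score = stats::rnorm(4^k),
    label = "N"
  )
  ranked <- rank_kmers(scores, k)
  # neutral scores get zeroed, so rescore as enhancer/silencer mix
  scores$label <- rep(c("E", "S"), length.out = 4^k)
  ranked <- rank_kmers(scores, k)

  sre <- build_sre_graph(g, ranked, R = 30, side = "top")
  expect_length(sre$vertices, 30)
  expect_setequal(sre$vertices, ranked$kmer[ranked$rank <= 30])
  # brute-force edge verification: exactly the de Bruijn edges inside U
  u <- sre$vertices
  expected <- expand.grid(from = u, to = u, stringsAsFactors = FALSE)
  expected <- expected[substr(expected$from, 2, k) ==
                         substr(expected$to, 1, k - 1), ]
  expect_setequal(
    paste(sre$edges$from, sre$edges$to),
    paste(expected$from, expected$to)
  )
  # idempotence: re-inducing on the same vertex set changes nothing
  expect_identical(sremine:::induced_edges(u, k), sre$edges)

  # full induction at R = 4^k
  full <- build_sre_graph(g, ranked, R = 4^k, side = "top")
  expect_setequal(full$vertices, g$vertices)
  expect_identical(nrow(full$edges), as.integer(4^(k + 1)))

  # R = 1: singleton, no edges unless homopolymer
  ranked_hp <- rank_kmers(
    tibble::tibble(kmer = g$vertices,
                   score = ifelse(g$vertices == "AAA", 10, 0),
                   label = ifelse(g$vertices == "AAA", "E", "N")),
    k
  )
  single <- build_sre_graph(g, ranked_hp, R = 1, side = "top")
  expect_identical(single$vertices, "AAA")
  expect_identical(nrow(single$edges), 1L) # the self-loop

  # top/bottom disjoint when 2R <= 4^k and scores distinct
  top <- build_sre_graph(g, ranked, R = 30, side = "top")
  bottom <- build_sre_graph(g, ranked, R = 30, side = "bottom")
  expect_length(intersect(top$vertices, bottom$vertices), 0)

  expect_error(build_sre_graph(g, ranked, R = 0), class = "sremine_parameter_error")
  expect_error(build_sre_graph(g, ranked, R = 4^k + 1),
               class = "sremine_parameter_error")
})

test_that("undirected adjacency agrees with igraph on random vertex sets", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (rep in 1:20) {
    vs <- random_vertex_set(sample(4:10, 1), k = 3)
    adj <- sremine:::undirected_adjacency(vs, 3)
    edges <- sremine:::induced_edges(vs, 3)
    edges <- edges[edges$from != edges$to, ]
    ig <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = vs)
    )
    for (i in seq_along(vs)) {
      expect_setequal(
        vs[adj[[i]]],
        igraph::neighbors(ig, vs[i]) |> names() |> unique()
      )
    }
  }
})
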