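# Independent brute-force oracles used to validate the mining algorithms.
# They enumerate subsets exhaustively and never share code with the
# implementation under test.

# Undirected adjacency matrix over a k-mer vertex set, self-loops dropped,
# computed from first principles (suffix/prefix overlap of length k-1).
oracle_adjacency <- function(vertices) {
  n <- length(vertices)
  k <- nchar(vertices[1])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        fwd <- substr(vertices[i], 2, k) == substr(vertices[j], 1, k - 1)
        bwd <- substr(vertices[j], 2, k) == substr(vertices[i], 1, k - 1)
        adj[i, j] <- fwd || bwd
      }
    }
  }
  adj
}

oracle_connected <- function(members, adj) {
  if (length(members) <= 1) return(TRUE)
  reached <- members[1]
  frontier <- members[1]
  while (length(frontier)) {
    nxt <- setdiff(members[colSums(adj[frontier, members, drop = FALSE]) > 0],
                   reached)
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  length(reached) == length(members)
}

# All locally-maximal alpha-cohesive connected induced subgraphs, by full
# enumeration of the 2^n vertex subsets.  Returns a sorted character vector
# of canonical "kmer kmer ..." keys.
oracle_mcs <- function(vertices, supports, alpha) {
  n <- length(vertices)
  adj <- oracle_adjacency(vertices)
  tset <- function(members) Reduce(intersect, supports[members])
  keys <- character(0)
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!oracle_connected(members, adj)) next
    if (length(tset(members)) < alpha) next
    nbrs <- setdiff(which(colSums(adj[members, , drop = FALSE]) > 0), members)
    maximal <- all(vapply(
      nbrs, function(u) length(tset(c(members, u))) < alpha, logical(1)
    ))
    if (maximal) {
      keys <- c(keys, paste(sort(vertices[members]), collapse = " "))
    }
  }
  sort(unique(keys))
}

# All subsets M of ids with |M| >= beta and |intersection of exon sets| >=
# theta, by full enumeration.  Returns sorted canonical "id id ..." keys.
oracle_collections <- function(ids, exon_sets, theta, beta) {
  n <- length(ids)
  keys <- character(0)
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < beta) next
    shared <- Reduce(intersect, exon_sets[members])
    if (length(shared) >= theta) {
      keys <- c(keys, paste(sort(ids[members]), collapse = " "))
    }
  }
  sort(keys)
}

# Random connected-ish SRE-like vertex set: sample k-mers, biased towards
# chains so induced graphs are not mostly edgeless.
random_vertex_set <- function(n, k = 4) {
  start <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                 collapse = "")
  vs <- start
  while (length(vs) < n) {
    if (stats::runif(1) < 0.7) {
      prev <- sample(vs, 1)
      nxt <- paste0(substr(prev, 2, k),
                    sample(c("A", "C", "G", "T"), 1))
      vs <- union(vs, nxt)
    } else {
      vs <- union(vs, paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                            collapse = ""))
    }
  }
  sort(vs[seq_len(n)])
}

# Random sparse supports over an integer exon universe.
random_supports <- function(vertices, n_exons = 12, density = 0.5) {
  supports <- lapply(vertices, function(v) {
    sort(sample(n_exons, stats::rbinom(1, n_exons, density)))
  })
  names(supports) <- vertices
  supports
}

# Wrap vertex set + supports into the package's profile structure so
# mine_mcs can consume a hand-built instance.
as_profile <- function(vertices, supports, n_exons) {
  structure(
    list(
      kmers = vertices,
      exons = sprintf("x%03d", seq_len(n_exons)),
      k = nchar(vertices[1]),
      support = supports
    ),
    class = "sre_profile"
  )
}

as_sre_graph <- function(vertices, element_type = "enhancer") {
  k <- nchar(vertices[1])
  structure(
    list(
      element_type = element_type,
      k = k,
      vertices = sort(vertices),
      edges = NULL,
      ranked = NULL
    ),
    class = "sre_graph"
  )
}

mcs_keys <- function(mcs_tbl) {
  sort(vapply(mcs_tbl$kmers, function(ks) paste(sort(ks), collapse = " "), ""))
}

collection_keys <- function(col_tbl) {
  sort(vapply(col_tbl$mcs_ids, function(m) paste(sort(m), collapse = " "), ""))
}
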