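#' Pipeline run configuration
#'
#' Bundles the tunable parameters of a full mining run.  Defaults follow
#' the published genome-scale analysis this package implements: the top
#' and bottom `R = 400` ranked hexamers form the enhancer and silencer
#' graphs, a candidate element must reside in `alpha = 1000` exons, a
#' collection of `beta = 2` or more elements must share `theta = 100`
#' exons, and occurrence is evaluated on the first 50 nt of each exon.
#' `alpha` and `theta` are independent thresholds.
#'
#' @param k k-mer length (default 6).
#' @param R vertices per SRE graph (default 400); must be `<= 4^k`.
#' @param alpha minimum exon support of a cohesive subgraph (default 1000).
#' @param theta minimum shared-exon count of a collection (default 100).
#' @param beta minimum collection size (default 2).
#' @param window analysis window length in nt (default 50).
#' @param window_end `"first"` or `"last"` window of the exon.
#' @param merge_same_type merge overlapping same-type occurrences in the
#'   filtering stage (default `TRUE`; `FALSE` reports the unmerged
#'   reading).
#' @return A `sremine_config` list.
#' @export
sremine_config <- function(k = 6, R = 400, alpha = 1000, theta = 100,
                           beta = 2, window = 50,
                           window_end = c("first", "last"),
                           merge_same_type = TRUE) {
  window_end <- match.arg(window_end)
  for (p in list(k = k, R = R, alpha = alpha, theta = theta, beta = beta,
                 window = window)) {
    if (!is.numeric(p) || length(p) != 1 || p < 1) {
      abort_param("all numeric run parameters must be single integers >= 1")
    }
  }
  if (R > 4^k) abort_param("R must be <= 4^k")
  structure(
    list(
      k = as.integer(k), R = as.integer(R), alpha = as.integer(alpha),
      theta = as.integer(theta), beta = as.integer(beta),
      window = as.integer(window), window_end = window_end,
      merge_same_type = isTRUE(merge_same_type)
    ),
    class = "sremine_config"
  )
}

#' Run the full two-level mining pipeline
#'
#' Scores and exons in; combinatorial SRE sets out.  Stages: rank k-mers;
#' induce the enhancer (top-R) and silencer (bottom-R) graphs; window the
#' exons once (both profiles share the same exon universe, so shared-exon
#' intersections across element types are well-defined); build the two
#' occurrence profiles; mine maximal alpha-cohesive subgraphs per type;
#' combine both MCS tables into one ID space; enumerate MCS collections;
#' filter each collection at sequence level and emit the SRE sets.
#'
#' @param scores score table (tibble with `kmer`, `score`, `label`) or a
#'   TSV path readable by [read_score_table()].
#' @param exons exon sequences: a tibble with `exon_id` and `sequence`, a
#'   named character vector, or a FASTA path.
#' @param config a [sremine_config()].
#' @param out_dir optional directory; when given, every stage artifact is
#'   written there as TSV/FASTA-side files plus a `run_log.tsv`.
#' @return An object of class `sremine_run`: list with `config`, `windows`,
#'   `graphs` (enhancer/silencer `sre_graph`s), `mcs` (combined MCS
#'   tibble), `collections`, `sre_sets` and `counts` (stage-count tibble).
#' @export
run_pipeline <- function(scores, exons, config = sremine_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "sremine_config"))
  if (is.character(scores) && length(scores) == 1) {
    scores <- read_score_table(scores)
  }
  if (is.character(exons) && length(exons) == 1 && file.exists(exons)) {
    exons <- read_exon_fasta(exons)
  }

  debruijn <- build_debruijn(config$k)
  ranked <- rank_kmers(scores, config$k)
  graphs <- list(
    enhancer = build_sre_graph(debruijn, ranked, config$R, side = "top"),
    silencer = build_sre_graph(debruijn, ranked, config$R, side = "bottom")
  )
  windows <- window_exons(exons, W = config$window, end = config$window_end)
  profiles <- lapply(graphs, build_profile, windows = windows)
  mcs_by_type <- lapply(names(graphs), function(ty) {
    mine_mcs(graphs[[ty]], profiles[[ty]], config$alpha)
  })
  mcs <- combine_mcs(mcs_by_type[[1]], mcs_by_type[[2]])
  collections <- enumerate_collections(mcs, config$theta, config$beta)
  sre_sets <- filter_collections(
    collections, mcs, windows, config$theta,
    merge_same_type = config$merge_same_type
  )

  run <- structure(
    list(
      config = config,
      windows = windows,
      graphs = graphs,
      mcs = mcs,
      collections = collections,
      sre_sets = sre_sets,
      counts = stage_counts(mcs, collections, sre_sets)
    ),
    class = "sremine_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

stage_counts <- function(mcs, collections, sre_sets) {
  tibble::tibble(
    stage = c("mcs_enhancer", "mcs_silencer", "mcs_total",
              "collections", "sre_sets"),
    count = c(
      sum(mcs$element_type == "enhancer"),
      sum(mcs$element_type == "silencer"),
      nrow(mcs),
      nrow(collections),
      nrow(sre_sets)
    )
  )
}

#' Write all stage artifacts of a run
#'
#' @param run a `sremine_run`.
#' @param out_dir output directory (created if needed).
#' @return `run`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "sremine_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_mcs_table(run$mcs, p("mcs_table.tsv"))
  readr::write_tsv(collection_report(run$collections, run$mcs),
                   p("collections.tsv"))
  write_sre_sets(run$sre_sets, p("sre_sets.tsv"))
  readr::write_tsv(run$counts, p("summary.tsv"))
  cfg <- run$config
  log <- tibble::tibble(
    key = c("package_version", names(cfg)),
    value = c(
      as.character(utils::packageVersion("sremine")),
      vapply(cfg, as.character, "")
    )
  )
  readr::write_tsv(log, p("run_log.tsv"))
  invisible(run)
}

#' Per-stage counts of a run (or of saved run artifacts)
#'
#' @param run a `sremine_run`, or a directory written by [write_run()].
#' @return Tibble with columns `stage` and `count`.
#' @export
summarize_run <- function(run) {
  if (is.character(run)) {
    mcs <- read_mcs_table(file.path(run, "mcs_table.tsv"))
    collections <- read_collection_table(file.path(run, "collections.tsv"))
    sets <- readr::read_tsv(
      file.path(run, "sre_sets.tsv"),
      col_types = readr::cols()
    )
    return(stage_counts(mcs, collections, tibble::as_tibble(sets)))
  }
  stopifnot(inherits(run, "sremine_run"))
  run$counts
}

#' @export
print.sremine_run <- function(x, ...) {
  cat("<sremine_run>\n")
  cat(sprintf(
    "  k=%d R=%d alpha=%d theta=%d beta=%d window=%d(%s) merge=%s\n",
    x$config$k, x$config$R, x$config$alpha, x$config$theta, x$config$beta,
    x$config$window, x$config$window_end, x$config$merge_same_type
  ))
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-14s %d\n", x$counts$stage[i], x$counts$count[i]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the final SRE sets of a run
#'
#' One row per emitted combinatorial SRE set, with comma-joined element
#' sequences and types — the same schema as the exported
#' `sre_sets.tsv`.
#'
#' @param x a `sremine_run`.
#' @param ... unused.
#' @return Tibble `sre_set`, `element_types`, `n_exons`,
#'   `source_collection`.
#' @method tidy sremine_run
#' @export
tidy.sremine_run <- function(x, ...) {
  tibble::tibble(
    sre_set = vapply(x$sre_sets$elements, join_set, ""),
    element_types = vapply(x$sre_sets$element_types, join_set, ""),
    n_exons = x$sre_sets$n_supporting_exons,
    source_collection = x$sre_sets$source_collection
  )
}

#' One-row summary of a run
#'
#' @param x a `sremine_run`.
#' @param ... unused.
#' @return One-row tibble with the thresholds and per-stage counts.
#' @method glance sremine_run
#' @export
glance.sremine_run <- function(x, ...) {
  counts <- stats::setNames(x$counts$count, x$counts$stage)
  tibble::tibble(
    n_exons = length(x$windows$exon_id),
    alpha = x$config$alpha,
    theta = x$config$theta,
    beta = x$config$beta,
    n_mcs = counts[["mcs_total"]],
    n_collections = counts[["collections"]],
    n_sre_sets = counts[["sre_sets"]]
  )
}
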