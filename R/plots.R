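#' Plot MCS size against exon support
#'
#' Each point is one maximal cohesive subgraph; the x axis is the number
#' of k-mers it spans (its potential element length is size + k - 1) and
#' the y axis its exon support.
#'
#' @param mcs MCS tibble from [mine_mcs()] or [combine_mcs()].
#' @return A ggplot object.
#' @export
plot_mcs_support <- function(mcs) {
  df <- tibble::tibble(
    size = lengths(mcs$kmers),
    n_exons = mcs$n_exons,
    element_type = mcs$element_type
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$size, y = .data$n_exons, colour = .data$element_type
  )) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::labs(
      x = "k-mers in subgraph",
      y = "supporting exons",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot stage counts across an alpha sweep
#'
#' Runs the pipeline at several `alpha` values on fixed inputs and plots
#' the number of MCSs and of MCS collections against `alpha`.  The MCS
#' count is non-increasing in `alpha` (raising the support floor can only
#' remove candidate elements).
#'
#' @param scores,exons inputs as in [run_pipeline()].
#' @param alphas numeric vector of `alpha` values to sweep.
#' @param config base [sremine_config()]; its `alpha` is overridden.
#' @return A ggplot object; the sweep table is attached as attribute
#'   `"sweep"`.
#' @export
plot_alpha_sweep <- function(scores, exons, alphas, config = sremine_config()) {
  sweep <- purrr::map_dfr(alphas, function(a) {
    cfg <- sremine_config(
      k = config$k, R = config$R, alpha = a, theta = config$theta,
      beta = config$beta, window = config$window,
      window_end = config$window_end,
      merge_same_type = config$merge_same_type
    )
    glance(run_pipeline(scores, exons, cfg))
  })
  long <- tidyr::pivot_longer(
    sweep[c("alpha", "n_mcs", "n_collections")],
    cols = c("n_mcs", "n_collections"),
    names_to = "stage", values_to = "count"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$alpha, y = .data$count, colour = .data$stage
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "count", colour = NULL) +
    ggplot2::theme_minimal()
  attr(p, "sweep") <- sweep
  p
}
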