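#' Plot allele-frequency trajectories
#'
#' One line per SNP and replicate over generations, faceted by replicate
#' (and phase when present), coloured by truth label if a `selected` column
#' is supplied or joinable.
#'
#' @param trajectories A tibble with columns `pos` (or `locus`),
#'   `replicate` (optional), `generation`, `p`, e.g. the `trajectories`
#'   element of [simulate_experiment()].
#' @param truth Optional per-variant tibble with `pos` and `selected` for
#'   colouring.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, truth = NULL) {
  df <- trajectories
  if (!"pos" %in% names(df) && "locus" %in% names(df)) {
    df <- dplyr::rename(df, pos = "locus")
  }
  if (!"replicate" %in% names(df)) df$replicate <- "all"
  if (!is.null(truth)) {
    df <- dplyr::left_join(df, dplyr::select(truth, "pos", "selected"),
                           by = "pos")
  } else if (!"selected" %in% names(df)) {
    df$selected <- FALSE
  }
  g <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$generation, y = .data$p,
    group = interaction(.data$pos, .data$replicate),
    colour = .data$selected
  )) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "allele frequency") +
    ggplot2::theme_minimal()
  facets <- intersect(c("phase", "replicate"), names(df))
  if (length(facets) > 0) {
    g <- g + ggplot2::facet_wrap(facets, scales = "free_x")
  }
  g
}

#' Manhattan-style plot of a genome scan
#'
#' Negative log10 weighted p values along positions, one panel per test,
#' with the declared candidate thresholds as horizontal lines.
#'
#' @param scan An `er_scan` from [run_primary()].
#' @param alpha FDR level whose threshold is drawn (default 0.01).
#' @return A ggplot object.
#' @export
plot_scan <- function(scan, alpha = 0.01) {
  stopifnot(inherits(scan, "er_scan"))
  df <- scan$results
  thr <- purrr::imap_dfr(scan$curves, function(cv, nm) {
    d <- declare_candidates(cv, alpha)
    tibble(test_label = nm, threshold = d$threshold)
  })
  df$test_label <- paste0(df$test, "_", df$replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos,
                                   y = -log10(.data$p_weighted))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_hline(data = thr[!is.na(thr$threshold), ],
                        ggplot2::aes(yintercept = -log10(.data$threshold)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap("test_label", ncol = 1) +
    ggplot2::labs(x = "position", y = expression(-log[10](p[weighted]))) +
    ggplot2::theme_minimal()
}
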