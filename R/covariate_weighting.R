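# all compositions of `total` units into k non-negative parts
.compositions <- function(total, k) {
  if (k == 1) return(matrix(total, 1, 1))
  do.call(rbind, lapply(0:total, function(i) {
    cbind(i, .compositions(total - i, k - 1), deparse.level = 0)
  }))
}

.all_ones_wf <- function(n, alpha, reason = NULL) {
  structure(
    list(bin_edges = numeric(0), weights = 1, fold_weights = NULL,
         folds = rep(1L, n), bins = rep(1L, n), occupancy = n,
         n_bins = 1L, n_folds = 1L, alpha = alpha, step = NA_real_,
         fallback = !is.null(reason)),
    class = "coverage_weights"
  )
}

#' Learn covariate-based p-value weights
#'
#' Independent-hypothesis-weighting-style procedure: the covariate (here,
#' mean coverage per SNP) is split into `n_bins` equal-occupancy groups and
#' non-negative per-group weights are chosen on a simplex grid under the
#' budget constraint (occupancy-weighted mean weight = 1) to maximise the
#' number of weighted p values at or below `alpha`. Weights are cross-fitted:
#' each fold's items receive weights learned on the other folds, which keeps
#' the procedure from inflating significance on uninformative covariates.
#'
#' With fewer than `10 * n_bins` observations the procedure falls back to
#' all-ones weights with a warning. `n_bins = 1` always returns all-ones.
#'
#' @param p Raw p values.
#' @param covariate Per-test covariate (independent of p under the null),
#'   same length as `p`.
#' @param alpha Working significance level the weight search optimises for.
#' @param n_bins Number of covariate groups G (default 5).
#' @param n_folds Number of cross-fit folds F (default 5; `n_folds = 1` is
#'   only allowed with `n_bins = 1`).
#' @param step Grid resolution on each weight (default 0.25).
#' @return An object of class `coverage_weights`.
#' @seealso [apply_weights()], [weight_pvalues()]
#' @export
learn_weights <- function(p, covariate, alpha = 0.05, n_bins = 5,
                          n_folds = 5, step = 0.25) {
  n <- length(p)
  if (length(covariate) != n) abort("`p` and `covariate` lengths differ")
  if (n_bins < 1) abort("`n_bins` must be >= 1")
  if (n_folds < 2 && n_bins > 1) {
    abort("`n_folds` must be >= 2 when learning (n_bins > 1)")
  }
  if (n_bins == 1) return(.all_ones_wf(n, alpha))
  if (n < 10 * n_bins) {
    warn(sprintf("fewer than %d items: falling back to all-ones weights",
                 10 * n_bins))
    return(.all_ones_wf(n, alpha, reason = "too_few_items"))
  }
  G <- as.integer(n_bins)
  # equal-occupancy bins by covariate rank; edges kept for new data
  rk <- rank(covariate, ties.method = "first")
  bins <- ceiling(rk * G / n)
  sc <- sort(covariate)
  bin_edges <- sc[floor(n * seq_len(G - 1) / G)]
  occupancy <- tabulate(bins, nbins = G)
  folds <- sample(rep_len(seq_len(n_folds), n))
  units <- as.integer(round(G / step))
  Wu <- .compositions(units, G)       # unit grid, each row sums to G/step
  W <- Wu * step
  levels <- (0:units) * step
  dist1 <- rowSums(abs(W - 1))
  fold_weights <- matrix(NA_real_, n_folds, G)
  for (f in seq_len(n_folds)) {
    train <- folds != f
    obj <- numeric(nrow(W))
    for (g in seq_len(G)) {
      pg <- sort(p[train & bins == g])
      counts_g <- findInterval(alpha * levels, pg)
      obj <- obj + counts_g[Wu[, g] + 1L]
    }
    best <- which(obj == max(obj))
    best <- best[which.min(dist1[best])]
    w <- W[best, ]
    # exact budget w.r.t. full-data occupancy
    fold_weights[f, ] <- w * n / sum(occupancy * w)
  }
  consensus <- colMeans(fold_weights)
  consensus <- consensus * n / sum(occupancy * consensus)
  structure(
    list(bin_edges = bin_edges, weights = consensus,
         fold_weights = fold_weights, folds = folds, bins = bins,
         occupancy = occupancy, n_bins = G, n_folds = as.integer(n_folds),
         alpha = alpha, step = step, fallback = FALSE),
    class = "coverage_weights"
  )
}

#' Apply learned covariate weights to p values
#'
#' Computes `p_weighted = min(1, p / w)` where `w` is the weight of the
#' item's covariate bin. Items in a zero-weight group get `p_weighted = 1`.
#' Covariates outside the learned range are clamped to the nearest bin (the
#' number of clamped items is attached as the `"n_clamped"` attribute).
#'
#' @param p Raw p values.
#' @param wf A `coverage_weights` object from [learn_weights()].
#' @param covariate Covariate values for `p`.
#' @param folds Optional per-item fold ids: when supplied (as for the
#'   learning data itself), each item gets the weights of the fold that
#'   excluded it (cross-fitting); otherwise the consensus weights are used.
#' @return Numeric vector of weighted p values.
#' @export
apply_weights <- function(p, wf, covariate, folds = NULL) {
  stopifnot(inherits(wf, "coverage_weights"))
  if (length(covariate) != length(p)) {
    abort("`p` and `covariate` lengths differ")
  }
  if (wf$n_bins == 1) {
    out <- pmin(1, p)
    attr(out, "n_clamped") <- 0L
    return(out)
  }
  bins <- findInterval(covariate, wf$bin_edges) + 1L
  n_clamped <- sum(covariate < min(wf$bin_edges) |
                     covariate > max(wf$bin_edges))
  if (!is.null(folds)) {
    if (length(folds) != length(p)) abort("`folds` length differs from `p`")
    w <- wf$fold_weights[cbind(folds, bins)]
  } else {
    w <- wf$weights[bins]
  }
  out <- ifelse(w <= 0, 1, pmin(1, p / w))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Learn and cross-fit weights in one step
#'
#' Convenience wrapper: learns weights on (`p`, `covariate`) and returns the
#' cross-fitted weighted p values for the same items (each item weighted by
#' the fold that excluded it).
#'
#' @inheritParams learn_weights
#' @return A tibble with columns `p_raw`, `covariate`, `bin`, `fold`,
#'   `weight`, `p_weighted`; the `coverage_weights` object is attached as
#'   the `"weights"` attribute.
#' @export
weight_pvalues <- function(p, covariate, alpha = 0.05, n_bins = 5,
                           n_folds = 5, step = 0.25) {
  wf <- learn_weights(p, covariate, alpha, n_bins, n_folds, step)
  pw <- apply_weights(p, wf, covariate,
                      folds = if (is.null(wf$fold_weights)) NULL
                              else wf$folds)
  w <- if (is.null(wf$fold_weights)) rep(1, length(p))
       else wf$fold_weights[cbind(wf$folds, wf$bins)]
  out <- tibble(
    p_raw = p, covariate = covariate, bin = wf$bins, fold = wf$folds,
    weight = w, p_weighted = as.numeric(pw)
  )
  attr(out, "weights") <- wf
  out
}

#' @export
print.coverage_weights <- function(x, ...) {
  cat("<coverage_weights>\n")
  if (x$fallback) cat("  fallback: all-ones weights\n")
  cat(sprintf("  %d bin(s), %d fold(s), alpha = %g\n",
              x$n_bins, x$n_folds, x$alpha))
  cat("  consensus weights:", paste(signif(x$weights, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.coverage_weights <- function(x, ...) {
  edges <- c(-Inf, x$bin_edges, Inf)
  tibble(
    bin = seq_len(x$n_bins),
    covariate_lower = edges[seq_len(x$n_bins)],
    covariate_upper = edges[seq_len(x$n_bins) + 1],
    occupancy = x$occupancy,
    weight = x$weights
  )
}

#' @export
glance.coverage_weights <- function(x, ...) {
  tibble(
    n_bins = x$n_bins, n_folds = x$n_folds, alpha = x$alpha,
    budget = sum(x$occupancy * x$weights) / sum(x$occupancy),
    fallback = x$fallback
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.coverage_weights <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$bin), y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "coverage bin (equal occupancy)", y = "weight",
                  title = "Covariate weights") +
    ggplot2::theme_minimal()
}
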