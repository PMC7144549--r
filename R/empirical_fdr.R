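#' Empirical FDR from matched neutral simulations
#'
#' Nonparametric empirical false-discovery-rate estimation. At every
#' candidate threshold t (the distinct observed weighted p values) the
#' expected null exceedance count is estimated *conservatively* from the M
#' matched neutral sets: the exceedances pooled over sets, `T(t)`, are
#' treated as a Poisson count with mean `M * lambda(t)` and replaced by the
#' exact one-sided upper confidence bound `qgamma(level, T + 1) / M`
#' (Garwood bound; `level` defaults to 0.95). The estimate is then
#' `efdr(t) = min(1, qgamma(level, T(t) + 1) / (M * max(1, n_obs(t))))`.
#' The upper bound is what makes a finite simulation honest: the plain
#' ratio `mean(T)/n_obs` is unbiased but noisy, and because candidates are
#' declared at the *largest* threshold passing the cutoff, its downward
#' fluctuations systematically leak false discoveries at the declaration
#' boundary. The per-item q value is the monotone step-down envelope
#' `q(t) = min over t' >= t of efdr(t')`, which makes candidate declaration
#' threshold-consistent.
#'
#' @param p_obs Observed weighted p values.
#' @param p_null_sets A list of M weighted p-value vectors from matched
#'   neutral simulations, each the same length as `p_obs`.
#' @param level One-sided confidence level of the upper bound on the mean
#'   null exceedance count; 0.95 by default. `level = 0` reproduces the
#'   plain (non-conservative) plug-in ratio.
#' @return An object of class `efdr_curve` with elements `curve` (tibble:
#'   `threshold`, `n_obs_le`, `n_null_le_mean`, `efdr`, `q`), `q` (per-item
#'   q values aligned with `p_obs`), `p_obs`, and `n_null_sets`.
#' @export
efdr_q_values <- function(p_obs, p_null_sets, level = 0.95) {
  if (length(p_obs) == 0) abort("`p_obs` is empty")
  if (!is.list(p_null_sets)) p_null_sets <- list(p_null_sets)
  if (length(p_null_sets) < 1) abort("need at least one null set")
  lens <- lengths(p_null_sets)
  if (any(lens != length(p_obs))) {
    abort("each null set must match the observed vector's length")
  }
  thresholds <- sort(unique(p_obs))
  ps <- sort(p_obs)
  n_obs_le <- findInterval(thresholds, ps)
  null_counts <- vapply(p_null_sets, function(pn) {
    findInterval(thresholds, sort(pn))
  }, numeric(length(thresholds)))
  null_counts <- matrix(null_counts, nrow = length(thresholds))
  n_null_le_mean <- rowMeans(null_counts)
  M <- length(p_null_sets)
  T_pooled <- rowSums(null_counts)
  null_upper <- if (level > 0) stats::qgamma(level, T_pooled + 1) / M
                else n_null_le_mean
  efdr <- pmin(1, null_upper / pmax(1, n_obs_le))
  q <- rev(cummin(rev(efdr)))
  curve <- tibble(
    threshold = thresholds, n_obs_le = n_obs_le,
    n_null_le_mean = n_null_le_mean, efdr = efdr, q = q
  )
  structure(
    list(curve = curve, q = q[match(p_obs, thresholds)], p_obs = p_obs,
         n_null_sets = length(p_null_sets)),
    class = "efdr_curve"
  )
}

#' Declare candidates at a target empirical FDR
#'
#' Picks the largest threshold t* whose step-down q value does not exceed
#' `alpha`; all items with weighted p at or below t* are candidates. When no
#' threshold qualifies the candidate set is empty.
#'
#' @param curve An `efdr_curve` from [efdr_q_values()].
#' @param alpha Target FDR in (0, 1), e.g. 0.01 or 0.05.
#' @return A list with `threshold` (t*, or `NA` if none qualifies),
#'   `candidates` (integer indices into the observed vector), `alpha` and
#'   `n_candidates`.
#' @export
declare_candidates <- function(curve, alpha = 0.01) {
  stopifnot(inherits(curve, "efdr_curve"))
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1)")
  ok <- which(curve$curve$q <= alpha)
  if (length(ok) == 0) {
    return(list(threshold = NA_real_, candidates = integer(0),
                alpha = alpha, n_candidates = 0L))
  }
  tstar <- max(curve$curve$threshold[ok])
  cand <- which(curve$p_obs <= tstar)
  list(threshold = tstar, candidates = cand, alpha = alpha,
       n_candidates = length(cand))
}

#' @export
print.efdr_curve <- function(x, ...) {
  cat("<efdr_curve>\n")
  cat(sprintf("  %d observed p values, %d null set(s)\n",
              length(x$p_obs), x$n_null_sets))
  for (a in c(0.01, 0.05)) {
    d <- declare_candidates(x, a)
    cat(sprintf("  candidates at %g%% FDR: %d\n", 100 * a, d$n_candidates))
  }
  invisible(x)
}

#' @export
tidy.efdr_curve <- function(x, ...) x$curve

#' @export
glance.efdr_curve <- function(x, ...) {
  tibble(
    n_obs = length(x$p_obs),
    n_null_sets = x$n_null_sets,
    n_candidates_fdr01 = declare_candidates(x, 0.01)$n_candidates,
    n_candidates_fdr05 = declare_candidates(x, 0.05)$n_candidates
  )
}

#' @export
autoplot.efdr_curve <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = -log10(.data$threshold))) +
    ggplot2::geom_step(ggplot2::aes(y = .data$efdr), colour = "grey60") +
    ggplot2::geom_step(ggplot2::aes(y = .data$q), colour = "black") +
    ggplot2::geom_hline(yintercept = c(0.01, 0.05), linetype = "dotted") +
    ggplot2::labs(x = expression(-log[10](threshold)),
                  y = "empirical FDR (grey) / q envelope (black)",
                  title = "Empirical FDR curve") +
    ggplot2::theme_minimal()
}
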