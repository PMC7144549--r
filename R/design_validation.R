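#' Plan a dilution (secondary-experiment founding) mix
#'
#' Under the deterministic mixing model `d0 = m * evolved + (1 - m) *
#' ancestral`, finds the set of mixing proportions m for which every
#' candidate SNP's predicted D0 frequency lands inside `target_range`
#' (intermediate frequencies give a deterministic re-selection response
#' while leaving room to rise). The feasible set is the intersection of the
#' per-SNP m-intervals; the recommended m is its midpoint. When the
#' intersection is empty the plan is reported infeasible together with the
#' size of the largest satisfiable SNP subset.
#'
#' @param evolved,ancestral Candidate-SNP allele frequencies in the evolved
#'   and (reconstituted) ancestral populations, aligned.
#' @param target_range Length-2 numeric, default `c(0.25, 0.75)`.
#' @return An object of class `dilution_plan`: `feasible`, `m_interval`,
#'   `m` (recommended; `NA` if infeasible), `predicted_d0` at the
#'   recommended m, `n_snps`, `max_satisfiable` (largest subset size with a
#'   common m, reported when infeasible).
#' @export
plan_dilution <- function(evolved, ancestral, target_range = c(0.25, 0.75)) {
  assert_prob(evolved, "evolved")
  assert_prob(ancestral, "ancestral")
  if (length(evolved) != length(ancestral) || length(evolved) == 0) {
    abort("`evolved` and `ancestral` must be aligned, non-empty vectors")
  }
  L <- target_range[1]; U <- target_range[2]
  if (!(L >= 0 && L < U && U <= 1)) abort("need 0 <= L < U <= 1")
  d <- evolved - ancestral
  lo <- ifelse(d > 0, (L - ancestral) / d,
        ifelse(d < 0, (U - ancestral) / d,
               ifelse(ancestral >= L & ancestral <= U, 0, 1)))
  hi <- ifelse(d > 0, (U - ancestral) / d,
        ifelse(d < 0, (L - ancestral) / d,
               ifelse(ancestral >= L & ancestral <= U, 1, 0)))
  lo <- pmax(0, pmin(1, lo))
  hi <- pmax(0, pmin(1, hi))
  bad <- lo > hi   # constant-prediction SNPs outside the window
  m_lo <- max(lo)
  m_hi <- min(hi)
  feasible <- !any(bad) && m_lo <= m_hi
  if (feasible) {
    m <- (m_lo + m_hi) / 2
    plan <- list(
      feasible = TRUE, m_interval = c(m_lo, m_hi), m = m,
      predicted_d0 = dilute(evolved, ancestral, m),
      intervals = tibble(lower = lo, upper = hi),
      n_snps = length(evolved), max_satisfiable = length(evolved),
      target_range = c(L, U)
    )
  } else {
    # largest subset with a common m: interval stabbing by endpoint sweep
    okiv <- which(!bad)
    if (length(okiv) > 0) {
      ev <- rbind(cbind(lo[okiv], 1), cbind(hi[okiv] + 1e-12, -1))
      ev <- ev[order(ev[, 1], -ev[, 2]), , drop = FALSE]
      depth <- cumsum(ev[, 2])
      best <- max(depth)
      best_m <- if (best > 0) ev[which.max(depth), 1] else NA_real_
    } else {
      best <- 0
      best_m <- NA_real_
    }
    plan <- list(
      feasible = FALSE, m_interval = c(NA_real_, NA_real_), m = NA_real_,
      predicted_d0 = rep(NA_real_, length(evolved)),
      intervals = tibble(lower = lo, upper = hi),
      n_snps = length(evolved), max_satisfiable = as.integer(best),
      best_m = best_m, target_range = c(L, U)
    )
  }
  structure(plan, class = "dilution_plan")
}

#' @export
print.dilution_plan <- function(x, ...) {
  cat("<dilution_plan>\n")
  if (x$feasible) {
    cat(sprintf("  feasible m in [%.3f, %.3f]; recommended m = %.3f (%d SNPs)\n",
                x$m_interval[1], x$m_interval[2], x$m, x$n_snps))
  } else {
    cat(sprintf("  infeasible for all %d SNPs; largest satisfiable subset: %d\n",
                x$n_snps, x$max_satisfiable))
  }
  invisible(x)
}

#' @export
tidy.dilution_plan <- function(x, ...) {
  dplyr::mutate(x$intervals, predicted_d0 = x$predicted_d0)
}

#' @export
glance.dilution_plan <- function(x, ...) {
  tibble(feasible = x$feasible, m = x$m, m_lower = x$m_interval[1],
         m_upper = x$m_interval[2], n_snps = x$n_snps,
         max_satisfiable = x$max_satisfiable)
}

#' Probability ellipse of 2-D points
#'
#' Normal-theory coverage ellipse: centred on the mean, shaped by the sample
#' covariance, with squared Mahalanobis radius at the chi-square quantile
#' (df = 2) of the coverage level.
#'
#' @param points A two-column matrix or data frame of (x, y) pairs; at least
#'   3 non-collinear points.
#' @param level Coverage probability in (0, 1), default 0.99.
#' @return An object of class `prob_ellipse`: `center`, `cov`, `radius2`
#'   (`qchisq(level, 2)`), `level`, `n`.
#' @export
probability_ellipse <- function(points, level = 0.99) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) abort("`points` must have two columns")
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3) abort("need at least 3 points")
  if (!(level > 0 && level < 1)) abort("`level` must be in (0, 1)")
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  if (!all(is.finite(S)) || det(S) <= .Machine$double.eps * max(1, sum(S^2))) {
    abort("degenerate point set (identical or collinear points)")
  }
  structure(
    list(center = ctr, cov = S, radius2 = stats::qchisq(level, df = 2),
         level = level, n = nrow(pts)),
    class = "prob_ellipse"
  )
}

#' Test whether points lie inside a probability ellipse
#'
#' @param points Two-column matrix/data frame.
#' @param ellipse A `prob_ellipse`.
#' @return Logical vector: squared Mahalanobis distance `<= radius2`.
#' @export
in_ellipse <- function(points, ellipse) {
  stopifnot(inherits(ellipse, "prob_ellipse"))
  pts <- as.matrix(points)
  d2 <- stats::mahalanobis(pts, ellipse$center, ellipse$cov)
  d2 <= ellipse$radius2
}

#' Boundary coordinates of a probability ellipse (for plotting)
#'
#' @param ellipse A `prob_ellipse`.
#' @param n Number of boundary points.
#' @return A tibble with columns `x`, `y`.
#' @export
ellipse_points <- function(ellipse, n = 181) {
  stopifnot(inherits(ellipse, "prob_ellipse"))
  eig <- eigen(ellipse$cov, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(theta), sin(theta)) * sqrt(ellipse$radius2)
  xy <- t(eig$vectors %*% (sqrt(pmax(eig$values, 0)) * circ) + ellipse$center)
  tibble(x = xy[, 1], y = xy[, 2])
}

#' Primary-versus-secondary concordance of frequency changes
#'
#' Summarises how faithfully a secondary (dilution) experiment reproduces
#' the primary experiment's selection signal: Pearson correlation and
#' sign (quadrant) concordance of the paired AFCs, a probability ellipse
#' around the focal SNPs, and a separation score against a matched neutral
#' simulation cloud (the fraction of focal points falling outside the
#' neutral cloud's own ellipse at the same level).
#'
#' @param primary_afc,secondary_afc Aligned AFC vectors.
#' @param focal Integer indices of focal (candidate) SNPs; default all.
#' @param neutral_pairs Optional two-column matrix/data frame of AFC pairs
#'   from matched neutral simulation.
#' @param level Ellipse coverage probability, default 0.99.
#' @return An object of class `concordance_report`: `pearson_r`,
#'   `quadrant_concordance`, `n_candidates`, `ellipse` (or `NULL` with a
#'   flag when < 3 usable focal points), `neutral_ellipse`,
#'   `separation_score`, plus the point sets for plotting.
#' @export
concordance_summary <- function(primary_afc, secondary_afc, focal = NULL,
                                neutral_pairs = NULL, level = 0.99) {
  if (length(primary_afc) != length(secondary_afc)) {
    abort("AFC vectors must be aligned")
  }
  focal <- focal %||% seq_along(primary_afc)
  ok <- stats::complete.cases(primary_afc, secondary_afc)
  r <- stats::cor(primary_afc[ok], secondary_afc[ok])
  quad <- mean(primary_afc[ok] * secondary_afc[ok] > 0)
  fx <- cbind(primary_afc, secondary_afc)[intersect(focal, which(ok)), ,
                                          drop = FALSE]
  ell <- NULL; flag <- NA_character_
  if (nrow(fx) >= 3) {
    ell <- tryCatch(probability_ellipse(fx, level),
                    error = function(e) NULL)
    if (is.null(ell)) flag <- "degenerate_focal_ellipse"
  } else {
    flag <- "too_few_focal_points"
  }
  nell <- NULL; sep <- NA_real_
  if (!is.null(neutral_pairs)) {
    nm <- as.matrix(neutral_pairs)
    nell <- tryCatch(probability_ellipse(nm, level), error = function(e) NULL)
    if (!is.null(nell) && nrow(fx) > 0) {
      sep <- mean(!in_ellipse(fx, nell))
    }
  }
  structure(
    list(pearson_r = r, quadrant_concordance = quad,
         n_candidates = nrow(fx), ellipse = ell, neutral_ellipse = nell,
         separation_score = sep, level = level, flag = flag,
         pairs = tibble(primary_afc = primary_afc,
                        secondary_afc = secondary_afc,
                        focal = seq_along(primary_afc) %in% focal),
         neutral_pairs = if (is.null(neutral_pairs)) NULL else {
           nm <- as.matrix(neutral_pairs)
           tibble(primary_afc = nm[, 1], secondary_afc = nm[, 2])
         }),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  cat(sprintf("  Pearson r = %.3f, sign concordance = %.3f (%d focal SNPs)\n",
              x$pearson_r, x$quadrant_concordance, x$n_candidates))
  if (!is.na(x$separation_score)) {
    cat(sprintf("  separation from neutral cloud (level %g): %.3f\n",
                x$level, x$separation_score))
  }
  invisible(x)
}

#' @export
tidy.concordance_report <- function(x, ...) x$pairs

#' @export
glance.concordance_report <- function(x, ...) {
  tibble(pearson_r = x$pearson_r,
         quadrant_concordance = x$quadrant_concordance,
         n_candidates = x$n_candidates,
         separation_score = x$separation_score,
         level = x$level, flag = x$flag)
}

#' @export
autoplot.concordance_report <- function(object, ...) {
  g <- ggplot2::ggplot(object$pairs,
                       ggplot2::aes(x = .data$primary_afc,
                                    y = .data$secondary_afc))
  if (!is.null(object$neutral_pairs)) {
    g <- g + ggplot2::geom_point(data = object$neutral_pairs,
                                 colour = "orange", alpha = 0.5)
  }
  g <- g +
    ggplot2::geom_point(ggplot2::aes(colour = .data$focal), alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red"))
  if (!is.null(object$ellipse)) {
    g <- g + ggplot2::geom_path(data = ellipse_points(object$ellipse),
                                ggplot2::aes(x = .data$x, y = .data$y),
                                inherit.aes = FALSE)
  }
  if (!is.null(object$neutral_ellipse)) {
    g <- g + ggplot2::geom_path(data = ellipse_points(object$neutral_ellipse),
                                ggplot2::aes(x = .data$x, y = .data$y),
                                inherit.aes = FALSE, colour = "orange")
  }
  g + ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "primary AFC", y = "secondary AFC",
                  title = "Repeatability of frequency changes") +
    ggplot2::theme_minimal()
}
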