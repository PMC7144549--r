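#' Pseudo-count allele frequency
#'
#' Laplace-half stabilised frequency `(alt + 0.5) / (coverage + 1)`: never
#' exactly 0 or 1, so logit transforms and F-statistics stay finite. Cells
#' with zero coverage are missing (`NA`).
#'
#' @param ref_count,alt_count Non-negative read counts (vectors).
#' @return Frequencies in (0, 1); `NA` where coverage is zero.
#' @export
#' @examples
#' pseudo_count_freq(20, 0)    # 0.5 / 21
#' pseudo_count_freq(10, 10)   # 0.5
pseudo_count_freq <- function(ref_count, alt_count) {
  if (any(ref_count < 0 | alt_count < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  R <- ref_count + alt_count
  ifelse(is.na(R) | R == 0, NA_real_, (alt_count + 0.5) / (R + 1))
}

#' Allele-frequency change between two time points
#'
#' AFC per variant and replicate on pseudo-count frequencies:
#' `p(to) - p(from)`, in \[-1, 1\]. Missing cells yield missing AFCs with a
#' flag.
#'
#' @param counts Long count tibble.
#' @param samples Sample sheet.
#' @param from_tp,to_tp Timepoint labels; default per-replicate first/last
#'   generation.
#' @return A tibble: variant key columns, `replicate`, `p_from`, `p_to`,
#'   `afc`, `flag`.
#' @export
compute_afc <- function(counts, samples, from_tp = NULL, to_tp = NULL) {
  assert_count_tbl(counts)
  assert_sample_sheet(samples)
  ends <- .endpoint_samples(samples, from_tp, to_tp)
  pair <- dplyr::inner_join(
    dplyr::select(ends$from, "replicate", from_id = "sample_id"),
    dplyr::select(ends$to, "replicate", to_id = "sample_id"),
    by = "replicate"
  )
  purrr::pmap_dfr(pair, function(replicate, from_id, to_id) {
    c0 <- counts[counts$sample_id == from_id, ]
    c1 <- counts[counts$sample_id == to_id, ]
    c1 <- c1[match(paste(c0$chrom, c0$pos), paste(c1$chrom, c1$pos)), ]
    p_from <- pseudo_count_freq(c0$ref_count, c0$alt_count)
    p_to <- pseudo_count_freq(c1$ref_count, c1$alt_count)
    tibble(
      chrom = c0$chrom, pos = c0$pos, ref = c0$ref, alt = c0$alt,
      replicate = replicate, p_from = p_from, p_to = p_to,
      afc = p_to - p_from,
      flag = ifelse(is.na(p_from) | is.na(p_to), "missing_cell",
                    NA_character_)
    )
  })
}

#' Temporal effective population size from two allele-frequency samples
#'
#' Waples-style temporal estimator adapted to Pool-Seq: per SNP,
#' `Fc = (p0 - pt)^2 / (z - p0 * pt)` with `z = (p0 + pt) / 2`, aggregated
#' over SNPs as a ratio of sums. The two-stage sampling noise of pooled
#' sequencing (individuals into the pool, then reads over the pool) is
#' removed via `1/S = 1/(2n) + 1/R - 1/(2nR)` at each time point (`n` pool
#' size in diploids, `R` read depth), averaged over SNPs; the final-time
#' noise term is additionally scaled by the drift-reduced terminal
#' heterozygosity. The corrected F is inverted through the exact drift
#' relation
#' `E[F] = 1 - (1 - 1/(2 Ne))^t` (equivalent to `t / (2 F)` for small
#' `t / Ne` but unbiased for longer experiments). A non-positive corrected F
#' (no drift signal beyond sampling noise) gives an infinite estimate with
#' the `infinite_ne` flag.
#'
#' @param p0,pt Pseudo-count allele frequencies at the two time points.
#' @param t Generations between the samples (>= 1).
#' @param n0,nt Pool sizes (diploid individuals) at the two time points.
#' @param r0,rt Read depths per SNP at the two time points.
#' @return An object of class `ne_estimate` (also a one-row tibble via
#'   [generics::tidy()]): fields `ne`, `f_bar`, `correction`, `t`,
#'   `n_snps`, `infinite_ne`.
#' @export
estimate_ne <- function(p0, pt, t, n0, nt, r0, rt) {
  if (length(pt) != length(p0)) abort("`p0` and `pt` lengths differ")
  if (t < 1) abort("`t` must be >= 1")
  r0 <- rep_len(r0, length(p0))
  rt <- rep_len(rt, length(p0))
  ok <- !is.na(p0) & !is.na(pt) & r0 > 0 & rt > 0
  z <- (p0 + pt) / 2
  den <- z - p0 * pt
  ok <- ok & den > 0
  if (!any(ok)) abort("no informative SNP (all fixed or missing)")
  if (sum(ok) < 100) {
    warn(sprintf("only %d informative SNPs; Ne estimate has high variance",
                 sum(ok)))
  }
  num <- (p0 - pt)^2
  f_bar <- sum(num[ok]) / sum(den[ok])
  inv_s <- function(n, r) 1 / (2 * n) + 1 / r - 1 / (2 * n * r)
  c0 <- mean(inv_s(n0, r0[ok]))
  ct <- mean(inv_s(nt, rt[ok]))
  corr <- c0 + ct
  # the final-time noise term scales with terminal heterozygosity, itself
  # reduced by drift by (1 - F); solving F = f_bar - c0 - ct (1 - F) keeps
  # the estimator near-unbiased for long experiments
  f_drift <- (f_bar - c0 - ct) / (1 - ct)
  # exact inversion of the per-generation drift recursion
  # E[F] = 1 - (1 - 1/(2Ne))^t; the small-F linearisation t/(2F) overshoots
  # Ne noticeably once t/Ne is no longer small
  ne <- if (f_drift > 0 && f_drift < 1) {
    1 / (2 * (1 - (1 - f_drift)^(1 / t)))
  } else if (f_drift >= 1) {
    0.5  # drift signal at its ceiling: smallest expressible size
  } else {
    Inf
  }
  structure(
    list(ne = ne, f_bar = f_bar, correction = corr, t = t,
         n_snps = sum(ok), infinite_ne = !is.finite(ne)),
    class = "ne_estimate"
  )
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("<ne_estimate> Ne = %s (F = %.5g, sampling correction = %.5g, t = %d, %d SNPs)\n",
              if (x$infinite_ne) "Inf" else sprintf("%.1f", x$ne),
              x$f_bar, x$correction, x$t, x$n_snps))
  invisible(x)
}

#' @export
tidy.ne_estimate <- function(x, ...) {
  tibble(kind = "ne", value = x$ne, f_bar = x$f_bar,
         correction = x$correction, t = x$t, n_snps = x$n_snps,
         infinite_ne = x$infinite_ne)
}

#' @export
glance.ne_estimate <- function(x, ...) tidy(x)

#' Per-replicate Ne estimates from a count table
#'
#' Applies [estimate_ne()] to every replicate's first/last sequenced
#' generations using pseudo-count frequencies.
#'
#' @inheritParams compute_afc
#' @return A tibble with one row per replicate: `replicate`, `ne`, `f_bar`,
#'   `correction`, `t`, `n_snps`, `infinite_ne`.
#' @export
estimate_ne_table <- function(counts, samples, from_tp = NULL, to_tp = NULL) {
  ends <- .endpoint_samples(samples, from_tp, to_tp)
  purrr::map_dfr(unique(ends$from$replicate), function(r) {
    s0 <- ends$from[ends$from$replicate == r, ]
    s1 <- ends$to[ends$to$replicate == r, ]
    c0 <- counts[counts$sample_id == s0$sample_id, ]
    c1 <- counts[counts$sample_id == s1$sample_id, ]
    c1 <- c1[match(paste(c0$chrom, c0$pos), paste(c1$chrom, c1$pos)), ]
    est <- estimate_ne(
      pseudo_count_freq(c0$ref_count, c0$alt_count),
      pseudo_count_freq(c1$ref_count, c1$alt_count),
      t = s1$generation - s0$generation,
      n0 = s0$pool_size, nt = s1$pool_size,
      r0 = c0$ref_count + c0$alt_count, rt = c1$ref_count + c1$alt_count
    )
    dplyr::mutate(dplyr::rename(tidy(est), ne = "value"),
                  replicate = r, .before = 1)
  })
}

#' Selection coefficient from an allele-frequency time series
#'
#' For additive selection (`h = 0.5`, fitnesses `1 + s`, `1 + s/2`, `1`) the
#' deterministic frequency recursion advances the logit of p by
#' approximately `log(1 + s/2)` per generation. The estimator fits a
#' least-squares slope `b` of `logit(p_t)` on generations and inverts that
#' increment: `s_hat = 2 * (exp(b) - 1)`. Other dominance coefficients are
#' refused (no closed-form logit-linear inverse).
#'
#' @param freqs Allele frequencies in (0, 1) (pseudo-count stabilised
#'   upstream); at least two time points.
#' @param generations Generation of each frequency.
#' @param h Dominance coefficient; only 0.5 is supported.
#' @return An object of class `s_estimate` with fields `s`, `slope`,
#'   `n_timepoints`, `flag` (`"boundary"` when the series touches the
#'   pseudo-count extremes).
#' @export
#' @examples
#' estimate_s(c(0.52, 0.98), c(0, 30))
estimate_s <- function(freqs, generations, h = 0.5) {
  if (!identical(h, 0.5)) {
    abort("only h = 0.5 (additive selection) is supported by the logit-linear estimator")
  }
  if (length(freqs) != length(generations)) {
    abort("`freqs` and `generations` lengths differ")
  }
  keep <- !is.na(freqs)
  freqs <- freqs[keep]; generations <- generations[keep]
  if (length(freqs) < 2) abort("need at least two time points")
  if (any(freqs <= 0 | freqs >= 1)) {
    abort("frequencies must be strictly inside (0, 1); apply pseudo-counts")
  }
  flag <- NA_character_
  if (any(freqs < 0.01 | freqs > 0.99)) flag <- "boundary"
  y <- logit(freqs)
  b <- if (stats::var(generations) == 0) 0
       else stats::cov(generations, y) / stats::var(generations)
  structure(
    list(s = 2 * (exp(b) - 1), slope = b,
         n_timepoints = length(freqs), flag = flag),
    class = "s_estimate"
  )
}

#' @export
print.s_estimate <- function(x, ...) {
  cat(sprintf("<s_estimate> s = %.4f (logit slope %.4f, %d time points%s)\n",
              x$s, x$slope, x$n_timepoints,
              if (is.na(x$flag)) "" else paste0(", ", x$flag)))
  invisible(x)
}

#' @export
tidy.s_estimate <- function(x, ...) {
  tibble(kind = "s", value = x$s, slope = x$slope,
         n_timepoints = x$n_timepoints, flag = x$flag)
}

#' @export
glance.s_estimate <- function(x, ...) tidy(x)

#' Per-SNP selection coefficients from a count table
#'
#' Estimates `s` for each variant in each replicate from the pseudo-count
#' frequencies at all sequenced generations of that replicate (for the usual
#' two-time-point design this uses the endpoints).
#'
#' @param counts Long count tibble.
#' @param samples Sample sheet; restrict beforehand to one phase if desired.
#' @param variants Optional tibble with `chrom`, `pos` to restrict to.
#' @param h Dominance coefficient; only 0.5 is supported.
#' @return A tibble: variant key columns, `replicate`, `phase`, `s`,
#'   `slope`, `n_timepoints`, `flag`.
#' @export
estimate_s_table <- function(counts, samples, variants = NULL, h = 0.5) {
  assert_count_tbl(counts)
  assert_sample_sheet(samples)
  if (!is.null(variants)) {
    counts <- dplyr::semi_join(counts, variants, by = c("chrom", "pos"))
  }
  dat <- counts %>%
    dplyr::inner_join(
      dplyr::select(samples, "sample_id", "replicate", "generation", "phase"),
      by = "sample_id"
    ) %>%
    dplyr::mutate(p = pseudo_count_freq(.data$ref_count, .data$alt_count))
  dat %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$replicate, .data$phase) %>%
    dplyr::summarise(
      tryCatch({
        est <- estimate_s(.data$p, .data$generation, h = h)
        tibble(s = est$s, slope = est$slope,
               n_timepoints = est$n_timepoints, flag = est$flag)
      }, error = function(e) {
        tibble(s = NA_real_, slope = NA_real_, n_timepoints = 0L,
               flag = "insufficient_data")
      }),
      .groups = "drop"
    )
}
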