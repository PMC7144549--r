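# vectorised two-sided Fisher p values by minimum-likelihood enumeration of
# the hypergeometric support; matches stats::fisher.test's tail rule
# (probabilities <= observed up to a 1 + 1e-7 relative tolerance)
fet_pvalues <- function(ref0, alt0, ref1, alt1) {
  m <- ref0 + ref1          # total ref
  nn <- alt0 + alt1         # total alt
  k <- ref0 + alt0          # first-sample depth
  x <- ref0
  nvar <- length(x)
  p <- rep(1, nvar)
  ok <- m > 0 & nn > 0 & k > 0 & (ref1 + alt1) > 0
  if (!any(ok)) return(list(p = p, degenerate = !ok))
  lo <- pmax(0, k - nn)[ok]
  hi <- pmin(k, m)[ok]
  lens <- hi - lo + 1
  gid <- rep.int(seq_along(lens), lens)
  xs <- sequence(lens, from = lo)
  d <- stats::dhyper(xs, m[ok][gid], nn[ok][gid], k[ok][gid])
  dobs <- stats::dhyper(x[ok], m[ok], nn[ok], k[ok])
  inc <- d <= dobs[gid] * (1 + 1e-7)
  psum <- rowsum(d * inc, gid)[, 1]
  p[ok] <- pmin(1, psum)
  list(p = p, degenerate = !ok)
}

#' Fisher's exact test on a 2x2 table of allele counts
#'
#' Two-sided exact test comparing (ref, alt) counts between two time points
#' of one replicate, using the minimum-likelihood tail rule (sum of
#' hypergeometric probabilities not exceeding the observed table's). A zero
#' margin (variant monomorphic or a sample unsequenced) yields `p = 1` with a
#' `"degenerate"` flag.
#'
#' @param c0 Integer vector `c(ref, alt)` at the first time point.
#' @param c1 Integer vector `c(ref, alt)` at the second time point.
#' @return A one-row tibble: `statistic` (log odds ratio, 0.5-corrected),
#'   `p_raw`, `covariate` (mean coverage of the two samples) and `flag`.
#' @export
#' @examples
#' fisher_exact_2x2(c(8, 2), c(1, 5))
fisher_exact_2x2 <- function(c0, c1) {
  if (length(c0) != 2 || length(c1) != 2 || any(c(c0, c1) < 0)) {
    abort("`c0` and `c1` must be non-negative (ref, alt) pairs")
  }
  res <- fet_pvalues(c0[1], c0[2], c1[1], c1[2])
  lor <- log((c0[1] + 0.5) * (c1[2] + 0.5) / ((c0[2] + 0.5) * (c1[1] + 0.5)))
  tibble(
    statistic = lor,
    p_raw = res$p,
    covariate = mean(c(sum(c0), sum(c1))),
    flag = if (res$degenerate) "degenerate" else NA_character_
  )
}

#' Cochran-Mantel-Haenszel test across replicate strata
#'
#' Mantel-Haenszel chi-square (1 df, no continuity correction by default)
#' for association between time point and allele, stratified by replicate.
#' Strata with a degenerate margin contribute nothing; if all strata are
#' degenerate the result is `p = 1` with a flag. A single stratum reduces to
#' the ordinary uncorrected chi-square of that table.
#'
#' @param strata A list of 2x2 matrices (rows = time points, cols =
#'   c(ref, alt)), one per replicate.
#' @param correct Apply the continuity correction? Default `FALSE`.
#' @return A one-row tibble: `statistic` (chi-square), `p_raw`, `covariate`
#'   (mean coverage over all samples) and `flag`.
#' @export
#' @examples
#' cmh_test(list(matrix(c(8, 1, 2, 5), 2), matrix(c(9, 2, 3, 6), 2)))
cmh_test <- function(strata, correct = FALSE) {
  if (!is.list(strata) || length(strata) < 1) {
    abort("`strata` must be a non-empty list of 2x2 tables")
  }
  a <- e <- v <- numeric(length(strata))
  covs <- numeric(0)
  for (i in seq_along(strata)) {
    tab <- strata[[i]]
    if (!all(dim(tab) == c(2, 2)) || any(tab < 0)) {
      abort("each stratum must be a non-negative 2x2 table")
    }
    covs <- c(covs, rowSums(tab))
    N <- sum(tab)
    if (N <= 1) { v[i] <- 0; next }
    r <- rowSums(tab); cc <- colSums(tab)
    a[i] <- tab[1, 1]
    e[i] <- r[1] * cc[1] / N
    v[i] <- r[1] * r[2] * cc[1] * cc[2] / (N^2 * (N - 1))
  }
  vsum <- sum(v)
  if (vsum == 0) {
    return(tibble(statistic = 0, p_raw = 1, covariate = mean(covs),
                  flag = "degenerate"))
  }
  dev <- sum(a - e)
  stat <- (max(0, abs(dev) - if (correct) 0.5 else 0))^2 / vsum
  tibble(
    statistic = stat,
    p_raw = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    covariate = mean(covs),
    flag = NA_character_
  )
}

# vectorised CMH across variants: per-replicate count matrices
# lists ref0/alt0/ref1/alt1, each a [variant x replicate] matrix
cmh_pvalues <- function(ref0, alt0, ref1, alt1, correct = FALSE) {
  N <- ref0 + alt0 + ref1 + alt1
  r1 <- ref0 + alt0; r2 <- ref1 + alt1
  c1 <- ref0 + ref1; c2 <- alt0 + alt1
  ok <- N > 1
  e <- ifelse(ok, r1 * c1 / pmax(N, 1), 0)
  v <- ifelse(ok, r1 * r2 * c1 * c2 / (pmax(N, 1)^2 * pmax(N - 1, 1)), 0)
  a <- ifelse(ok, ref0, 0)
  dev <- rowSums(a - e)
  vsum <- rowSums(v)
  stat <- ifelse(vsum > 0,
                 pmax(0, abs(dev) - if (correct) 0.5 else 0)^2 / vsum, 0)
  p <- ifelse(vsum > 0,
              stats::pchisq(stat, df = 1, lower.tail = FALSE), 1)
  list(statistic = stat, p = p, degenerate = vsum == 0)
}

# wide per-variant count matrices for a set of replicates at two timepoints
.count_matrices <- function(counts, samples, replicates, from_tp, to_tp) {
  ends <- .endpoint_samples(samples[samples$replicate %in% replicates, ],
                            from_tp, to_tp)
  vars <- dplyr::distinct(counts, .data$chrom, .data$pos, .data$ref,
                          .data$alt)
  key <- paste(vars$chrom, vars$pos)
  get_mat <- function(ids, col) {
    vapply(ids, function(sid) {
      sub <- counts[counts$sample_id == sid, ]
      out <- sub[[col]][match(key, paste(sub$chrom, sub$pos))]
      ifelse(is.na(out), 0L, out)
    }, integer(length(key)))
  }
  from_ids <- ends$from$sample_id[match(replicates, ends$from$replicate)]
  to_ids <- ends$to$sample_id[match(replicates, ends$to$replicate)]
  if (anyNA(from_ids) || anyNA(to_ids)) {
    miss <- c(replicates[is.na(from_ids)], replicates[is.na(to_ids)])
    abort(sprintf("missing start/end sample for replicate(s): %s",
                  paste(unique(miss), collapse = ", ")))
  }
  list(
    vars = vars,
    ref0 = get_mat(from_ids, "ref_count"), alt0 = get_mat(from_ids, "alt_count"),
    ref1 = get_mat(to_ids, "ref_count"), alt1 = get_mat(to_ids, "alt_count")
  )
}

#' Genome-scan tests on an allele count table
#'
#' Runs, per variant, either Fisher's exact test within one replicate
#' (`test = "fet"`) or the Cochran-Mantel-Haenszel test across replicates
#' (`test = "cmh"`) contrasting the first and last sequenced generation
#' (or explicit timepoint labels). The coverage covariate is the mean read
#' depth over all samples entering the test, the quantity later used for
#' p-value weighting.
#'
#' @param counts Long count tibble.
#' @param samples Sample sheet.
#' @param test `"cmh"` or `"fet"`.
#' @param replicates Replicate ids entering the test; default all in
#'   `samples` (for `"fet"` exactly one id is required).
#' @param from_tp,to_tp Optional timepoint labels; default the per-replicate
#'   first/last generation.
#' @return A tibble with one row per variant: variant key columns, `test`,
#'   `replicates`, `statistic`, `p_raw`, `covariate`, `flag`.
#' @export
test_selection <- function(counts, samples, test = c("cmh", "fet"),
                           replicates = NULL, from_tp = NULL, to_tp = NULL) {
  test <- match.arg(test)
  assert_count_tbl(counts)
  assert_sample_sheet(samples)
  replicates <- replicates %||% unique(samples$replicate)
  if (test == "fet" && length(replicates) != 1) {
    abort("FET is a within-replicate test; give exactly one replicate id")
  }
  mats <- .count_matrices(counts, samples, replicates, from_tp, to_tp)
  cov <- (mats$ref0 + mats$alt0 + mats$ref1 + mats$alt1)
  covariate <- rowSums(cov) / (2 * length(replicates))
  if (test == "fet") {
    res <- fet_pvalues(mats$ref0[, 1], mats$alt0[, 1],
                       mats$ref1[, 1], mats$alt1[, 1])
    stat <- log((mats$ref0[, 1] + 0.5) * (mats$alt1[, 1] + 0.5) /
                  ((mats$alt0[, 1] + 0.5) * (mats$ref1[, 1] + 0.5)))
    p <- res$p; degen <- res$degenerate
  } else {
    res <- cmh_pvalues(mats$ref0, mats$alt0, mats$ref1, mats$alt1)
    stat <- res$statistic; p <- res$p; degen <- res$degenerate
  }
  # never report an exact zero: floor at the smallest positive double so
  # -log10 transforms stay finite
  p <- pmax(p, .Machine$double.xmin)
  dplyr::mutate(
    mats$vars,
    test = toupper(test),
    replicates = paste(replicates, collapse = ","),
    statistic = stat,
    p_raw = p,
    covariate = covariate,
    flag = ifelse(degen, "degenerate", NA_character_)
  )
}
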