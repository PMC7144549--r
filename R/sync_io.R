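#' Read a sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `replicate`,
#' `timepoint`, `generation`, `phase` and `pool_size`, one row per sequenced
#' pool, in the column order of the matching sync file.
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      replicate = readr::col_character(),
      timepoint = readr::col_character(),
      generation = readr::col_double(),
      phase = readr::col_character(),
      pool_size = readr::col_integer()
    )
  )
  assert_sample_sheet(sheet)
}

.base_order <- c("A", "T", "C", "G")  # sync column order is A:T:C:G:N:del

#' Read a sync-format allele count table
#'
#' Parses the popoolation2 sync dialect (`chrom pos ref A:T:C:G:N:del ...`,
#' one count column per sample) into a long tibble of biallelic ref/alt
#' counts. The alternative allele is chosen by `alt_policy`; `N` and deletion
#' counts are discarded. Sites with no non-reference reads in any sample are
#' monomorphic and dropped.
#'
#' @param path Path to a sync file (no header line).
#' @param sample_sheet A tibble as returned by [read_sample_sheet()]; rows
#'   must match the sync count columns in order.
#' @param alt_policy How to pick the alternative allele. `"global_major"`
#'   (default) takes the most frequent non-reference base summed over all
#'   samples, breaking ties alphabetically.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `sample_id`,
#'   `ref_count`, `alt_count`, `coverage`.
#' @export
read_sync <- function(path, sample_sheet, alt_policy = "global_major") {
  alt_policy <- match.arg(alt_policy, "global_major")
  assert_sample_sheet(sample_sheet)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), sample_id = character(),
      ref_count = integer(), alt_count = integer(), coverage = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  n_samples <- nrow(sample_sheet)
  expected <- 3L + n_samples
  bad <- which(n_fields != expected)
  if (length(bad) > 0) {
    abort(sprintf(
      "sync line %d has %d fields; expected %d (3 + %d samples)",
      bad[1], n_fields[bad[1]], expected, n_samples
    ))
  }
  mat <- matrix(unlist(fields), ncol = expected, byrow = TRUE)
  chrom <- mat[, 1]
  pos <- suppressWarnings(as.integer(mat[, 2]))
  ref <- mat[, 3]
  bad <- which(is.na(pos) | pos < 1 | !(ref %in% c("A", "C", "G", "T")))
  if (length(bad) > 0) {
    abort(sprintf("sync line %d is malformed (position or reference base)",
                  bad[1]))
  }
  n_var <- length(pos)
  # per-sample A/T/C/G count arrays: [variant, base]
  count_arr <- array(0L, dim = c(n_var, 4L, n_samples))
  for (j in seq_len(n_samples)) {
    col <- mat[, 3L + j]
    parts <- strsplit(col, ":", fixed = TRUE)
    if (any(lengths(parts) != 6L)) {
      abort(sprintf("sync line %d sample %d: count field is not A:T:C:G:N:del",
                    which(lengths(parts) != 6L)[1], j))
    }
    pm <- matrix(suppressWarnings(as.integer(unlist(parts))),
                 ncol = 6L, byrow = TRUE)
    if (anyNA(pm) || any(pm < 0)) {
      abort(sprintf("sync line %d sample %d: non-numeric or negative count",
                    which(rowSums(is.na(pm)) > 0 | rowSums(pm < 0) > 0)[1], j))
    }
    count_arr[, , j] <- pm[, 1:4]
  }
  totals <- apply(count_arr, c(1, 2), sum)  # summed over samples
  colnames(totals) <- .base_order
  ref_idx <- match(ref, .base_order)
  non_ref <- totals
  non_ref[cbind(seq_len(n_var), ref_idx)] <- -1L
  # most frequent non-reference base; which.max over alphabetical order
  # breaks ties alphabetically
  alpha_ord <- order(.base_order)
  alt_idx <- alpha_ord[max.col(non_ref[, alpha_ord, drop = FALSE],
                               ties.method = "first")]
  alt <- .base_order[alt_idx]
  poly <- non_ref[cbind(seq_len(n_var), alt_idx)] > 0
  keep <- which(poly)
  if (length(keep) == 0) {
    warn("no polymorphic biallelic site found; returning empty table")
  }
  out <- purrr::map_dfr(seq_len(n_samples), function(j) {
    tibble(
      chrom = chrom[keep],
      pos = pos[keep],
      ref = ref[keep],
      alt = alt[keep],
      sample_id = sample_sheet$sample_id[j],
      ref_count = count_arr[cbind(keep, ref_idx[keep], j)],
      alt_count = count_arr[cbind(keep, alt_idx[keep], j)]
    )
  })
  out$coverage <- out$ref_count + out$alt_count
  dplyr::arrange(out, match(.data$chrom, unique(chrom)), .data$pos,
                 match(.data$sample_id, sample_sheet$sample_id))
}

#' Write an allele count table in sync format
#'
#' Inverse of [read_sync()]: ref and alt counts are placed in their base
#' columns of the `A:T:C:G:N:del` field, all other columns are written as 0.
#'
#' @param counts A long count tibble (see [read_sync()]).
#' @param path Output file path.
#' @param sample_order Optional character vector giving the sample column
#'   order; defaults to order of appearance in `counts`.
#' @return `path`, invisibly.
#' @export
write_sync <- function(counts, path, sample_order = NULL) {
  assert_count_tbl(counts)
  sample_order <- sample_order %||% unique(counts$sample_id)
  if (nrow(counts) == 0) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  key <- paste(counts$chrom, counts$pos, sep = ":")
  var_keys <- unique(key)
  vi <- match(key, var_keys)
  si <- match(counts$sample_id, sample_order)
  if (anyNA(si)) abort("sample_id not covered by `sample_order`")
  n_var <- length(var_keys)
  first <- !duplicated(vi)
  chrom <- counts$chrom[first]
  pos <- counts$pos[first]
  ref <- counts$ref[first]
  alt <- counts$alt[first]
  base_counts <- array(0L, dim = c(n_var, 4L, length(sample_order)))
  ref_idx <- match(ref, .base_order)
  alt_idx <- match(alt, .base_order)
  base_counts[cbind(vi, ref_idx[vi], si)] <- counts$ref_count
  base_counts[cbind(vi, alt_idx[vi], si)] <- counts$alt_count
  cols <- vapply(seq_along(sample_order), function(j) {
    sprintf("%d:%d:%d:%d:0:0",
            base_counts[, 1, j], base_counts[, 2, j],
            base_counts[, 3, j], base_counts[, 4, j])
  }, character(n_var))
  cols <- matrix(cols, nrow = n_var)
  lines <- do.call(paste, c(list(chrom, pos, ref), lapply(seq_len(ncol(cols)),
                  function(j) cols[, j]), sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a BED mask of intervals to exclude
#'
#' BED intervals are 0-based, half-open `[start, end)`; conversion against
#' 1-based sync positions happens inside [filter_snps()].
#'
#' @param path Path to a 3+ column BED file.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()),
                         comment = "#")
  if (ncol(bed) < 3) abort("BED file needs at least 3 columns")
  tibble(chrom = as.character(bed[[1]]),
         start = as.numeric(bed[[2]]),
         end = as.numeric(bed[[3]]))
}

#' Filter a SNP catalog by repeat mask and coverage quantile
#'
#' Applies the two catalog-level filters: variants inside masked (repeat)
#' intervals are removed, and variants whose coverage in any sample exceeds
#' that sample's genome-wide `coverage_quantile` are removed (a conservative
#' guard against copy-number artifacts in any one library).
#'
#' @param counts A long count tibble.
#' @param mask Optional tibble of 0-based half-open intervals
#'   (`chrom`, `start`, `end`), e.g. from [read_bed()].
#' @param coverage_quantile Upper coverage quantile in (0, 1]; default 0.99.
#' @return The filtered tibble; the removal report is attached as the
#'   `"filter_report"` attribute (see [filter_report()]).
#' @export
filter_snps <- function(counts, mask = NULL, coverage_quantile = 0.99) {
  assert_count_tbl(counts)
  if (!(coverage_quantile > 0 && coverage_quantile <= 1)) {
    abort("`coverage_quantile` must be in (0, 1]")
  }
  if (!"coverage" %in% names(counts)) {
    counts$coverage <- counts$ref_count + counts$alt_count
  }
  vkey <- paste(counts$chrom, counts$pos, sep = ":")
  masked_keys <- character(0)
  if (!is.null(mask) && nrow(mask) > 0) {
    vars <- dplyr::distinct(counts, .data$chrom, .data$pos)
    vars$pos0 <- vars$pos - 1  # sync is 1-based, BED half-open 0-based
    hit <- dplyr::inner_join(
      vars, mask,
      by = dplyr::join_by("chrom", "pos0" >= "start", "pos0" < "end")
    )
    masked_keys <- unique(paste(hit$chrom, hit$pos, sep = ":"))
  }
  thr <- counts %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      threshold = stats::quantile(.data$coverage, coverage_quantile,
                                  names = FALSE),
      .groups = "drop"
    )
  over <- counts %>%
    dplyr::left_join(thr, by = "sample_id") %>%
    dplyr::filter(.data$coverage > .data$threshold)
  high_cov_keys <- unique(paste(over$chrom, over$pos, sep = ":"))
  drop_keys <- union(masked_keys, high_cov_keys)
  kept <- counts[!(vkey %in% drop_keys), , drop = FALSE]
  n_var_in <- length(unique(vkey))
  report <- list(
    n_variants_in = n_var_in,
    n_masked = length(masked_keys),
    n_high_coverage = length(high_cov_keys),
    n_removed = length(drop_keys),
    n_variants_kept = n_var_in - length(drop_keys),
    thresholds = thr
  )
  if (nrow(kept) == 0) warn("all variants removed by filtering")
  attr(kept, "filter_report") <- report
  kept
}

#' Retrieve the removal report of the last [filter_snps()] call
#'
#' @param counts A tibble returned by [filter_snps()].
#' @return A list with removal counts per rule and the per-sample coverage
#'   thresholds.
#' @export
filter_report <- function(counts) {
  rep <- attr(counts, "filter_report")
  if (is.null(rep)) abort("no filter report attached; run filter_snps() first")
  rep
}

#' Multi-mapper concordance filter
#'
#' Pool-Seq SNP calls can be mapper-dependent. Given the same samples counted
#' under two or more read mappers, this filter tests, per variant, whether the
#' allele frequency differs between mappers (counts summed over samples per
#' mapper; chi-square homogeneity on the mappers x \{ref, alt\} table, exact
#' test when any expected cell is below 5), adjusts p values across variants
#' by Benjamini-Hochberg, and keeps variants whose adjusted p exceeds `alpha`
#' (i.e. no detectable mapper disagreement).
#'
#' @param tables A named list of two or more long count tibbles, one per
#'   mapper, sharing variants and samples.
#' @param alpha Significance level for discordance; default 0.01.
#' @return A tibble with one row per shared variant: `chrom`, `pos`, `ref`,
#'   `alt`, per-variant `p_hom`, BH-adjusted `p_adj`, logical `kept`, and a
#'   `flag` column (`"zero_coverage"` for variants untestable in some mapper,
#'   which are excluded and not kept).
#' @export
mapper_concordance_filter <- function(tables, alpha = 0.01) {
  if (!is.list(tables) || length(tables) < 2) {
    abort("need count tables from at least two mappers")
  }
  purrr::walk(tables, assert_count_tbl)
  pooled <- purrr::imap_dfr(tables, function(tb, nm) {
    tb %>%
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
      dplyr::summarise(ref_count = sum(.data$ref_count),
                       alt_count = sum(.data$alt_count), .groups = "drop") %>%
      dplyr::mutate(mapper = if (is.character(nm)) nm else paste0("mapper", nm))
  })
  n_mappers <- length(tables)
  shared <- pooled %>%
    dplyr::count(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    dplyr::filter(.data$n == n_mappers) %>%
    dplyr::select(-"n")
  if (nrow(shared) == 0) abort("no variant shared by all mappers")
  pooled <- dplyr::inner_join(pooled, shared, by = variant_key_cols) %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$mapper)
  nv <- nrow(shared)
  # variant-major ordering so each block of n_mappers rows is one variant
  ord <- order(paste(pooled$chrom, pooled$pos), pooled$mapper)
  pooled <- pooled[ord, ]
  refm <- matrix(pooled$ref_count, ncol = n_mappers, byrow = TRUE)
  altm <- matrix(pooled$alt_count, ncol = n_mappers, byrow = TRUE)
  keys <- pooled[!duplicated(paste(pooled$chrom, pooled$pos)),
                 variant_key_cols]
  cov_zero <- (refm + altm) == 0
  flag <- ifelse(rowSums(cov_zero) > 0, "zero_coverage", NA_character_)
  p_hom <- rep(NA_real_, nv)
  testable <- which(is.na(flag))
  for (i in testable) {
    tab <- cbind(refm[i, ], altm[i, ])
    exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(colSums(tab) == 0)) {        # monomorphic in every mapper
      p_hom[i] <- 1
    } else if (any(exp_cells < 5)) {
      p_hom[i] <- stats::fisher.test(tab)$p.value
    } else {
      p_hom[i] <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value
      )
    }
  }
  p_adj <- rep(NA_real_, nv)
  p_adj[testable] <- stats::p.adjust(p_hom[testable], method = "BH")
  tibble::as_tibble(keys) %>%
    dplyr::mutate(
      p_hom = p_hom,
      p_adj = p_adj,
      kept = !is.na(p_adj) & p_adj > alpha,
      flag = flag
    )
}
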