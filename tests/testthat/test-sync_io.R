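test_that("read_sync extracts biallelic ref/alt counts per the column order", {
  sheet <- two_sample_sheet()
  f <- withr::local_tempfile()
  writeLines(c(
    "2L\t5\tT\t0:10:0:0:0:0\t0:8:2:0:0:0",   # alt must be C (A:T:C:G:N:del)
    "2L\t9\tA\t7:0:0:0:0:0\t9:0:0:0:0:0"     # monomorphic: dropped
  ), f)
  tb <- read_sync(f, sheet)
  expect_equal(unique(tb$pos), 5L)
  expect_equal(unique(tb$ref), "T")
  expect_equal(unique(tb$alt), "C")
  expect_equal(tb$ref_count[tb$sample_id == "s1"], 10L)
  expect_equal(tb$alt_count[tb$sample_id == "s1"], 0L)
  expect_equal(tb$alt_count[tb$sample_id == "s2"], 2L)
})

test_that("alt policy sums over samples and breaks ties alphabetically", {
  sheet <- two_sample_sheet()
  f <- withr::local_tempfile()
  # non-ref totals: T = 3, G = 3 -> tie broken alphabetically: G
  writeLines("3R\t2\tA\t5:2:0:1:0:0\t5:1:0:2:0:0", f)
  tb <- read_sync(f, sheet)
  expect_equal(unique(tb$alt), "G")
})

test_that("malformed sync input fails with a line number", {
  sheet <- two_sample_sheet()
  f <- withr::local_tempfile()
  writeLines(c("2L\t5\tT\t0:10:0:0:0:0\t0:8:2:0:0:0",
               "2L\tnope\tT\t0:10:0:0:0:0\t0:8:2:0:0:0"), f)
  expect_error(read_sync(f, sheet), "line 2")
  writeLines("2L\t5\tT\t0:10:0:0:0:0", f)   # one sample, sheet says two
  expect_error(read_sync(f, sheet), "expected 5")
})

test_that("write_sync/read_sync round-trips simulator output byte for byte", {
  sim <- small_experiment(n = 40, seed = 3)
  # restrict to the biallelic content: variants whose alt allele was read at
  # least once (loci fixed during the experiment are no longer biallelic and
  # are dropped by read_sync by design)
  poly <- dplyr::summarise(dplyr::group_by(sim$counts, pos),
                           keep = sum(alt_count) > 0 & sum(ref_count) > 0)
  sim$counts <- sim$counts[sim$counts$pos %in% poly$pos[poly$keep], ]
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_sync(sim$counts, f1)
  tb <- read_sync(f1, sim$samples)
  write_sync(tb, f2)
  expect_identical(readLines(f1), readLines(f2))
  # content identity too (column order normalised)
  orig <- dplyr::arrange(sim$counts, pos, sample_id)
  back <- dplyr::arrange(tb, pos, sample_id)
  expect_equal(back$ref_count, orig$ref_count)
  expect_equal(back$alt_count, orig$alt_count)
  expect_equal(back$alt, orig$alt)
})

test_that("write_sync handles empty and single-cell tables", {
  f <- withr::local_tempfile()
  empty <- make_counts(matrix(integer(), 0, 1), matrix(integer(), 0, 1), "s1")
  write_sync(empty, f)
  expect_length(readLines(f), 0)
  one <- make_counts(matrix(3L), matrix(7L), "s1", ref = "A", alt = "T")
  write_sync(one, f)
  expect_equal(readLines(f), "2L\t1\tA\t3:7:0:0:0:0")
})

test_that("coverage-quantile filter removes outlier variants, not typical ones", {
  ids <- c("s1", "s2")
  ref <- matrix(40L, 100, 2); alt <- matrix(40L, 100, 2)
  tb0 <- make_counts(ref, alt, ids)
  same <- filter_snps(tb0)                     # all coverages equal
  expect_equal(nrow(same), nrow(tb0))
  alt[7, 2] <- 720L                            # 10x coverage in one sample
  tb <- make_counts(ref, alt, ids)
  # expected by direct rule evaluation on the fixture
  thr <- stats::quantile(tb$coverage[tb$sample_id == "s2"], 0.99,
                         names = FALSE)
  expect_true(800 > thr)
  out <- filter_snps(tb)
  expect_false(7 %in% out$pos)
  expect_equal(dplyr::n_distinct(out$pos), 99)
  rep <- filter_report(out)
  expect_equal(rep$n_high_coverage, 1)
  expect_equal(rep$n_masked, 0)
})

test_that("mask removal honours 0-based half-open BED against 1-based sync", {
  tb <- make_counts(matrix(40L, 10, 1), matrix(40L, 10, 1), "s1")
  mask <- tibble::tibble(chrom = "2L", start = 4, end = 6)  # covers pos 5, 6
  out <- filter_snps(tb, mask = mask)
  expect_setequal(out$pos, setdiff(1:10, c(5, 6)))
  expect_equal(filter_report(out)$n_masked, 2)
})

test_that("filter_snps is idempotent and returns a subset", {
  set.seed(5)
  nv <- 200
  cov <- matrix(80L, nv, 2)
  cov[sample(nv, 3), 1] <- 900L   # spiked outliers over a tied background
  ref <- matrix(as.integer(cov * 0.6), nv, 2)
  alt <- cov - ref
  tb <- make_counts(ref, alt, c("s1", "s2"))
  once <- filter_snps(tb)
  twice <- filter_snps(once)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  expect_true(all(once$pos %in% tb$pos))
})

test_that("empty post-filter result warns but stays valid", {
  tb <- make_counts(matrix(40L, 3, 1), matrix(40L, 3, 1), "s1")
  mask <- tibble::tibble(chrom = "2L", start = 0, end = 100)
  expect_warning(out <- filter_snps(tb, mask = mask), "all variants")
  expect_equal(nrow(out), 0)
})

test_that("concordant mappers keep everything; discordant variants drop", {
  ids <- c("s1", "s2")
  ref <- matrix(50L, 100, 2); alt <- matrix(50L, 100, 2)
  t1 <- make_counts(ref, alt, ids)
  res <- mapper_concordance_filter(list(a = t1, b = t1, c = t1))
  expect_true(all(res$kept))
  expect_true(all(res$p_adj == 1))

  # one variant with pooled counts (50,50) vs (95,5) among 100 concordant
  ref2 <- ref; alt2 <- alt
  ref2[42, ] <- c(95L, 95L); alt2[42, ] <- c(5L, 5L)
  t2 <- make_counts(ref2, alt2, ids)
  res2 <- mapper_concordance_filter(list(a = t1, b = t2))
  # independent oracle: chisq homogeneity + BH across the 100 variants
  p_orc <- sapply(1:100, function(i) {
    tab <- rbind(c(100, 100), c(sum(ref2[i, ]), sum(alt2[i, ])))
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  })
  adj_orc <- stats::p.adjust(p_orc, "BH")
  expect_equal(res2$p_adj[res2$pos == 42], adj_orc[42])
  expect_false(res2$kept[res2$pos == 42])
  expect_true(all(res2$kept[res2$pos != 42]))
})

test_that("zero-coverage-in-one-mapper variants are flagged, not kept", {
  ids <- c("s1", "s2")
  ref <- matrix(50L, 5, 2); alt <- matrix(50L, 5, 2)
  t1 <- make_counts(ref, alt, ids)
  ref2 <- ref; alt2 <- alt
  ref2[3, ] <- 0L; alt2[3, ] <- 0L
  t2 <- make_counts(ref2, alt2, ids)
  res <- mapper_concordance_filter(list(a = t1, b = t2))
  expect_equal(res$flag[res$pos == 3], "zero_coverage")
  expect_false(res$kept[res$pos == 3])
})

test_that("concordance filter kept set shrinks as alpha grows", {
  set.seed(8)
  ids <- "s1"
  ref1 <- matrix(rbinom(200, 80, 0.5), 200, 1)
  alt1 <- 80L - ref1
  ref2 <- matrix(rbinom(200, 80, 0.45), 200, 1)
  alt2 <- 80L - ref2
  t1 <- make_counts(ref1, alt1, ids); t2 <- make_counts(ref2, alt2, ids)
  kept_strict <- sum(mapper_concordance_filter(list(t1, t2), 0.001)$kept)
  kept_loose <- sum(mapper_concordance_filter(list(t1, t2), 0.2)$kept)
  expect_lte(kept_loose, kept_strict)
  expect_error(mapper_concordance_filter(list(t1)), "two mappers")
})
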