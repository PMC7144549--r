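test_that("two-sided FET matches enumeration for every table with margins <= 30", {
  # enumerate all 2x2 tables (a,b / c,d) with both row margins <= 30
  grid <- expand.grid(r1 = 0:30, r2 = 0:30, KEEP.OUT.ATTRS = FALSE)
  tabs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    r1 <- grid$r1[i]; r2 <- grid$r2[i]
    if (r1 + r2 == 0) return(NULL)
    a <- rep(0:r1, each = r2 + 1)
    c_ <- rep(0:r2, times = r1 + 1)
    cbind(a = a, b = r1 - a, c = c_, d = r2 - c_)
  }))
  got <- erpool:::fet_pvalues(tabs[, "a"], tabs[, "b"],
                              tabs[, "c"], tabs[, "d"])$p
  want <- mapply(fet_oracle, tabs[, "a"], tabs[, "b"],
                 tabs[, "c"], tabs[, "d"])
  expect_equal(got, unname(want), tolerance = 1e-10)
})

test_that("FET agrees with stats::fisher.test on random large tables", {
  set.seed(31)
  for (i in 1:50) {
    a <- rbinom(1, 120, 0.4); b <- 120 - a
    c_ <- rbinom(1, 150, 0.55); d <- 150 - c_
    expect_equal(
      fisher_exact_2x2(c(a, b), c(c_, d))$p_raw,
      stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value,
      tolerance = 1e-9
    )
  }
})

test_that("degenerate FET margins give p = 1 with a flag", {
  r <- fisher_exact_2x2(c(0, 0), c(5, 0))
  expect_equal(r$p_raw, 1)
  expect_equal(r$flag, "degenerate")
  expect_equal(fisher_exact_2x2(c(50, 50), c(50, 50))$p_raw, 1)
  expect_lt(fisher_exact_2x2(c(0, 10), c(10, 0))$p_raw, 0.01)
})

test_that("CMH equals the Mantel-Haenszel formula and its references", {
  # balanced strata: statistic 0, p 1
  bal <- cmh_test(replicate(3, matrix(c(10, 10, 10, 10), 2), simplify = FALSE))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_raw, 1)

  # two strata, hand-computed moments on printed toy counts
  s1 <- matrix(c(30, 10, 20, 25), 2, byrow = TRUE)
  s2 <- matrix(c(25, 15, 18, 30), 2, byrow = TRUE)
  hand <- local({
    num <- 0; den <- 0
    for (tab in list(s1, s2)) {
      N <- sum(tab); r <- rowSums(tab); cc <- colSums(tab)
      num <- num + tab[1, 1] - r[1] * cc[1] / N
      den <- den + r[1] * r[2] * cc[1] * cc[2] / (N^2 * (N - 1))
    }
    unname(num^2 / den)
  })
  got <- cmh_test(list(s1, s2))
  expect_equal(got$statistic, hand)
  arr <- array(c(s1, s2), c(2, 2, 2))
  ref <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_raw, ref$p.value)

  # single stratum reduces to the uncorrected chi-square up to the
  # hypergeometric-variance factor (N - 1)/N
  s <- matrix(c(8, 2, 1, 5), 2, byrow = TRUE)
  chi <- suppressWarnings(stats::chisq.test(s, correct = FALSE))
  one <- cmh_test(list(s))
  expect_equal(one$statistic,
               unname(chi$statistic) * (sum(s) - 1) / sum(s))
  expect_equal(one$p_raw,
               stats::pchisq(one$statistic, 1, lower.tail = FALSE))
})

test_that("CMH is invariant to joint row swaps and stratum order", {
  set.seed(17)
  strata <- replicate(4, matrix(rpois(4, 40), 2), simplify = FALSE)
  base <- cmh_test(strata)
  swapped <- lapply(strata, function(m) m[2:1, ])
  expect_equal(cmh_test(swapped)$statistic, base$statistic)
  expect_equal(cmh_test(rev(strata))$p_raw, base$p_raw)
  # all-degenerate strata flagged
  degen <- cmh_test(list(matrix(c(1, 0, 0, 0), 2)))
  expect_equal(degen$p_raw, 1)
  expect_equal(degen$flag, "degenerate")
})

test_that("table-level scans agree with the scalar tests", {
  sim <- small_experiment(n = 60, seed = 19, s = 0)
  fet <- test_selection(sim$counts, sim$samples, "fet", replicates = "x")
  cmh <- test_selection(sim$counts, sim$samples, "cmh")
  i <- 23
  cx <- sim$counts[sim$counts$pos == i, ]
  c0 <- cx[cx$sample_id == "x_F0", ]
  c1 <- cx[cx$sample_id == "x_F60", ]
  expect_equal(
    fet$p_raw[fet$pos == i],
    fisher_exact_2x2(c(c0$ref_count, c0$alt_count),
                     c(c1$ref_count, c1$alt_count))$p_raw
  )
  strata <- lapply(c("x", "y", "z"), function(r) {
    s0 <- cx[cx$sample_id == paste0(r, "_F0"), ]
    s1 <- cx[cx$sample_id == paste0(r, "_F60"), ]
    matrix(c(s0$ref_count, s0$alt_count, s1$ref_count, s1$alt_count),
           2, byrow = TRUE)
  })
  expect_equal(cmh$p_raw[cmh$pos == i], cmh_test(strata)$p_raw)
  expect_error(test_selection(sim$counts, sim$samples, "fet"),
               "exactly one replicate")
})

test_that("the tests' own null (sampling noise only) is not anti-conservative", {
  # effectively drift-free populations: any small p can only come from the
  # two-stage sampling noise the tests are supposed to calibrate against
  des <- experiment_design(
    n_variants = 10000, generations = c(0, 60),
    replicates = tibble::tibble(replicate = c("x", "y", "z"), ne = 1e7,
                                census = 1e7),
    coverage_mean = 80, seed = 23
  )
  sim <- simulate_experiment(des)
  cmh <- test_selection(sim$counts, sim$samples, "cmh")
  fet <- test_selection(sim$counts, sim$samples, "fet", replicates = "x")
  expect_lte(mean(cmh$p_raw <= 0.01), 0.015)
  expect_lte(mean(fet$p_raw <= 0.01), 0.015)
})
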