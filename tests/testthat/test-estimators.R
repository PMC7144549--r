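test_that("pseudo-count frequencies are stabilised and symmetric", {
  expect_equal(pseudo_count_freq(20, 0), 0.5 / 21)
  expect_equal(pseudo_count_freq(10, 10), 0.5)
  expect_equal(pseudo_count_freq(0, 40), 40.5 / 41)
  expect_true(is.na(pseudo_count_freq(0, 0)))
  expect_error(pseudo_count_freq(-1, 2), "non-negative")
})

test_that("AFC is the pseudo-count difference and is antisymmetric", {
  sheet <- two_sample_sheet()
  tb <- make_counts(matrix(c(50L, 2L), 1), matrix(c(50L, 98L), 1),
                    c("s1", "s2"))
  afc <- compute_afc(tb, sheet)
  expect_equal(afc$afc, 98.5 / 101 - 50.5 / 101)   # +0.475 on pseudo-counts
  rev_afc <- compute_afc(tb, sheet, from_tp = "F60", to_tp = "F0")
  expect_equal(rev_afc$afc, -afc$afc)
  # identical counts -> zero change
  tb2 <- make_counts(matrix(c(30L, 30L), 1), matrix(c(10L, 10L), 1),
                     c("s1", "s2"))
  expect_equal(compute_afc(tb2, sheet)$afc, 0)
})

test_that("missing cells propagate as flagged missing AFCs", {
  sheet <- two_sample_sheet()
  tb <- make_counts(matrix(c(0L, 10L), 1), matrix(c(0L, 10L), 1),
                    c("s1", "s2"))
  afc <- compute_afc(tb, sheet)
  expect_true(is.na(afc$afc))
  expect_equal(afc$flag, "missing_cell")
})

test_that("the temporal Ne estimator equals its step-by-step formula on a toy", {
  p0 <- c(0.3, 0.5, 0.7, 0.2, 0.6)
  pt <- c(0.4, 0.45, 0.6, 0.35, 0.66)
  t <- 20; n0 <- nt <- 500; r0 <- rep(100, 5); rt <- rep(120, 5)
  est <- suppressWarnings(estimate_ne(p0, pt, t, n0, nt, r0, rt))
  # independent hand evaluation
  z <- (p0 + pt) / 2
  fbar <- sum((p0 - pt)^2) / sum(z - p0 * pt)
  c0 <- mean(1 / (2 * n0) + 1 / r0 - 1 / (2 * n0 * r0))
  ct <- mean(1 / (2 * nt) + 1 / rt - 1 / (2 * nt * rt))
  fd <- (fbar - c0 - ct) / (1 - ct)
  ne_hand <- 1 / (2 * (1 - (1 - fd)^(1 / t)))
  expect_equal(suppressWarnings(estimate_ne(p0, pt, t, n0, nt, r0, rt))$ne,
               ne_hand)
  expect_equal(est$n_snps, 5)
})

test_that("no drift signal yields an infinite Ne flag", {
  p0 <- runif(200, 0.2, 0.8)
  est <- estimate_ne(p0, p0, t = 10, n0 = 1e6, nt = 1e6,
                     r0 = rep(1e6, 200), rt = rep(1e6, 200))
  expect_true(est$infinite_ne)
  expect_equal(est$ne, Inf)
})

test_that("Ne is invariant to relabelling ref and alt alleles", {
  set.seed(12)
  p0 <- runif(300, 0.1, 0.9)
  pt <- pmin(0.99, pmax(0.01, p0 + rnorm(300, 0, 0.1)))
  a <- estimate_ne(p0, pt, 30, 1000, 1000, rep(80, 300), rep(80, 300))
  b <- estimate_ne(1 - p0, 1 - pt, 30, 1000, 1000, rep(80, 300),
                   rep(80, 300))
  expect_equal(a$ne, b$ne)
})

test_that("Ne recovery stays within 15% at realistic sizes", {
  recover_once <- function(ne_true, seed) {
    set.seed(seed)
    p0 <- runif(1000, 0.05, 0.95)
    pt <- erpool:::wf_drift_final(p0, ne_true, 60)
    r0 <- rpois(1000, 80); rt <- rpois(1000, 80)
    s0 <- pool_sequence(p0, 1250, r0)
    s1 <- pool_sequence(pt, 1250, rt)
    estimate_ne(
      pseudo_count_freq(s0$ref_count, s0$alt_count),
      pseudo_count_freq(s1$ref_count, s1$alt_count),
      60, 1250, 1250, r0, rt
    )$ne
  }
  for (ne_true in c(100, 200, 500)) {
    est <- vapply(1:50, function(i) recover_once(ne_true, ne_true * 101 + i),
                  numeric(1))
    expect_lt(abs(stats::median(est) - ne_true) / ne_true, 0.15)
  }
})

test_that("estimate_s inverts the deterministic recursion", {
  flat <- estimate_s(rep(0.4, 3), c(0, 10, 20))
  expect_equal(flat$s, 0)
  # the logit of the additive recursion is linear with slope log(1 + s/2)
  # only to first order in s: recovery is essentially exact for weak and
  # moderate selection and degrades to a known ~10% downward bias by
  # s = 0.3 (the per-generation logit increment declines as p rises)
  for (s_true in c(0.02, 0.1)) {
    for (p0 in c(0.1, 0.5)) {
      tr <- erpool:::wf_traj(p0, Inf, 40, s = s_true)[1, ]
      gens <- 0:40
      keep <- tr > 0.02 & tr < 0.98
      est <- estimate_s(tr[keep], gens[keep])
      expect_lt(abs(est$s - s_true) / s_true, 0.05)
    }
  }
  for (p0 in c(0.1, 0.5)) {
    tr <- erpool:::wf_traj(p0, Inf, 40, s = 0.3)[1, ]
    keep <- tr > 0.02 & tr < 0.98
    est <- estimate_s(tr[keep], (0:40)[keep])
    expect_lt(abs(est$s - 0.3) / 0.3, 0.12)
    expect_lt(est$s, 0.3)   # the bias is downward, never inflating s
  }
})

test_that("estimate_s guards its domain", {
  expect_error(estimate_s(c(0.5, 0.9), c(0, 10), h = 0.3), "h = 0.5")
  expect_error(estimate_s(c(0, 0.5), c(0, 10)), "inside")
  expect_error(estimate_s(0.5, 0), "two time points")
  bnd <- estimate_s(c(0.5 / 101, 0.9), c(0, 20))
  expect_equal(bnd$flag, "boundary")
})

test_that("table-level s estimation matches the scalar path", {
  sim <- small_experiment(n = 30, seed = 14, s = 0.2, n_sel = 10)
  tbl <- estimate_s_table(sim$counts, sim$samples)
  cx <- sim$counts[sim$counts$pos == 1, ]
  p <- pseudo_count_freq(
    cx$ref_count[cx$sample_id %in% c("x_F0", "x_F60")],
    cx$alt_count[cx$sample_id %in% c("x_F0", "x_F60")]
  )
  direct <- estimate_s(p, c(0, 60))
  expect_equal(tbl$s[tbl$pos == 1 & tbl$replicate == "x"], direct$s)
  # selected SNPs should look selected in at least one replicate
  sel_s <- dplyr::summarise(dplyr::group_by(dplyr::filter(tbl, pos <= 10),
                                            pos), mx = max(s))
  expect_true(all(sel_s$mx > 0))
})
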