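test_that("fixation and loss are absorbing; deterministic neutrality is constant", {
  tr <- erpool:::wf_traj(c(0, 1), ne = 100, t = 25, s = 0.5)
  expect_true(all(tr[1, ] == 0))
  expect_true(all(tr[2, ] == 1))
  det <- erpool:::wf_traj(0.37, ne = Inf, t = 50, s = 0)
  expect_true(all(det == 0.37))
})

test_that("neutral drift is mean-preserving and matches the closed-form variance", {
  for (case in list(c(50, 10), c(50, 60), c(200, 10), c(200, 60),
                    c(1000, 60))) {
    ne <- case[1]; t <- case[2]
    set.seed(ne + t)
    p0 <- 0.5
    pt <- erpool:::wf_drift_final(rep(p0, 10000), ne, t)
    v_theory <- p0 * (1 - p0) * (1 - (1 - 1 / (2 * ne))^t)
    # mean preservation within 3 standard errors
    expect_lt(abs(mean(pt) - p0), 3 * sd(pt) / sqrt(10000))
    # variance within Monte-Carlo error (chi-square-based ~5 sd of var)
    expect_lt(abs(var(pt) - v_theory), 5 * v_theory * sqrt(2 / 9999))
  }
})

test_that("deterministic selection response is strictly increasing in s", {
  svals <- c(0, 0.02, 0.1, 0.26, 0.5)
  p30 <- sapply(svals, function(s) {
    erpool:::wf_traj(0.52, Inf, 30, s = s)[, 31]
  })
  expect_true(all(diff(p30) > 0))
  # strong-selection regime: 0.52 rises past 0.95 within 30 generations
  expect_gte(p30[svals == 0.26], 0.95)
})

test_that("pool sequencing has the two-stage binomial variance", {
  set.seed(21)
  p <- 0.3; n_pool <- 50; R <- 100
  cells <- pool_sequence(rep(p, 20000), n_pool, R)
  freq <- cells$alt_count / cells$coverage
  v_theory <- p * (1 - p) * (1 / (2 * n_pool) + (1 - 1 / (2 * n_pool)) / R)
  expect_lt(abs(mean(freq) - p), 0.005)
  expect_lt(abs(var(freq) - v_theory), 0.1 * v_theory)
  # degenerate cases
  ones <- pool_sequence(rep(1, 5), 10, 30)
  expect_true(all(ones$alt_count == 30))
  zero_cov <- pool_sequence(0.5, 10, 0)
  expect_true(zero_cov$missing)
})

test_that("dilution is the weighted frequency average", {
  expect_equal(dilute(0.9, 0.3, 1), 0.9)
  expect_equal(dilute(0.9, 0.3, 0.3), 0.48)  # 30:70 evolved:ancestral mix
  expect_equal(dilute(c(0.5, 0.8), c(0.5, 0.2), 0), c(0.5, 0.2))
})

test_that("simulate_experiment is seed-deterministic with correct dimensions", {
  des <- experiment_design(n_variants = 10, generations = c(0, 70), seed = 4)
  a <- simulate_experiment(des)
  b <- simulate_experiment(des)
  expect_identical(a$counts, b$counts)
  expect_identical(a$trajectories, b$trajectories)
  expect_equal(nrow(a$counts), 10 * 6)   # 10 variants x (3 reps x 2 tps)
  expect_equal(nrow(a$samples), 6)
})

test_that("an all-neutral design has near-zero mean frequency change", {
  des <- experiment_design(
    n_variants = 1000, generations = c(0, 60),
    replicates = tibble::tibble(replicate = "x", ne = 200), seed = 9
  )
  sim <- simulate_experiment(des)
  afc <- compute_afc(sim$counts, sim$samples)
  expect_lt(abs(mean(afc$afc, na.rm = TRUE)), 0.01)
})

test_that("secondary phase starts from the diluted frequencies", {
  sim <- small_experiment(
    n = 150, seed = 13,
    dilution = list(source = "x", m = 0.3, n_replicates = 2)
  )
  expect_true(any(sim$samples$phase == "secondary"))
  expect_setequal(unique(sim$samples$replicate),
                  c("x", "y", "z", "x.1", "x.2"))
  d0 <- sim$trajectories[sim$trajectories$replicate == "x.1" &
                           sim$trajectories$generation == 0, ]
  ev <- sim$trajectories[sim$trajectories$replicate == "x" &
                           sim$trajectories$generation == 60, ]
  expect_equal(d0$p, dilute(ev$p, sim$truth$p0, 0.3))
})

test_that("a YAML config reproduces the in-code design", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_variants: 50",
    "generations: [0, 70]",
    "coverage_mean: 90",
    "s: 0.2",
    "selected: [1, 2, 3]",
    "seed: 12",
    "replicates:",
    "  - {replicate: x, ne: 206}",
    "  - {replicate: z, ne: 226}",
    "dilution: {source: x, m: 0.3, n_replicates: 2}"
  ), f)
  des <- read_experiment_design(f)
  ref <- experiment_design(
    n_variants = 50, generations = c(0, 70), coverage_mean = 90, s = 0.2,
    selected = 1:3, seed = 12,
    replicates = tibble::tibble(replicate = c("x", "z"), ne = c(206, 226)),
    dilution = list(source = "x", m = 0.3, n_replicates = 2)
  )
  expect_equal(des$replicates, ref$replicates)
  expect_equal(des$dilution, ref$dilution)
  expect_identical(simulate_experiment(des)$counts,
                   simulate_experiment(ref)$counts)
})

test_that("dilution with an unknown source replicate is a config error", {
  expect_error(
    experiment_design(dilution = list(source = "q", m = 0.3)),
    "source replicate"
  )
})

test_that("matched neutral sets mirror shape and coverage of the observed table", {
  sim <- small_experiment(n = 120, seed = 6, s = 0)
  nulls <- simulate_neutral_matched(
    sim$counts, sim$samples, c(x = 200, y = 200, z = 200),
    n_sets = 3, seed = 2
  )
  expect_length(nulls, 3)
  for (nc in nulls) {
    expect_equal(nrow(nc), nrow(sim$counts))
    merged <- dplyr::inner_join(
      nc, sim$counts, by = c("chrom", "pos", "sample_id"),
      suffix = c("_null", "_obs")
    )
    expect_equal(merged$coverage_null, merged$coverage_obs)
  }
  # neutral expectation: mean AFC across sets near zero
  afcs <- sapply(nulls, function(nc) {
    mean(compute_afc(nc, sim$samples)$afc, na.rm = TRUE)
  })
  expect_lt(abs(mean(afcs)), 0.02)
})

test_that("infinite Ne leaves the matched null at its starting frequency", {
  sim <- small_experiment(n = 400, seed = 10, s = 0, coverage_mean = 2000)
  nulls <- simulate_neutral_matched(
    sim$counts, sim$samples, c(x = Inf, y = Inf, z = Inf),
    n_sets = 1, seed = 5
  )
  afc <- compute_afc(nulls[[1]], sim$samples)
  # only two-stage sampling noise remains at 2000x coverage
  expect_lt(sd(afc$afc, na.rm = TRUE), 0.03)
  expect_lt(abs(mean(afc$afc, na.rm = TRUE)), 0.005)
})

test_that("a replicate without an Ne estimate is rejected", {
  sim <- small_experiment(n = 20, seed = 2, s = 0)
  expect_error(
    simulate_neutral_matched(sim$counts, sim$samples, c(x = 200, y = 200)),
    "z"
  )
})
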