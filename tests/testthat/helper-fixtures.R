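# shared fixtures, built in code at test time

two_sample_sheet <- function(ids = c("s1", "s2"), replicate = "x",
                             generations = c(0, 60), pool_size = 1250L) {
  tibble::tibble(
    sample_id = ids, replicate = replicate,
    timepoint = paste0("F", generations), generation = generations,
    phase = "primary", pool_size = pool_size
  )
}

# minimal long count tibble from per-sample (ref, alt) matrices
make_counts <- function(ref_mat, alt_mat, sample_ids,
                        chrom = "2L", ref = "A", alt = "T") {
  nv <- nrow(ref_mat)
  purrr::map_dfr(seq_along(sample_ids), function(j) {
    tibble::tibble(
      chrom = chrom, pos = seq_len(nv), ref = ref, alt = alt,
      sample_id = sample_ids[j],
      ref_count = as.integer(ref_mat[, j]),
      alt_count = as.integer(alt_mat[, j]),
      coverage = as.integer(ref_mat[, j] + alt_mat[, j])
    )
  })
}

# a small simulated experiment reused across files
small_experiment <- function(n = 200, seed = 11, s = 0.12, n_sel = 15,
                             ne = 200, generations = c(0, 60),
                             coverage_mean = 80, dilution = NULL) {
  des <- experiment_design(
    n_variants = n,
    replicates = tibble::tibble(replicate = c("x", "y", "z"), ne = ne),
    generations = generations, coverage_mean = coverage_mean,
    s = s, selected = seq_len(n_sel), dilution = dilution, seed = seed
  )
  simulate_experiment(des)
}

# independent two-sided FET oracle: explicit choose()-based enumeration
fet_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  pobs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}
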