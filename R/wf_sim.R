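#' Forward Wright-Fisher allele-frequency trajectories
#'
#' Simulates diploid Wright-Fisher dynamics with additive-dominance selection
#' (fitnesses `w11 = 1 + s`, `w12 = 1 + h*s`, `w22 = 1`). Each generation the
#' deterministic selection update is applied and, for finite `ne`, `2*ne`
#' gametes are drawn binomially. Frequencies 0 and 1 are absorbing.
#'
#' @param p0 Numeric vector of starting frequencies in \[0, 1\] (one per
#'   locus; loci are unlinked and drift independently).
#' @param ne Effective population size (diploids) governing drift; `Inf`
#'   gives the deterministic trajectory.
#' @param t Number of generations to simulate.
#' @param s Selection coefficient(s), recycled over loci; `s = 0` is neutral
#'   drift.
#' @param h Dominance coefficient in \[0, 1\]; 0.5 is additive.
#' @return A tibble with columns `locus`, `generation` (0..t) and `p`.
#' @seealso [pool_sequence()], [simulate_experiment()]
#' @export
#' @examples
#' set.seed(1)
#' simulate_trajectory(0.5, ne = 200, t = 10)
simulate_trajectory <- function(p0, ne, t, s = 0, h = 0.5) {
  m <- wf_traj(p0, ne, t, s, h)
  tibble(
    locus = rep(seq_along(p0), times = t + 1),
    generation = rep(0:t, each = length(p0)),
    p = as.vector(m)
  )
}

# matrix engine: rows = loci, cols = generations 0..t
wf_traj <- function(p0, ne, t, s = 0, h = 0.5) {
  assert_prob(p0, "p0")
  if (any(s <= -1)) abort("`s` must be > -1")
  if (h < 0 || h > 1) abort("`h` must be in [0, 1]")
  if (!(is.infinite(ne) || (ne >= 1))) abort("`ne` must be >= 1 or Inf")
  n <- length(p0)
  s <- rep_len(s, n)
  out <- matrix(NA_real_, nrow = n, ncol = t + 1)
  p <- p0
  out[, 1] <- p
  if (t == 0) return(out)
  w11 <- 1 + s
  w12 <- 1 + h * s
  gametes <- if (is.finite(ne)) max(1L, round(2 * ne)) else Inf
  for (g in seq_len(t)) {
    q <- 1 - p
    wbar <- p^2 * w11 + 2 * p * q * w12 + q^2
    p <- p * (p * w11 + q * w12) / wbar
    if (is.finite(ne)) {
      p <- stats::rbinom(n, gametes, p) / gametes
    }
    out[, g + 1] <- p
  }
  out
}

# final-generation frequencies only (no trajectory storage)
wf_drift_final <- function(p0, ne, t, s = 0, h = 0.5) {
  if (t == 0) return(p0)
  wf_traj(p0, ne, t, s, h)[, t + 1]
}

#' Two-stage Pool-Seq sampling of read counts
#'
#' Emulates pooled sequencing: `2 * pool_size` chromosomes are sampled
#' binomially at the true frequency `p` to form the pool frequency, then
#' `coverage` reads are drawn binomially at the pool frequency. A coverage of
#' 0 yields a missing cell (`NA` counts).
#'
#' @param p True population allele frequency (vector).
#' @param pool_size Number of diploid individuals in the pool (recycled).
#' @param coverage Read depth per locus (recycled).
#' @return A tibble with columns `ref_count`, `alt_count`, `coverage` and
#'   logical `missing`.
#' @export
pool_sequence <- function(p, pool_size, coverage) {
  assert_prob(p[!is.na(p)], "p")  # NA marks an upstream missing cell
  n <- length(p)
  pool_size <- rep_len(pool_size, n)
  coverage <- rep_len(coverage, n)
  if (any(pool_size < 1)) abort("`pool_size` must be >= 1")
  if (any(coverage < 0)) abort("`coverage` must be >= 0")
  p_in <- ifelse(is.na(p), 0, p)
  p_pool <- stats::rbinom(n, 2 * pool_size, p_in) / (2 * pool_size)
  alt <- stats::rbinom(n, coverage, p_pool)
  ref <- coverage - alt
  miss <- coverage == 0 | is.na(p)
  alt[is.na(p)] <- NA_integer_
  ref[is.na(p)] <- NA_integer_
  tibble(ref_count = as.integer(ref), alt_count = as.integer(alt),
         coverage = as.integer(coverage), missing = miss)
}

#' Deterministic dilution of an evolved population with ancestral genotypes
#'
#' Mixing `m` evolved with `1 - m` ancestral individuals moves each allele
#' frequency to the weighted average, the deterministic model behind dilution
#' designs (e.g. a 30:70 evolved:ancestral mix is `m = 0.3`).
#'
#' @param p_evolved,p_ancestral Allele frequencies in \[0, 1\].
#' @param m Proportion of evolved individuals in the mixture, in \[0, 1\].
#' @return `m * p_evolved + (1 - m) * p_ancestral`.
#' @export
dilute <- function(p_evolved, p_ancestral, m) {
  assert_prob(p_evolved, "p_evolved")
  assert_prob(p_ancestral, "p_ancestral")
  assert_prob(m, "m")
  m * p_evolved + (1 - m) * p_ancestral
}

#' Specify a replicated evolve-and-resequence experiment
#'
#' Bundles everything the simulator needs: replicate structure with
#' per-replicate effective sizes, census and pool sizes, sampling
#' generations, founder-frequency model, a coverage model, the selection
#' specification, and an optional secondary (dilution) phase.
#'
#' Defaults mirror a replicated fly experiment founded from 426 isofemale
#' lines: three replicates at census 1,250 with whole-population pools,
#' founder frequencies on the grid k/852 (twice the line count, fixation
#' classes excluded), and Poisson-distributed read depth around a per-sample
#' mean.
#'
#' @param n_variants Number of unlinked SNPs to simulate.
#' @param replicates Tibble with columns `replicate`, `ne` and optionally
#'   `census` (default 1250) and `pool_size` (default census).
#' @param generations Primary-phase sampling generations (must include 0).
#' @param founder_freq Founder allele-frequency model: a function of `n`, a
#'   numeric vector of length `n_variants`, or `NULL` for the default grid.
#' @param coverage_mean Mean read depth per sample: a scalar, or a named
#'   vector keyed by sample id.
#' @param coverage_model `"poisson"` (cell-level Poisson variation, default)
#'   or `"fixed"`.
#' @param s Selection coefficient applied to `selected` variants.
#' @param h Dominance coefficient (0.5 = additive).
#' @param selected Integer indices of selected variants (may be empty).
#' @param dilution `NULL`, or a list with elements `source` (replicate id),
#'   `m` (proportion evolved), `n_replicates`, `generations` (default
#'   `c(0, 30)`), optional `at_generation` (primary generation providing the
#'   evolved flies; default the last primary generation) and optional `ne`
#'   (per secondary replicate; default the source replicate's).
#' @param block_size Variants per linked block sharing one trajectory
#'   (1 = fully unlinked, the default).
#' @param seed Integer root seed; all stage- and replicate-level streams are
#'   derived from it deterministically.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_variants = 1000,
                              replicates = tibble(
                                replicate = c("x", "y", "z"),
                                ne = c(206, 263, 226)
                              ),
                              generations = c(0, 70),
                              founder_freq = NULL,
                              coverage_mean = 80,
                              coverage_model = c("poisson", "fixed"),
                              s = 0,
                              h = 0.5,
                              selected = integer(0),
                              dilution = NULL,
                              block_size = 1,
                              seed = 1L) {
  coverage_model <- match.arg(coverage_model)
  replicates <- as_tibble(replicates)
  if (!"census" %in% names(replicates)) replicates$census <- 1250
  if (!"pool_size" %in% names(replicates)) {
    replicates$pool_size <- replicates$census
  }
  if (any(replicates$ne <= 0) || any(replicates$ne > replicates$census)) {
    abort("need 0 < ne <= census for every replicate")
  }
  if (!0 %in% generations) abort("`generations` must include 0")
  if (s <= -1) abort("`s` must be > -1")
  if (length(selected) > 0 &&
      (min(selected) < 1 || max(selected) > n_variants)) {
    abort("`selected` indices out of range")
  }
  if (!is.null(dilution)) {
    if (is.null(dilution$source) ||
        !dilution$source %in% replicates$replicate) {
      abort("dilution source replicate absent from `replicates`")
    }
    if (is.null(dilution$m) || dilution$m < 0 || dilution$m > 1) {
      abort("dilution mixing proportion `m` must be in [0, 1]")
    }
    dilution$n_replicates <- dilution$n_replicates %||% 2L
    dilution$generations <- dilution$generations %||% c(0, 30)
    dilution$at_generation <- dilution$at_generation %||% max(generations)
    src_ne <- replicates$ne[replicates$replicate == dilution$source]
    dilution$ne <- rep_len(dilution$ne %||% src_ne, dilution$n_replicates)
  }
  structure(
    list(
      n_variants = n_variants, replicates = replicates,
      generations = sort(unique(generations)), founder_freq = founder_freq,
      coverage_mean = coverage_mean, coverage_model = coverage_model,
      s = s, h = h, selected = as.integer(selected), dilution = dilution,
      block_size = as.integer(block_size), seed = as.integer(seed)
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>\n")
  cat(sprintf("  %d variants (%d selected, s = %g, h = %g), %d replicate(s)\n",
              x$n_variants, length(x$selected), x$s, x$h, nrow(x$replicates)))
  cat(sprintf("  primary generations: %s\n",
              paste(x$generations, collapse = ", ")))
  if (!is.null(x$dilution)) {
    cat(sprintf("  secondary: %d replicate(s) from %s, m = %g, generations %s\n",
                x$dilution$n_replicates, x$dilution$source, x$dilution$m,
                paste(x$dilution$generations, collapse = ", ")))
  }
  invisible(x)
}

.founder_default <- function(n, n_lines = 426) {
  grid <- seq_len(2 * n_lines - 1) / (2 * n_lines)
  sample(grid, n, replace = TRUE)
}

.sample_coverage <- function(design, sample_id, n) {
  mu <- design$coverage_mean
  if (!is.null(names(mu))) {
    mu <- if (sample_id %in% names(mu)) mu[[sample_id]] else mean(mu)
  }
  if (design$coverage_model == "fixed") rep.int(as.integer(round(mu)), n)
  else stats::rpois(n, mu)
}

#' Simulate a full (optionally two-stage) E&R experiment
#'
#' Draws founder frequencies, evolves each replicate forward under the
#' design's selection specification, pool-sequences every sampling time
#' point, and, if a dilution phase is specified, mixes the evolved source
#' replicate with the reconstituted founder frequencies at proportion `m`
#' and evolves the secondary replicates. Output is fully reproducible from
#' the design's seed.
#'
#' @param design An [experiment_design()].
#' @return An object of class `er_experiment`: a list with `counts` (long
#'   count tibble), `samples` (sample sheet), `truth` (per-variant tibble
#'   with `selected` and `s`), `trajectories` (true allele frequencies at
#'   the sampled generations) and `design`.
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  n <- design$n_variants
  set.seed(derive_seed(design$seed, "founder"))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  p0 <- if (is.function(design$founder_freq)) design$founder_freq(n)
        else if (is.numeric(design$founder_freq)) {
          rep_len(design$founder_freq, n)
        } else .founder_default(n)
  assert_prob(p0, "founder frequencies")
  if (any(p0 <= 0 | p0 >= 1)) abort("founder frequencies must be in (0, 1)")
  s_vec <- rep(0, n)
  s_vec[design$selected] <- design$s
  truth <- tibble(
    chrom = "sim", pos = seq_len(n), ref = ref, alt = alt, p0 = p0,
    selected = seq_len(n) %in% design$selected, s = s_vec
  )
  gens <- design$generations
  t_max <- max(gens)
  blocks <- if (design$block_size > 1) {
    rep(seq_len(ceiling(n / design$block_size)),
        each = design$block_size)[seq_len(n)]
  } else seq_len(n)
  block_first <- !duplicated(blocks)

  counts <- list(); samples <- list(); trajectories <- list()
  evolved_final <- list()
  for (r in seq_len(nrow(design$replicates))) {
    rep_id <- design$replicates$replicate[r]
    set.seed(derive_seed(design$seed, "traj", rep_id))
    traj_b <- wf_traj(p0[block_first], design$replicates$ne[r], t_max,
                      s_vec[block_first], design$h)
    traj <- traj_b[match(blocks, blocks[block_first]), , drop = FALSE]
    evolved_final[[rep_id]] <- traj[, t_max + 1]
    for (g in gens) {
      sid <- sprintf("%s_F%d", rep_id, g)
      set.seed(derive_seed(design$seed, "seq", rep_id, g))
      cov <- .sample_coverage(design, sid, n)
      cells <- pool_sequence(traj[, g + 1], design$replicates$pool_size[r],
                             cov)
      counts[[sid]] <- tibble(
        chrom = "sim", pos = seq_len(n), ref = ref, alt = alt,
        sample_id = sid, ref_count = cells$ref_count,
        alt_count = cells$alt_count, coverage = cells$coverage
      )
      samples[[sid]] <- tibble(
        sample_id = sid, replicate = rep_id, timepoint = sprintf("F%d", g),
        generation = g, phase = "primary",
        pool_size = design$replicates$pool_size[r]
      )
      trajectories[[sid]] <- tibble(
        chrom = "sim", pos = seq_len(n), replicate = rep_id,
        phase = "primary", generation = g, p = traj[, g + 1]
      )
    }
  }

  dil <- design$dilution
  if (!is.null(dil)) {
    src <- dil$source
    src_row <- design$replicates[design$replicates$replicate == src, ]
    p_evolved <- evolved_final[[src]]
    p_d0 <- dilute(p_evolved, p0, dil$m)
    t2_max <- max(dil$generations)
    for (j in seq_len(dil$n_replicates)) {
      rep_id <- sprintf("%s.%d", src, j)
      set.seed(derive_seed(design$seed, "traj2", rep_id))
      traj_b <- wf_traj(p_d0[block_first], dil$ne[j], t2_max,
                        s_vec[block_first], design$h)
      traj <- traj_b[match(blocks, blocks[block_first]), , drop = FALSE]
      for (g in dil$generations) {
        sid <- sprintf("%s_D%d", rep_id, g)
        set.seed(derive_seed(design$seed, "seq2", rep_id, g))
        cov <- .sample_coverage(design, sid, n)
        cells <- pool_sequence(traj[, g + 1], src_row$pool_size, cov)
        counts[[sid]] <- tibble(
          chrom = "sim", pos = seq_len(n), ref = ref, alt = alt,
          sample_id = sid, ref_count = cells$ref_count,
          alt_count = cells$alt_count, coverage = cells$coverage
        )
        samples[[sid]] <- tibble(
          sample_id = sid, replicate = rep_id,
          timepoint = sprintf("D%d", g), generation = g, phase = "secondary",
          pool_size = src_row$pool_size
        )
        trajectories[[sid]] <- tibble(
          chrom = "sim", pos = seq_len(n), replicate = rep_id,
          phase = "secondary", generation = g, p = traj[, g + 1]
        )
      }
    }
  }

  structure(
    list(
      counts = dplyr::bind_rows(counts),
      samples = dplyr::bind_rows(samples),
      truth = truth,
      trajectories = dplyr::bind_rows(trajectories),
      design = design
    ),
    class = "er_experiment"
  )
}

#' Read an experiment design from a YAML configuration file
#'
#' The file mirrors [experiment_design()]'s arguments: top-level scalars
#' (`n_variants`, `generations`, `coverage_mean`, `coverage_model`, `s`,
#' `h`, `selected`, `block_size`, `seed`), a `replicates` list of records
#' with `replicate`, `ne` and optional `census`/`pool_size`, and an optional
#' `dilution` section.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_design` object.
#' @export
read_experiment_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg),
                        c("n_variants", "generations", "coverage_mean",
                          "coverage_model", "s", "h", "selected",
                          "block_size", "seed", "founder_freq", "dilution"))]
  if (!is.null(cfg$replicates)) {
    args$replicates <- dplyr::bind_rows(cfg$replicates)
  }
  if (!is.null(args$selected)) args$selected <- unlist(args$selected)
  if (!is.null(args$generations)) args$generations <- unlist(args$generations)
  do.call(experiment_design, args)
}

#' @export
print.er_experiment <- function(x, ...) {
  cat("<er_experiment>\n")
  cat(sprintf("  %d variants x %d samples (%d selected)\n",
              x$design$n_variants, nrow(x$samples), sum(x$truth$selected)))
  invisible(x)
}

#' Neutral simulations matched to an observed count table
#'
#' For each simulated set and each variant: the observed starting-time
#' frequency (pseudo-count stabilised) seeds a neutral Wright-Fisher
#' trajectory at the replicate's effective size; the starting-time counts
#' are resampled at the observed starting coverage (so sequencing noise
#' enters the null at both ends) and the final time point is pool-sequenced
#' at the observed final coverage. The output tables are shape- and
#' coverage-matched to the observed table, which makes them a valid null for
#' the empirical-FDR estimator.
#'
#' @param counts Observed long count tibble.
#' @param samples Sample sheet covering `counts`.
#' @param ne Named numeric vector (or tibble with columns `replicate`, `ne`)
#'   of per-replicate effective sizes; every replicate in `samples` must be
#'   covered. `Inf` disables drift.
#' @param n_sets Number of neutral sets M.
#' @param from_tp,to_tp Timepoint labels; default first and last generation
#'   per replicate.
#' @param seed Optional integer seed for reproducible null sets.
#' @return A list of `n_sets` count tibbles.
#' @export
simulate_neutral_matched <- function(counts, samples, ne, n_sets = 10,
                                     from_tp = NULL, to_tp = NULL,
                                     seed = NULL) {
  assert_count_tbl(counts)
  assert_sample_sheet(samples)
  if (is.data.frame(ne)) ne <- stats::setNames(ne$ne, ne$replicate)
  reps <- unique(samples$replicate)
  if (!all(reps %in% names(ne))) {
    abort(sprintf("no Ne estimate for replicate(s): %s",
                  paste(setdiff(reps, names(ne)), collapse = ", ")))
  }
  ends <- .endpoint_samples(samples, from_tp, to_tp)
  t0_ids <- ends$from$sample_id
  if (length(t0_ids) == 0) abort("no starting-time sample per replicate")
  out <- vector("list", n_sets)
  for (set in seq_len(n_sets)) {
    set_counts <- vector("list", length(reps) * 2)
    k <- 0
    for (r in reps) {
      s_from <- ends$from[ends$from$replicate == r, ]
      s_to <- ends$to[ends$to$replicate == r, ]
      if (nrow(s_from) != 1 || nrow(s_to) != 1) {
        abort(sprintf("replicate %s lacks a start or end sample", r))
      }
      obs0 <- counts[counts$sample_id == s_from$sample_id, ]
      obs1 <- counts[counts$sample_id == s_to$sample_id, ]
      obs1 <- obs1[match(paste(obs0$chrom, obs0$pos),
                         paste(obs1$chrom, obs1$pos)), ]
      t_gen <- s_to$generation - s_from$generation
      if (!is.null(seed)) set.seed(derive_seed(seed, "null", set, r))
      p0_hat <- pseudo_count_freq(obs0$ref_count, obs0$alt_count)
      cells0 <- pool_sequence(p0_hat, s_from$pool_size, obs0$coverage)
      p_final <- wf_drift_final(ifelse(is.na(p0_hat), 0, p0_hat),
                                ne[[r]], t_gen)
      p_final[is.na(p0_hat)] <- NA_real_
      cells1 <- pool_sequence(p_final, s_to$pool_size, obs1$coverage)
      k <- k + 1
      set_counts[[k]] <- tibble(
        chrom = obs0$chrom, pos = obs0$pos, ref = obs0$ref, alt = obs0$alt,
        sample_id = s_from$sample_id, ref_count = cells0$ref_count,
        alt_count = cells0$alt_count, coverage = cells0$coverage
      )
      k <- k + 1
      set_counts[[k]] <- tibble(
        chrom = obs0$chrom, pos = obs0$pos, ref = obs0$ref, alt = obs0$alt,
        sample_id = s_to$sample_id, ref_count = cells1$ref_count,
        alt_count = cells1$alt_count, coverage = cells1$coverage
      )
    }
    out[[set]] <- dplyr::bind_rows(set_counts[seq_len(k)])
  }
  out
}

# per-replicate start/end samples, by timepoint label or generation extremes
.endpoint_samples <- function(samples, from_tp = NULL, to_tp = NULL) {
  pick <- function(tp, which_end) {
    if (!is.null(tp)) {
      sel <- samples[samples$timepoint == tp, ]
      if (nrow(sel) == 0) abort(sprintf("timepoint '%s' absent", tp))
      return(sel)
    }
    samples %>%
      dplyr::group_by(.data$replicate) %>%
      dplyr::filter(.data$generation == if (which_end == "from")
        min(.data$generation) else max(.data$generation)) %>%
      dplyr::slice(1) %>%
      dplyr::ungroup()
  }
  list(from = pick(from_tp, "from"), to = pick(to_tp, "to"))
}
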