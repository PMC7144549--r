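# run tests on one count table; returns named list of TestResult tibbles
.run_tests <- function(counts, samples, replicates, from_tp, to_tp) {
  out <- list()
  if (length(replicates) > 1) {
    out[[paste0("CMH_", paste(replicates, collapse = ","))]] <-
      test_selection(counts, samples, "cmh", replicates, from_tp, to_tp)
  }
  for (r in replicates) {
    out[[paste0("FET_", r)]] <-
      test_selection(counts, samples, "fet", r, from_tp, to_tp)
  }
  out
}

# weight observed p values (cross-fitted) and null p values (consensus or
# relearned), then estimate the empirical-FDR curve for one test
.weighted_efdr <- function(obs, null_results, weight_alpha, n_bins, n_folds,
                           reweight_null) {
  wt <- weight_pvalues(obs$p_raw, obs$covariate, alpha = weight_alpha,
                       n_bins = n_bins, n_folds = n_folds)
  wf <- attr(wt, "weights")
  p_null <- lapply(null_results, function(nr) {
    if (reweight_null) {
      weight_pvalues(nr$p_raw, nr$covariate, alpha = weight_alpha,
                     n_bins = n_bins, n_folds = n_folds)$p_weighted
    } else {
      # null tables are item-matched to the observed table, so each null
      # item inherits the fold of its observed twin: the null then passes
      # through *exactly* the weighting the observed data received
      folds <- if (is.null(wf$fold_weights) ||
                     length(wf$folds) != length(nr$p_raw)) NULL
               else wf$folds
      as.numeric(apply_weights(nr$p_raw, wf, nr$covariate, folds = folds))
    }
  })
  curve <- efdr_q_values(wt$p_weighted, p_null)
  list(weights = wf, p_weighted = wt$p_weighted, curve = curve)
}

#' Run the primary genome-scan workflow
#'
#' End-to-end primary analysis: optional SNP-catalog filtering, temporal Ne
#' estimation per replicate, CMH across replicates and FET within each
#' replicate, coverage-covariate p-value weighting, matched neutral
#' simulation at the estimated Ne values, empirical-FDR q values, candidate
#' declaration at each requested FDR level, and selection-coefficient
#' estimates for the declared candidates.
#'
#' @param counts Long count tibble (see [read_sync()] or
#'   [simulate_experiment()]).
#' @param samples Sample sheet; only `phase == "primary"` rows are used if a
#'   phase column distinguishes phases.
#' @param ne Optional per-replicate Ne (named vector or tibble); estimated
#'   from the data when `NULL`.
#' @param alphas FDR levels to declare candidates at (default 1% and 5%).
#' @param n_null_sets Number M of matched neutral simulation sets.
#' @param weight_alpha,n_bins,n_folds Parameters of [learn_weights()].
#' @param reweight_null Relearn weights on every neutral set instead of
#'   sharing the observed-data weights (default FALSE).
#' @param mask,coverage_quantile Optional [filter_snps()] inputs; filtering
#'   is skipped when both are `NULL`.
#' @param from_tp,to_tp Optional timepoint labels (default per-replicate
#'   first/last generation).
#' @param seed Integer seed driving fold assignment and neutral simulation.
#' @return An object of class `er_scan`: `results` (per test x variant
#'   tibble with `p_raw`, `p_weighted`, `q`), `candidates` (per test x
#'   alpha), `ne`, `s` (per-SNP estimates for candidates), `afc`, `weights`,
#'   `curves`, and a `manifest` recording all parameters.
#' @export
run_primary <- function(counts, samples, ne = NULL,
                        alphas = c(0.01, 0.05), n_null_sets = 10,
                        weight_alpha = 0.05, n_bins = 5, n_folds = 5,
                        reweight_null = FALSE, mask = NULL,
                        coverage_quantile = NULL, from_tp = NULL,
                        to_tp = NULL, seed = 1L) {
  assert_count_tbl(counts)
  assert_sample_sheet(samples)
  seed <- as.integer(seed)
  if ("phase" %in% names(samples) && any(samples$phase == "primary")) {
    samples <- samples[samples$phase == "primary", ]
  }
  counts <- counts[counts$sample_id %in% samples$sample_id, ]
  filter_rep <- NULL
  if (!is.null(mask) || !is.null(coverage_quantile)) {
    counts <- filter_snps(counts, mask = mask,
                          coverage_quantile = coverage_quantile %||% 0.99)
    filter_rep <- filter_report(counts)
  }
  reps <- unique(samples$replicate)
  ne_tbl <- if (is.null(ne)) {
    estimate_ne_table(counts, samples, from_tp, to_tp)
  } else if (is.data.frame(ne)) {
    ne
  } else {
    tibble(replicate = names(ne), ne = unname(ne))
  }
  if (!"ne" %in% names(ne_tbl)) {
    ne_tbl <- dplyr::rename(ne_tbl, ne = "value")
  }
  ne_vec <- stats::setNames(ne_tbl$ne, ne_tbl$replicate)

  obs_tests <- .run_tests(counts, samples, reps, from_tp, to_tp)
  null_counts <- simulate_neutral_matched(
    counts, samples, ne_vec, n_sets = n_null_sets,
    from_tp = from_tp, to_tp = to_tp, seed = derive_seed(seed, "null")
  )
  results <- list(); curves <- list(); weights <- list()
  cand_rows <- list()
  for (nm in names(obs_tests)) {
    obs <- obs_tests[[nm]]
    test_reps <- strsplit(sub("^[A-Z]+_", "", nm), ",")[[1]]
    null_results <- lapply(null_counts, function(ncnt) {
      if (startsWith(nm, "CMH")) {
        test_selection(ncnt, samples, "cmh", test_reps, from_tp, to_tp)
      } else {
        test_selection(ncnt, samples, "fet", test_reps, from_tp, to_tp)
      }
    })
    set.seed(derive_seed(seed, "weights", nm))
    we <- .weighted_efdr(obs, null_results, weight_alpha, n_bins, n_folds,
                         reweight_null)
    obs$p_weighted <- we$p_weighted
    obs$q <- we$curve$q
    results[[nm]] <- obs
    curves[[nm]] <- we$curve
    weights[[nm]] <- we$weights
    for (a in alphas) {
      dec <- declare_candidates(we$curve, a)
      if (dec$n_candidates > 0) {
        cand_rows[[paste(nm, a)]] <- obs[dec$candidates, ] %>%
          dplyr::mutate(alpha = a, threshold = dec$threshold)
      }
    }
  }
  candidates <- if (length(cand_rows) > 0) {
    dplyr::bind_rows(cand_rows)
  } else {
    dplyr::mutate(dplyr::bind_rows(results)[0, ],
                  alpha = numeric(0), threshold = numeric(0))
  }
  afc <- compute_afc(counts, samples, from_tp, to_tp)
  s_tbl <- NULL
  if (nrow(candidates) > 0) {
    cand_vars <- dplyr::distinct(candidates, .data$chrom, .data$pos)
    s_tbl <- estimate_s_table(counts, samples, variants = cand_vars)
  }
  structure(
    list(
      results = dplyr::bind_rows(results), candidates = candidates,
      ne = ne_tbl, s = s_tbl, afc = afc, weights = weights, curves = curves,
      filter_report = filter_rep,
      manifest = list(
        n_variants = length(unique(paste(counts$chrom, counts$pos))),
        replicates = reps, alphas = alphas, n_null_sets = n_null_sets,
        weight_alpha = weight_alpha, n_bins = n_bins, n_folds = n_folds,
        reweight_null = reweight_null, seed = seed,
        ne = as.list(ne_vec), timestamp = format(Sys.time())
      )
    ),
    class = "er_scan"
  )
}

#' @export
print.er_scan <- function(x, ...) {
  cat("<er_scan>\n")
  cat(sprintf("  %d variants, tests: %s\n", x$manifest$n_variants,
              paste(names(x$curves), collapse = ", ")))
  if (nrow(x$candidates %||% tibble()) > 0) {
    smry <- dplyr::count(x$candidates, .data$test, .data$alpha)
    for (i in seq_len(nrow(smry))) {
      cat(sprintf("  %s @ %g%% FDR: %d candidate(s)\n",
                  smry$test[i], 100 * smry$alpha[i], smry$n[i]))
    }
  } else {
    cat("  no candidates declared\n")
  }
  invisible(x)
}

#' @export
tidy.er_scan <- function(x, ...) x$results

#' @export
glance.er_scan <- function(x, ...) {
  tibble(
    n_variants = x$manifest$n_variants,
    n_tests = length(x$curves),
    n_candidates = nrow(x$candidates %||% tibble()),
    n_null_sets = x$manifest$n_null_sets,
    seed = x$manifest$seed
  )
}

#' Run the secondary (dilution) validation workflow
#'
#' Re-runs the identical test/weighting/empirical-FDR machinery on the
#' secondary phase (founding D0 versus evolved D30 of the diluted
#' replicates), joins the results with the primary candidates, estimates
#' per-SNP selection coefficients in both phases, and summarises
#' repeatability: paired primary/secondary AFCs of the candidates with
#' probability ellipse and a matched neutral-simulation comparison cloud.
#'
#' @param primary An `er_scan` from [run_primary()].
#' @param counts Long count tibble containing the secondary-phase samples
#'   (and the primary ones for the AFC join).
#' @param samples Full sample sheet (both phases).
#' @param source_replicate Primary replicate that was diluted; default
#'   inferred from secondary replicate ids of the form `"x.1"`.
#' @param candidate_alpha FDR level defining the focal candidate set
#'   (default 0.01); falls back to the least stringent declared level with a
#'   warning when empty.
#' @param n_null_sets M for the secondary empirical FDR.
#' @param seed Integer seed.
#' @inheritParams run_primary
#' @return An object of class `er_validation`: `scan` (the secondary
#'   `er_scan`), `concordance` (a `concordance_report`), `s_by_phase`
#'   (per-SNP s in primary and secondary), and `manifest`.
#' @export
run_secondary <- function(primary, counts, samples, source_replicate = NULL,
                          candidate_alpha = 0.01, alphas = c(0.01, 0.05),
                          n_null_sets = 10, weight_alpha = 0.05, n_bins = 5,
                          n_folds = 5, reweight_null = FALSE, seed = 1L) {
  stopifnot(inherits(primary, "er_scan"))
  assert_count_tbl(counts)
  assert_sample_sheet(samples)
  sec <- samples[samples$phase == "secondary", ]
  if (nrow(sec) == 0) abort("no secondary-phase samples in the sample sheet")
  # every secondary replicate needs both its endpoints sequenced
  per_rep <- dplyr::count(sec, .data$replicate)
  incomplete <- per_rep$replicate[per_rep$n < 2]
  if (length(incomplete) > 0) {
    abort(sprintf(
      "secondary replicate(s) missing a time point: %s",
      paste(incomplete, collapse = ", ")
    ))
  }
  source_replicate <- source_replicate %||%
    unique(sub("\\..*$", "", sec$replicate))
  if (length(source_replicate) != 1) {
    abort("give `source_replicate`: secondary replicates stem from several")
  }
  sec_counts <- counts[counts$sample_id %in% sec$sample_id, ]
  scan2 <- run_primary(
    sec_counts, sec, ne = NULL, alphas = alphas, n_null_sets = n_null_sets,
    weight_alpha = weight_alpha, n_bins = n_bins, n_folds = n_folds,
    reweight_null = reweight_null, seed = derive_seed(seed, "secondary")
  )

  cands <- primary$candidates
  if (is.null(cands) || nrow(cands) == 0) {
    abort("the primary scan declared no candidates to validate")
  }
  focal_cands <- dplyr::distinct(
    cands[cands$alpha == candidate_alpha, ], .data$chrom, .data$pos
  )
  if (nrow(focal_cands) == 0) {
    warn(sprintf("no primary candidate at alpha = %g; using all declared",
                 candidate_alpha))
    focal_cands <- dplyr::distinct(cands, .data$chrom, .data$pos)
  }

  prim_samples <- samples[samples$phase == "primary", ]
  afc_p <- compute_afc(counts[counts$sample_id %in% prim_samples$sample_id, ],
                       prim_samples)
  afc_p <- afc_p[afc_p$replicate == source_replicate, ]
  sec_rep1 <- sort(unique(sec$replicate))[1]
  afc_s <- scan2$afc[scan2$afc$replicate == sec_rep1, ]
  joined <- dplyr::inner_join(
    dplyr::select(afc_p, "chrom", "pos", primary_afc = "afc"),
    dplyr::select(afc_s, "chrom", "pos", secondary_afc = "afc"),
    by = c("chrom", "pos")
  )
  joined <- dplyr::semi_join(joined, focal_cands, by = c("chrom", "pos"))
  if (nrow(joined) == 0) {
    abort("primary candidates do not overlap the secondary count table")
  }

  # one matched neutral realisation of both phases for the comparison cloud
  ne_p <- stats::setNames(primary$ne$ne, primary$ne$replicate)
  null_p <- simulate_neutral_matched(
    counts[counts$sample_id %in%
             prim_samples$sample_id[prim_samples$replicate ==
                                      source_replicate], ],
    prim_samples[prim_samples$replicate == source_replicate, ],
    ne_p[source_replicate], n_sets = 1, seed = derive_seed(seed, "cloud_p")
  )[[1]]
  ne_s <- stats::setNames(scan2$ne$ne, scan2$ne$replicate)
  null_s <- simulate_neutral_matched(
    sec_counts[sec_counts$sample_id %in%
                 sec$sample_id[sec$replicate == sec_rep1], ],
    sec[sec$replicate == sec_rep1, ],
    ne_s[sec_rep1], n_sets = 1, seed = derive_seed(seed, "cloud_s")
  )[[1]]
  nafc_p <- compute_afc(null_p,
                        prim_samples[prim_samples$replicate ==
                                       source_replicate, ])
  nafc_s <- compute_afc(null_s, sec[sec$replicate == sec_rep1, ])
  ncloud <- dplyr::inner_join(
    dplyr::select(nafc_p, "chrom", "pos", primary_afc = "afc"),
    dplyr::select(nafc_s, "chrom", "pos", secondary_afc = "afc"),
    by = c("chrom", "pos")
  )
  ncloud <- dplyr::semi_join(ncloud, focal_cands, by = c("chrom", "pos"))

  conc <- concordance_summary(
    joined$primary_afc, joined$secondary_afc,
    focal = seq_len(nrow(joined)),
    neutral_pairs = ncloud[, c("primary_afc", "secondary_afc")]
  )

  s_prim <- estimate_s_table(
    counts[counts$sample_id %in%
             prim_samples$sample_id[prim_samples$replicate ==
                                      source_replicate], ],
    prim_samples[prim_samples$replicate == source_replicate, ],
    variants = focal_cands
  )
  s_sec <- estimate_s_table(sec_counts, sec, variants = focal_cands)
  s_by_phase <- dplyr::bind_rows(s_prim, s_sec)

  structure(
    list(scan = scan2, concordance = conc, s_by_phase = s_by_phase,
         candidates = focal_cands,
         manifest = list(source_replicate = source_replicate,
                         candidate_alpha = candidate_alpha,
                         n_null_sets = n_null_sets, seed = seed)),
    class = "er_validation"
  )
}

#' @export
print.er_validation <- function(x, ...) {
  cat("<er_validation>\n")
  cat(sprintf("  %d candidate SNP(s) from primary replicate %s\n",
              nrow(x$candidates), x$manifest$source_replicate))
  print(x$concordance)
  invisible(x)
}

#' @export
tidy.er_validation <- function(x, ...) x$s_by_phase

#' @export
glance.er_validation <- function(x, ...) glance(x$concordance)
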