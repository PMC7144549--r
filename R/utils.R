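#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# logit/inverse-logit on (0,1); inputs are pseudo-count stabilised upstream
logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable per-stage seed derivation: keeps every derived seed a valid 32-bit
# integer regardless of the root seed the caller passes
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  codes <- utf8ToInt(key)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647L
  as.integer(h)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1].", name))
  }
  invisible(x)
}

variant_key_cols <- c("chrom", "pos", "ref", "alt")

assert_count_tbl <- function(counts) {
  needed <- c(variant_key_cols, "sample_id", "ref_count", "alt_count")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    abort(sprintf(
      "count table is missing column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(counts)
}

assert_sample_sheet <- function(samples) {
  needed <- c("sample_id", "replicate", "timepoint", "generation", "phase",
              "pool_size")
  missing <- setdiff(needed, names(samples))
  if (length(missing) > 0) {
    abort(sprintf(
      "sample sheet is missing column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(samples$pool_size < 1)) abort("pool_size must be >= 1")
  if (any(samples$generation < 0)) abort("generation must be >= 0")
  invisible(samples)
}
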