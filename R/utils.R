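# Internal helpers shared across modules.

#' Study constants
#'
#' Condition labels, sampling rate and channel bookkeeping used throughout the
#' package. The default acquisition rate is 7.81 Hz; the three stimulus
#' conditions are painful posterior-to-anterior pressure (PAPain), nonpainful
#' 30 N pressure (PA30) and tactile brushing (Brush).
#' @name nirspine-constants
#' @keywords internal
NULL

CONDITIONS <- c("PAPain", "PA30", "Brush")
CHROMOPHORES <- c("O2Hb", "HHb")
WAVELENGTHS_NM <- c(760, 850)
FS_DEFAULT <- 7.81

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulation calls do not
#' perturb the caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Column-wise medians of a matrix, vectorised via one radix sort.
# Equivalent to apply(x, 2, median) for complete numeric input.
col_medians <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n == 0L || m == 0L) return(numeric(m))
  o <- order(rep.int(seq_len(m), rep.int(n, m)), x)
  xs <- matrix(x[o], nrow = n, ncol = m)
  if (n %% 2L == 1L) xs[(n + 1L) %/% 2L, ] else (xs[n %/% 2L, ] + xs[n %/% 2L + 1L, ]) / 2
}

# Deterministic child seeds derived from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable condition ordering: the study order where applicable.
ordered_conditions <- function(x) {
  u <- unique(x)
  if (all(u %in% CONDITIONS)) CONDITIONS[CONDITIONS %in% u] else u
}
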