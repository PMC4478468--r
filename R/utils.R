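#' The 20-letter amino-acid alphabet in PSI-BLAST column order
#'
#' Both the log-odds (PSSM) and frequency (PSFM) matrices written by
#' PSI-BLAST's `-Q` option order their 20 columns as
#' A R N D C Q E G H I L K M F P S T W Y V. Every matrix in this package
#' uses this ordering, and alignments require query and template profiles
#' to share it.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Draw k derived seeds (< 2^31) from a parent seed, for nested generators.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a
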