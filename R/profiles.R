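#' Construct a sequence profile (PSSM + PSFM)
#'
#' A `sequence_profile` bundles a protein sequence with its two PSI-BLAST
#' matrices: the position-specific scoring matrix (`pssm`, integer-valued
#' log-odds scores) and the position-specific frequency matrix (`psfm`,
#' per-position amino-acid frequencies). Rows correspond to sequence
#' positions, columns to the 20 residues in [aa_alphabet()] order.
#'
#' PSFM rows are renormalized to sum to 1; an all-zero frequency row (which
#' occurs in real PSI-BLAST output at positions with no hits) is replaced by
#' the uniform distribution (0.05 per residue). Sequence letters outside the
#' standard alphabet are mapped to `"X"`; their matrix rows are kept as given.
#'
#' @param sequence Amino-acid string of length L.
#' @param pssm L x 20 numeric matrix of log-odds scores.
#' @param psfm L x 20 numeric matrix of nonnegative frequencies (or
#'   percentages; rows are renormalized).
#' @param id Optional identifier carried through downstream output.
#' @return An object of class `sequence_profile` with fields `sequence`
#'   (character vector of length L), `pssm`, `psfm`, `alphabet`, `id`.
#' @export
sequence_profile <- function(sequence, pssm, psfm, id = "query") {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(as.character(sequence))
  L <- length(sequence)
  if (L < 1L) stop("empty sequence")
  pssm <- as.matrix(pssm)
  psfm <- as.matrix(psfm)
  if (!all(dim(pssm) == c(L, 20L)) || !all(dim(psfm) == c(L, 20L))) {
    stop("pssm and psfm must both be L x 20 with L = length(sequence)")
  }
  if (any(psfm < 0)) stop("psfm must be nonnegative")
  sequence[!(sequence %in% c(aa_alphabet(), "X"))] <- "X"
  rs <- rowSums(psfm)
  zero <- rs == 0
  if (any(zero)) {
    psfm[zero, ] <- 1 / 20
    rs[zero] <- 1
  }
  psfm <- psfm / rs
  colnames(pssm) <- colnames(psfm) <- aa_alphabet()
  structure(
    list(sequence = sequence, pssm = unname(pssm) ,
         psfm = unname(psfm), alphabet = aa_alphabet(), id = id),
    class = "sequence_profile"
  )
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat(sprintf("sequence_profile '%s': %d residues\n", x$id, length(x$sequence)))
  cat("  ", paste(utils::head(x$sequence, 60), collapse = ""),
      if (length(x$sequence) > 60) "...", "\n", sep = "")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII profile file
#'
#' Reads the plain-text matrix written by PSI-BLAST's `-Q` option: header
#' lines, then one row per residue holding the position index, the residue
#' letter, 20 integer log-odds scores, 20 frequency percentages and two
#' trailing per-position statistics, followed by Lambda/K footer lines.
#' Percentages are divided by 100 and each frequency row renormalized to
#' sum to 1 (all-zero rows become uniform).
#'
#' @param path Path to a profile file.
#' @return A [sequence_profile()].
#' @export
parse_psiblast_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  tokens <- strsplit(trimws(lines), "\\s+")
  is_row <- vapply(tokens, function(tk) {
    length(tk) >= 2L && grepl("^[0-9]+$", tk[1]) && grepl("^[A-Za-z]$", tk[2])
  }, logical(1))
  idx <- which(is_row)
  if (length(idx) == 0L) stop("no profile rows found in ", path)
  L <- length(idx)
  seqv <- character(L)
  pssm <- matrix(0, L, 20)
  psfm <- matrix(0, L, 20)
  for (r in seq_len(L)) {
    tk <- tokens[[idx[r]]]
    # 44 columns in the full dialect (index, residue, 20 + 20 matrix
    # entries, two per-position statistics); 42 when the statistics are absent
    if (!length(tk) %in% c(42L, 44L)) {
      stop(sprintf("malformed profile row at line %d of %s: expected 42 or 44 columns, found %d",
                   idx[r], path, length(tk)))
    }
    num <- suppressWarnings(as.numeric(tk[3:42]))
    if (anyNA(num)) {
      stop(sprintf("malformed profile row at line %d of %s: non-numeric matrix entry",
                   idx[r], path))
    }
    seqv[r] <- tk[2]
    pssm[r, ] <- num[1:20]
    psfm[r, ] <- num[21:40] / 100
  }
  id <- sub("\\.[^.]*$", "", basename(path))
  sequence_profile(seqv, pssm, psfm, id = id)
}

#' Write a profile in the PSI-BLAST ASCII dialect
#'
#' Emits the same per-row layout [parse_psiblast_profile()] reads (position,
#' residue, 20 log-odds scores, 20 frequency percentages, two per-position
#' statistics placeholders), so generated fixtures round-trip through the
#' parser. Frequencies are written as percentages with six decimals.
#'
#' @param profile A [sequence_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psiblast_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sequence_profile"))
  ab <- profile$alphabet
  hdr <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("          ", paste(sprintf("%4s", ab), collapse = ""),
           "  ", paste(sprintf("%8s", ab), collapse = ""))
  )
  L <- length(profile$sequence)
  rows <- vapply(seq_len(L), function(i) {
    paste0(sprintf("%5d %s ", i, profile$sequence[i]),
           paste(sprintf("%3d", round(profile$pssm[i, ])), collapse = " "),
           "  ",
           paste(sprintf("%10.6f", 100 * profile$psfm[i, ]), collapse = " "),
           sprintf("  %5.2f %9.2f", 0, 0))
  }, character(1))
  ftr <- c("", "                      K         Lambda",
           "Standard Ungapped    0.1337     0.3177")
  writeLines(c(hdr, rows, ftr), path)
  invisible(path)
}

#' Elementwise sigmoid normalization of a log-odds matrix
#'
#' PSSM log-odds scores can be negative; for neural-network input they are
#' mapped into (0, 1) by the logistic function 1 / (1 + exp(-x)), which is
#' strictly increasing in the raw score.
#'
#' @param pssm Numeric vector or matrix of finite log-odds scores.
#' @return Object of the same shape with entries in (0, 1).
#' @export
sigmoid_normalize <- function(pssm) {
  if (any(!is.finite(pssm))) stop("pssm entries must be finite")
  1 / (1 + exp(-pssm))
}

#' Shannon entropy of a frequency column
#'
#' Entropy (natural-log units) of a per-position amino-acid frequency
#' vector: -sum f_r log f_r, with 0 log 0 taken as 0. A fully conserved
#' column (one frequency equal to 1) has entropy 0; a uniform column over
#' 20 residues has entropy log(20), approximately 2.996.
#'
#' @param freqs Nonnegative frequency vector summing to 1 (tolerance 1e-4).
#' @return Entropy in `[0, log(20)]`.
#' @export
column_entropy <- function(freqs) {
  if (any(freqs < 0)) stop("frequencies must be nonnegative")
  if (abs(sum(freqs) - 1) > 1e-4) stop("frequencies must sum to 1")
  nz <- freqs > 0
  -sum(freqs[nz] * log(freqs[nz]))
}

#' Conservation score from column entropy
#'
#' CS = exp(-entropy): 1 for a fully conserved position, decreasing
#' monotonically to 1/20 at the uniform-frequency maximum entropy log(20).
#' The codomain is (0, 1]; higher means more conserved.
#'
#' @param entropy_value Entropy value(s) in `[0, log(20)]` (small numeric
#'   slack is tolerated).
#' @return Conservation score(s) in (0, 1].
#' @export
conservation_score <- function(entropy_value) {
  tol <- 1e-8
  if (any(entropy_value < -tol) || any(entropy_value > log(20) + tol)) {
    stop("entropy must lie in [0, log(20)]")
  }
  exp(-pmin(pmax(entropy_value, 0), log(20)))
}

#' Per-residue information features of a profile
#'
#' Computes the three derived tracks used as predictor input: the
#' sigmoid-normalized PSSM, per-position entropy of the PSFM, and the
#' conservation score.
#'
#' @param profile A [sequence_profile()].
#' @return Object of class `profile_features` with fields `pssm_sig`
#'   (L x 20 in (0,1)), `entropy` (length L), `cs` (length L).
#' @export
profile_features <- function(profile) {
  stopifnot(inherits(profile, "sequence_profile"))
  ent <- apply(profile$psfm, 1, column_entropy)
  structure(
    list(pssm_sig = sigmoid_normalize(profile$pssm),
         entropy = ent,
         cs = conservation_score(ent)),
    class = "profile_features"
  )
}

#' Write the per-residue feature table
#'
#' Tab-separated table with one row per residue: position, residue letter,
#' entropy, conservation score and the 20 sigmoid-normalized PSSM columns.
#'
#' @param profile A [sequence_profile()].
#' @param path Output path.
#' @param features Optional precomputed [profile_features()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(profile, path, features = profile_features(profile)) {
  df <- data.frame(
    position = seq_along(profile$sequence),
    residue = profile$sequence,
    entropy = features$entropy,
    cs = features$cs,
    features$pssm_sig,
    check.names = FALSE
  )
  colnames(df)[5:24] <- paste0("pssm_sig_", aa_alphabet())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
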