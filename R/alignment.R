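#' Parameters of the composite profile-alignment scoring function
#'
#' The pair score of query position i against template position j is
#' `w1 * Profile(i,j) + SS_Sim(i,j) - (w2*|dRD| + w3*|dRSA| + w4*|dPhi|)
#' - shift`; gaps are affine with `gap_open` charged on the first position
#' of a run and `gap_extend` on each additional position. The default
#' values are the ones obtained by fitting sequence alignments to
#' structural alignments of 23 structurally known outer membrane proteins:
#' gap open -7.0, gap extend -0.54, w1 0.65, w2 = w3 = w4 = 1.0 and shift
#' 0.76. The shift makes unrelated residue pairs score negative on average
#' so that local alignments do not extend through noise.
#'
#' @param gap_open,gap_extend Nonpositive gap penalties with
#'   `gap_open <= gap_extend`.
#' @param w1 Weight of the profile dot-product term.
#' @param w2,w3,w4 Weights of the RD, RSA and Phi difference terms.
#' @param shift Nonnegative constant subtracted from every pair score.
#' @param mode `"local"` (Smith-Waterman style) or `"global"`
#'   (end-to-end with terminal gap penalties).
#' @return Object of class `alignment_params`.
#' @export
alignment_params <- function(gap_open = -7.0, gap_extend = -0.54,
                             w1 = 0.65, w2 = 1.0, w3 = 1.0, w4 = 1.0,
                             shift = 0.76, mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    stop("require gap_open <= gap_extend <= 0")
  }
  if (shift < 0) stop("shift must be nonnegative")
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 w1 = w1, w2 = w2, w3 = w3, w4 = w4,
                 shift = shift, mode = mode),
            class = "alignment_params")
}

#' Ablated scoring parameters: profile and SS terms only
#'
#' The Control-PPA configuration zeroes the three structural-property
#' weights (`w2 = w3 = w4 = 0`) so the score uses only the profile
#' dot-product and secondary-structure similarity terms.
#'
#' @param ... Passed to [alignment_params()].
#' @return An `alignment_params` object.
#' @export
control_ppa_params <- function(...) {
  alignment_params(w2 = 0, w3 = 0, w4 = 0, ...)
}

#' A feature-annotated profile ready for alignment
#'
#' Couples a [sequence_profile()] with the per-residue predicted (or true)
#' [structural_features()] and the SS reliability track consumed by the
#' scoring function.
#'
#' @param profile A [sequence_profile()].
#' @param features A [structural_features()] of the same length.
#' @param ss_ri Length-L reliability vector (defaults to the margin of
#'   `features$ss_probs` when present).
#' @param id Entry label.
#' @return Object of class `aligned_entry`.
#' @export
aligned_entry <- function(profile, features, ss_ri = NULL,
                          id = profile$id) {
  stopifnot(inherits(profile, "sequence_profile"),
            inherits(features, "structural_features"))
  L <- length(profile$sequence)
  if (length(features$ss3) != L) stop("profile and features lengths differ")
  if (is.null(ss_ri)) {
    if (is.null(features$ss_probs)) stop("ss_ri missing and no ss_probs to derive it")
    ss_ri <- ss_reliability(features$ss_probs)
  }
  if (length(ss_ri) != L) stop("ss_ri length differs from profile length")
  structure(list(profile = profile, features = features,
                 ss_ri = as.numeric(ss_ri), id = id),
            class = "aligned_entry")
}

#' Build an alignment-ready entry from a feature prediction
#'
#' Wraps a profile and the data frame returned by [predict_features()]
#' into an [aligned_entry()] carrying the predicted SS, reliability, RSA,
#' RD and Phi tracks.
#'
#' @param profile A [sequence_profile()].
#' @param pred The matching [predict_features()] data frame.
#' @param id Entry label.
#' @return An [aligned_entry()].
#' @export
entry_from_prediction <- function(profile, pred, id = profile$id) {
  feats <- structural_features(
    ss3 = pred$ss3, rsa = pred$rsa, rd = pred$rd, phi_norm = pred$phi_norm,
    ss_probs = as.matrix(pred[, c("pH", "pE", "pC")])
  )
  aligned_entry(profile, feats, ss_ri = pred$ss_ri, id = id)
}

#' Profile similarity term for one position pair
#'
#' The symmetric cross dot-product of frequencies against log-odds scores:
#' `0.5 * (sum_k PSFM_q(i,k) PSSM_t(j,k) + sum_k PSFM_t(j,k) PSSM_q(i,k))`.
#' Raw (un-normalized) log-odds values are used, so the score lives on the
#' scale the alignment thresholds were calibrated on.
#'
#' @param q,t [aligned_entry()] objects sharing the alphabet ordering.
#' @param i,j 1-based positions in `q` and `t`.
#' @return Scalar profile score.
#' @export
profile_score <- function(q, t, i, j) {
  if (!identical(q$profile$alphabet, t$profile$alphabet)) {
    stop("query and template profiles use different alphabets")
  }
  0.5 * (sum(q$profile$psfm[i, ] * t$profile$pssm[j, ]) +
         sum(t$profile$psfm[j, ] * q$profile$pssm[i, ]))
}

#' Secondary-structure similarity term for one position pair
#'
#' Zero when the two residues have different predicted SS classes;
#' otherwise the mean of their reliability indices:
#' `delta(ss_q(i), ss_t(j)) * (SS_RI_q(i) + SS_RI_t(j)) / 2`.
#'
#' @inheritParams profile_score
#' @return Scalar in `[0, 1)`.
#' @export
ss_sim <- function(q, t, i, j) {
  if (q$features$ss3[i] != t$features$ss3[j]) return(0)
  0.5 * (q$ss_ri[i] + t$ss_ri[j])
}

#' Structural-property difference term for one position pair
#'
#' Weighted sum of absolute differences of the three `[0, 1]` property
#' tracks: `w2 |RD_q(i) - RD_t(j)| + w3 |RSA_q(i) - RSA_t(j)| +
#' w4 |Phi_q(i) - Phi_t(j)|`. Nonnegative; zero for identical features.
#'
#' @inheritParams profile_score
#' @param params An [alignment_params()].
#' @return Scalar penalty (subtracted from the pair score).
#' @export
property_delta <- function(q, t, i, j, params = alignment_params()) {
  params$w2 * abs(q$features$rd[i] - t$features$rd[j]) +
    params$w3 * abs(q$features$rsa[i] - t$features$rsa[j]) +
    params$w4 * abs(q$features$phi_norm[i] - t$features$phi_norm[j])
}

#' Composite pair score for one position pair
#'
#' `w1 * profile_score + ss_sim - property_delta - shift`.
#'
#' @inheritParams property_delta
#' @return Scalar pair score.
#' @export
pair_score <- function(q, t, i, j, params = alignment_params()) {
  params$w1 * profile_score(q, t, i, j) + ss_sim(q, t, i, j) -
    property_delta(q, t, i, j, params) - params$shift
}

# Full Lq x Lt pair-score matrix, vectorized.
pair_score_matrix <- function(q, t, params) {
  if (!identical(q$profile$alphabet, t$profile$alphabet)) {
    stop("query and template profiles use different alphabets")
  }
  prof <- 0.5 * (q$profile$psfm %*% t(t$profile$pssm) +
                 q$profile$pssm %*% t(t$profile$psfm))
  same <- outer(q$features$ss3, t$features$ss3, "==")
  ss <- same * (0.5 * outer(q$ss_ri, t$ss_ri, "+"))
  prop <- params$w2 * abs(outer(q$features$rd, t$features$rd, "-")) +
    params$w3 * abs(outer(q$features$rsa, t$features$rsa, "-")) +
    params$w4 * abs(outer(q$features$phi_norm, t$features$phi_norm, "-"))
  params$w1 * prof + ss - prop - params$shift
}

#' Align two feature-annotated profiles
#'
#' Affine-gap dynamic programming over the composite pair scores, with the
#' three-state (match / insertion / deletion) recurrence of Durbin et al.
#' A gap run of length g costs `gap_open + (g - 1) * gap_extend`; direct
#' transitions between the two gap states are allowed and open a new run.
#' Local mode clamps the match state at zero and tracebacks from the
#' maximal cell (score >= 0, possibly empty); global mode aligns
#' end-to-end with terminal gap runs penalized. Traceback tie-breaks are
#' deterministic: match preferred over insertion over deletion.
#'
#' @param q,t [aligned_entry()] objects.
#' @param params An [alignment_params()]; its `mode` selects local/global.
#' @return Object of class `alignment_result`: `score`, `pairs` (k x 2
#'   matrix of aligned 1-based positions, strictly increasing in both
#'   columns), `mode`, `qid`, `tid`, `qlen`, `tlen`.
#' @export
align_profiles <- function(q, t, params = alignment_params()) {
  stopifnot(inherits(q, "aligned_entry"), inherits(t, "aligned_entry"))
  n <- length(q$profile$sequence)
  m <- length(t$profile$sequence)
  if (n == 0L || m == 0L) stop("cannot align empty sequences")
  S <- pair_score_matrix(q, t, params)
  local <- params$mode == "local"
  go <- params$gap_open
  ge <- params$gap_extend
  NEG <- -1e18

  # state matrices, row r = sequence position r-1 of q; col c = pos c-1 of t
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in template: q residue unaligned
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in query: t residue unaligned
  pM <- matrix(0L, n + 1L, m + 1L)   # 0 start, 1 from M, 2 from Ix, 3 from Iy
  pIx <- matrix(0L, n + 1L, m + 1L)
  pIy <- matrix(0L, n + 1L, m + 1L)

  if (local) {
    M[1L, ] <- 0
    M[, 1L] <- 0
  } else {
    M[1L, 1L] <- 0
    if (n > 0L) {
      Ix[1L + seq_len(n), 1L] <- go + (seq_len(n) - 1L) * ge
      pIx[2L, 1L] <- 1L
      if (n > 1L) pIx[2L + seq_len(n - 1L), 1L] <- 2L
    }
    if (m > 0L) {
      Iy[1L, 1L + seq_len(m)] <- go + (seq_len(m) - 1L) * ge
      pIy[1L, 2L] <- 1L
      if (m > 1L) pIy[1L, 2L + seq_len(m - 1L)] <- 3L
    }
  }

  pick3 <- function(a, b, c) {
    # vectorized first-wins argmax over three candidate vectors
    best <- pmax(a, b, c)
    ifelse(a >= best, 1L, ifelse(b >= best, 2L, 3L))
  }

  for (i in seq_len(n)) {
    r <- i + 1L
    jj <- seq_len(m)
    # M: diagonal predecessors from row r-1, cols jj
    dM <- M[r - 1L, jj]
    dIx <- Ix[r - 1L, jj]
    dIy <- Iy[r - 1L, jj]
    best <- pmax(dM, dIx, dIy)
    ptr <- pick3(dM, dIx, dIy)
    if (local) {
      # a nonpositive predecessor is equivalent to starting a fresh
      # alignment at this pair (this also skips dead clamped cells)
      ptr[best <= 0] <- 0L
      best <- pmax(best, 0)
    }
    mrow <- S[i, ] + best
    if (local) {
      dead <- mrow < 0
      mrow[dead] <- 0
      ptr[dead] <- -1L
    }
    M[r, jj + 1L] <- mrow
    pM[r, jj + 1L] <- ptr

    # Ix: vertical predecessors from row r-1, same column
    uM <- M[r - 1L, jj + 1L] + go
    uIx <- Ix[r - 1L, jj + 1L] + ge
    uIy <- Iy[r - 1L, jj + 1L] + go
    Ix[r, jj + 1L] <- pmax(uM, uIx, uIy)
    pIx[r, jj + 1L] <- pick3(uM, uIx, uIy)

    # Iy: horizontal predecessors within row r (sequential)
    for (j in seq_len(m)) {
      c2 <- j + 1L
      a <- M[r, c2 - 1L] + go
      b <- Ix[r, c2 - 1L] + go
      d <- Iy[r, c2 - 1L] + ge
      if (a >= b && a >= d) {
        Iy[r, c2] <- a; pIy[r, c2] <- 1L
      } else if (b >= d) {
        Iy[r, c2] <- b; pIy[r, c2] <- 2L
      } else {
        Iy[r, c2] <- d; pIy[r, c2] <- 3L
      }
    }
  }

  if (local) {
    inner <- M[-1L, -1L, drop = FALSE]
    score <- max(inner)
    if (score <= 0) {
      return(structure(list(score = 0, pairs = matrix(0L, 0L, 2L),
                            mode = params$mode, qid = q$id, tid = t$id,
                            qlen = n, tlen = m),
                       class = "alignment_result"))
    }
    k <- which(inner == score)[1L]  # column-major first: deterministic
    i0 <- (k - 1L) %% n + 1L
    j0 <- (k - 1L) %/% n + 1L
    state <- 1L
    r <- i0 + 1L
    c <- j0 + 1L
  } else {
    cands <- c(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
    state <- which(cands == max(cands))[1L]
    score <- cands[state]
    r <- n + 1L
    c <- m + 1L
  }

  pairs_i <- integer(0)
  pairs_j <- integer(0)
  repeat {
    if (state == 1L) {
      if (r == 1L || c == 1L) break  # global border start cell
      pairs_i <- c(pairs_i, r - 1L)
      pairs_j <- c(pairs_j, c - 1L)
      prev <- pM[r, c]
      r <- r - 1L
      c <- c - 1L
      if (prev == 0L) break  # local fresh start
      state <- prev
    } else if (state == 2L) {
      prev <- pIx[r, c]
      r <- r - 1L
      state <- prev
      if (r == 1L && c == 1L) break
    } else {
      prev <- pIy[r, c]
      c <- c - 1L
      state <- prev
      if (r == 1L && c == 1L) break
    }
    if (!local && r == 1L && c == 1L) break
  }
  pairs <- cbind(rev(pairs_i), rev(pairs_j))
  colnames(pairs) <- c("q", "t")
  structure(list(score = score, pairs = pairs, mode = params$mode,
                 qid = q$id, tid = t$id, qlen = n, tlen = m),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment %s vs %s: score %.3f, %d aligned pairs\n",
              x$mode, x$qid, x$tid, x$score, nrow(x$pairs)))
  invisible(x)
}

#' Render an alignment as text and machine-readable JSON
#'
#' Writes a pairwise text block (ids, mode, score, aligned sequence rows
#' with a match line and gap characters) and, optionally, a JSON file with
#' the score and the aligned position pairs.
#'
#' @param result An [align_profiles()] result.
#' @param q,t The aligned entries (for sequence letters).
#' @param path Text output path (`NULL` to skip).
#' @param json_path JSON output path (`NULL` to skip).
#' @return Character vector of the text block, invisibly.
#' @export
write_alignment <- function(result, q, t, path = NULL, json_path = NULL) {
  pr <- result$pairs
  qs <- q$profile$sequence
  ts <- t$profile$sequence
  arow <- character(0); brow <- character(0); mrow <- character(0)
  if (nrow(pr) > 0L) {
    li <- pr[1L, 1L]; lj <- pr[1L, 2L]
    arow <- qs[li]; brow <- ts[lj]
    mrow <- if (qs[li] == ts[lj]) "|" else " "
    if (nrow(pr) > 1L) for (k in 2:nrow(pr)) {
      i <- pr[k, 1L]; j <- pr[k, 2L]
      gi <- (li + 1L):i; gi <- gi[gi < i]
      gj <- (lj + 1L):j; gj <- gj[gj < j]
      if (length(gi)) {
        arow <- c(arow, qs[gi]); brow <- c(brow, rep("-", length(gi)))
        mrow <- c(mrow, rep(" ", length(gi)))
      }
      if (length(gj)) {
        arow <- c(arow, rep("-", length(gj))); brow <- c(brow, ts[gj])
        mrow <- c(mrow, rep(" ", length(gj)))
      }
      arow <- c(arow, qs[i]); brow <- c(brow, ts[j])
      mrow <- c(mrow, if (qs[i] == ts[j]) "|" else " ")
      li <- i; lj <- j
    }
  }
  lines <- c(
    sprintf("# %s alignment: %s (len %d) vs %s (len %d)",
            result$mode, result$qid, result$qlen, result$tid, result$tlen),
    sprintf("# score: %.4f  aligned pairs: %d", result$score, nrow(pr)),
    paste(arow, collapse = ""),
    paste(mrow, collapse = ""),
    paste(brow, collapse = "")
  )
  if (!is.null(path)) writeLines(lines, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(query = result$qid, template = result$tid, mode = result$mode,
           score = result$score,
           pairs = if (nrow(pr)) unname(pr) else matrix(0L, 0L, 2L)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(lines)
}
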