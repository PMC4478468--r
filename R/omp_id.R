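#' Build a searchable library of feature-annotated profiles
#'
#' Runs the feature-prediction pipeline over a set of profiles and stores
#' each as an [aligned_entry()] carrying predicted secondary structure,
#' reliability, RSA, RD and Phi tracks. Entries whose prediction fails are
#' skipped with a warning; duplicate ids are an error.
#'
#' @param profiles List of [sequence_profile()] objects (or paths to
#'   PSI-BLAST profile files).
#' @param bundle A trained [train_model_bundle()] result.
#' @param ids Optional entry ids (default: profile ids).
#' @return Object of class `omp_library`.
#' @export
build_library <- function(profiles, bundle, ids = NULL) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  profiles <- lapply(profiles, function(p) {
    if (is.character(p)) parse_psiblast_profile(p) else p
  })
  if (is.null(ids)) ids <- vapply(profiles, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate library ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  entries <- vector("list", length(profiles))
  keep <- logical(length(profiles))
  for (k in seq_along(profiles)) {
    ent <- tryCatch(
      entry_from_prediction(profiles[[k]],
                            predict_features(profiles[[k]], bundle),
                            id = ids[k]),
      error = function(e) {
        warning("skipping library entry '", ids[k], "': ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(ent)) {
      entries[[k]] <- ent
      keep[k] <- TRUE
    }
  }
  entries <- entries[keep]
  if (length(entries) == 0L) stop("no library entries could be built")
  structure(list(entries = entries,
                 ids = vapply(entries, `[[`, character(1), "id")),
            class = "omp_library")
}

#' @export
print.omp_library <- function(x, ...) {
  cat(sprintf("omp_library: %d entries\n", length(x$entries)))
  invisible(x)
}

#' Save / load a library directory
#'
#' The on-disk form is a manifest JSON plus, per entry, a PSI-BLAST-dialect
#' profile file and a predicted-feature TSV, so a library round-trips
#' through plain text.
#'
#' @param lib An `omp_library`.
#' @param dir Directory path.
#' @return `dir` (save) or the restored `omp_library` (load).
#' @export
save_library <- function(lib, dir) {
  stopifnot(inherits(lib, "omp_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ent in lib$entries) {
    write_psiblast_profile(ent$profile,
                           file.path(dir, paste0(ent$id, ".profile")))
    df <- data.frame(
      position = seq_along(ent$profile$sequence),
      residue = ent$profile$sequence,
      ss3 = ent$features$ss3,
      pH = ent$features$ss_probs[, "H"],
      pE = ent$features$ss_probs[, "E"],
      pC = ent$features$ss_probs[, "C"],
      ss_ri = ent$ss_ri,
      rsa = ent$features$rsa,
      rd = ent$features$rd,
      phi_norm = ent$features$phi_norm
    )
    utils::write.table(df, file.path(dir, paste0(ent$id, ".features.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(ids = lib$ids),
                       file.path(dir, "manifest.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_library
#' @export
load_library <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  entries <- lapply(man$ids, function(id) {
    prof <- parse_psiblast_profile(file.path(dir, paste0(id, ".profile")))
    prof$id <- id
    df <- utils::read.table(file.path(dir, paste0(id, ".features.tsv")),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    feats <- structural_features(
      ss3 = df$ss3, rsa = df$rsa, rd = df$rd, phi_norm = df$phi_norm,
      ss_probs = as.matrix(df[, c("pH", "pE", "pC")])
    )
    aligned_entry(prof, feats, ss_ri = df$ss_ri, id = id)
  })
  structure(list(entries = entries,
                 ids = vapply(entries, `[[`, character(1), "id")),
            class = "omp_library")
}

#' Search a query against a library
#'
#' Locally aligns the query against every library entry and ranks hits by
#' alignment score, descending; ties rank by id. The ranking is
#' deterministic and invariant under library order permutation.
#'
#' @param query An [aligned_entry()].
#' @param lib An `omp_library`.
#' @param params An [alignment_params()].
#' @return Data frame with columns `id`, `score`, sorted best-first.
#' @export
search_library <- function(query, lib, params = alignment_params()) {
  stopifnot(inherits(lib, "omp_library"))
  if (length(lib$entries) == 0L) stop("empty library")
  scores <- vapply(lib$entries, function(ent) {
    align_profiles(query, ent, params)$score
  }, numeric(1))
  ord <- order(-scores, lib$ids)
  data.frame(id = lib$ids[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}

#' Classify an alignment score against the OMP decision thresholds
#'
#' A score above the first threshold calls the query an OMP at the <1%
#' false-positive operating point; above the second (but not the first) at
#' the <5% point; otherwise non-OMP. Both comparisons are strict
#' ("higher than"). Defaults are the calibrated raw-score thresholds 20
#' and 15.
#'
#' @param score Finite alignment score(s).
#' @param thresholds Two decreasing thresholds `(t1, t5)`.
#' @return Character vector over
#'   `{"OMP_1pct", "OMP_5pct", "non-OMP"}`.
#' @export
classify_score <- function(score, thresholds = c(20, 15)) {
  if (any(!is.finite(score))) stop("scores must be finite")
  if (length(thresholds) != 2L || thresholds[1] <= thresholds[2]) {
    stop("thresholds must be two decreasing values")
  }
  ifelse(score > thresholds[1], "OMP_1pct",
         ifelse(score > thresholds[2], "OMP_5pct", "non-OMP"))
}

#' Z-score significance of a best hit against the rest of its score list
#'
#' `(best - mean(others)) / sd(others)`. Reported alongside the raw-score
#' threshold call as an auxiliary diagnostic, never overriding it. With
#' zero variance among the other scores the significance is undefined
#' (`NA`) and a warning is raised.
#'
#' @param best_score Best alignment score.
#' @param other_scores Scores of the remaining library hits (>= 2 values).
#' @return Single numeric z-score, or `NA` for degenerate variance.
#' @export
score_significance <- function(best_score, other_scores) {
  if (length(other_scores) < 2L) {
    stop("need at least 2 other scores (3 in total)")
  }
  s <- stats::sd(other_scores)
  if (s == 0) {
    warning("zero variance among other scores; significance undefined")
    return(NA_real_)
  }
  (best_score - mean(other_scores)) / s
}

#' Search, classify and report a verdict for one query
#'
#' @param query An [aligned_entry()].
#' @param lib An `omp_library`.
#' @param params An [alignment_params()].
#' @param thresholds Decision thresholds, see [classify_score()].
#' @return One-row data frame: `query`, `best_hit`, `score`, `z`, `call`.
#' @export
query_verdict <- function(query, lib, params = alignment_params(),
                          thresholds = c(20, 15)) {
  hits <- search_library(query, lib, params)
  z <- if (nrow(hits) >= 3L) {
    score_significance(hits$score[1], hits$score[-1])
  } else {
    NA_real_
  }
  data.frame(query = query$id, best_hit = hits$id[1], score = hits$score[1],
             z = z, call = classify_score(hits$score[1], thresholds),
             stringsAsFactors = FALSE)
}

#' ROC curve, AUC and true-positive counts at false-positive cutoffs
#'
#' Builds the full ROC step curve over all score thresholds (tied scores
#' are processed as one block so the curve does not depend on their
#' order), the area under it in instance units normalized to `[0, 1]`
#' (the Mann-Whitney statistic), and the count of true positives
#' recovered before exceeding each false-positive instance cutoff.
#'
#' @param scores Numeric prediction scores, higher = more OMP-like.
#' @param labels Logical (or 0/1) true labels, one per score; both classes
#'   must be present.
#' @param fp_cutoffs False-positive instance counts at which to report TP
#'   counts (cutoffs beyond the number of negatives are dropped).
#' @return Object of class `roc_result`: `curve` (data frame fp, tp),
#'   `auc`, `tp_at_fp` (named vector), `n_pos`, `n_neg`.
#' @export
evaluate_roc <- function(scores, labels, fp_cutoffs = seq(5, 50, by = 5)) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to build a ROC curve")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(s) sum(labels & scores == s), numeric(1)))
  fp <- cumsum(vapply(thr, function(s) sum(!labels & scores == s), numeric(1)))
  curve <- data.frame(fp = c(0, fp), tp = c(0, tp))
  # Mann-Whitney AUC with ties counted half
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  fp_cutoffs <- fp_cutoffs[fp_cutoffs <= n_neg]
  tp_at <- vapply(fp_cutoffs, function(cut) {
    ok <- curve$fp <= cut
    max(curve$tp[ok])
  }, numeric(1))
  names(tp_at) <- as.character(fp_cutoffs)
  structure(list(curve = curve, auc = auc, tp_at_fp = tp_at,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d positives / %d negatives: AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  if (length(x$tp_at_fp)) {
    cat("TP at FP cutoffs:\n")
    print(x$tp_at_fp)
  }
  invisible(x)
}

#' Q-score accuracies of a secondary-structure prediction
#'
#' Q3 is the fraction of residues whose 3-state class is predicted
#' correctly, pooled over the dataset; QH, QE and QC are the per-class
#' fractions (NA when a class is absent from the truth).
#'
#' @param pred,truth Character vectors of per-residue labels over
#'   `{H, E, C}` (strings are split).
#' @return Named numeric vector `Q3, QH, QE, QC`.
#' @export
q_scores <- function(pred, truth) {
  split1 <- function(x) unlist(strsplit(paste(x, collapse = ""), ""))
  p <- split1(pred)
  y <- split1(truth)
  if (length(p) != length(y)) stop("prediction and truth lengths differ")
  per_class <- vapply(c("H", "E", "C"), function(cl) {
    n <- sum(y == cl)
    if (n == 0L) NA_real_ else sum(p == cl & y == cl) / n
  }, numeric(1))
  c(Q3 = mean(p == y), QH = per_class[["H"]], QE = per_class[["E"]],
    QC = per_class[["C"]])
}

#' Mean absolute error
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return `mean(abs(pred - truth))`.
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("lengths differ")
  mean(abs(pred - truth))
}

#' Pearson correlation coefficient
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return Pearson correlation.
#' @export
pcc <- function(pred, truth) {
  stats::cor(pred, truth)
}

#' Write query verdicts as TSV with a provenance header
#'
#' @param verdicts Data frame of rows from [query_verdict()].
#' @param path Output path.
#' @param params The [alignment_params()] used (recorded in the header).
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path, params = alignment_params()) {
  hdr <- c(
    sprintf("# ppaomp %s verdicts", as.character(utils::packageVersion("ppaomp"))),
    sprintf("# mode=%s gap_open=%g gap_extend=%g w1=%g w2=%g w3=%g w4=%g shift=%g",
            params$mode, params$gap_open, params$gap_extend,
            params$w1, params$w2, params$w3, params$w4, params$shift)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(verdicts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
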