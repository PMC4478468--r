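test_that("score classification uses strict 20/15 thresholds monotonically", {
  expect_identical(classify_score(21), "OMP_1pct")
  expect_identical(classify_score(16), "OMP_5pct")
  expect_identical(classify_score(15), "non-OMP")
  expect_identical(classify_score(20), "OMP_5pct")
  expect_identical(classify_score(c(25, 18, 3)),
                   c("OMP_1pct", "OMP_5pct", "non-OMP"))
  # monotone in score
  calls <- classify_score(seq(0, 30, by = 0.5))
  lvl <- c("non-OMP" = 1, "OMP_5pct" = 2, "OMP_1pct" = 3)
  expect_true(all(diff(lvl[calls]) >= 0))
  expect_error(classify_score(Inf), "finite")
  expect_error(classify_score(10, thresholds = c(5, 10)), "decreasing")
})

test_that("score significance is a shift-invariant z with degenerate guard", {
  expect_equal(score_significance(10, c(8, 10, 12)), 0)
  expect_warning(z <- score_significance(30, c(10, 10, 10)), "variance")
  expect_true(is.na(z))
  others <- c(5, 9, 14, 2)
  expect_equal(score_significance(20, others),
               score_significance(20 + 7, others + 7), tolerance = 1e-12)
  expect_equal(score_significance(20, others),
               (20 - mean(others)) / stats::sd(others))
  expect_error(score_significance(5, 4), "at least 2")
})

test_that("ROC counts reproduce a hand-enumerated toy oracle", {
  # 10 items; sorted by descending score the labels read: P P N P N N P N N N
  scores <- c(9.5, 9.0, 8.5, 8.0, 7.5, 7.0, 6.5, 6.0, 5.5, 5.0)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  r <- evaluate_roc(scores, labels, fp_cutoffs = c(1, 2, 3, 6))
  expect_equal(unname(r$tp_at_fp), c(3, 3, 4, 4))
  expect_equal(r$n_pos, 4)
  expect_equal(r$n_neg, 6)
  # hand AUC: concordant pairs / (4*6)
  conc <- 0
  for (i in which(labels)) for (j in which(!labels)) {
    conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  expect_equal(r$auc, conc / 24, tolerance = 1e-12)
  # step curve is monotone and counts non-decreasing in the cutoff
  expect_true(all(diff(r$curve$tp) >= 0) && all(diff(r$curve$fp) >= 0))
  expect_true(all(diff(r$tp_at_fp) >= 0))
})

test_that("ROC handles ties, perfect separation, and label noise", {
  # perfect separation: all positives recovered at every cutoff
  r <- evaluate_roc(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE),
                    fp_cutoffs = 1:3)
  expect_equal(unname(r$tp_at_fp), c(2, 2, 2))
  expect_equal(r$auc, 1)
  # tied scores across classes count half
  r2 <- evaluate_roc(c(1, 1), c(TRUE, FALSE), fp_cutoffs = 1)
  expect_equal(r2$auc, 0.5)
  expect_error(evaluate_roc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # label-independent scores give AUC ~ 0.5
  big <- withr::with_seed(99, list(s = stats::rnorm(4000),
                            l = sample(c(TRUE, FALSE), 4000, TRUE)))
  expect_lt(abs(evaluate_roc(big$s, big$l, fp_cutoffs = 10)$auc - 0.5), 0.05)
})

test_that("our AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  dat <- withr::with_seed(7, list(s = stats::rnorm(200),
                           l = c(rep(TRUE, 80), rep(FALSE, 120))))
  dat$s[dat$l] <- dat$s[dat$l] + 1
  ours <- evaluate_roc(dat$s, dat$l, fp_cutoffs = 10)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(dat$l, dat$s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("library construction validates ids and round-trips through disk", {
  b <- tiny_bundle()
  profs <- lapply(1:3, function(k) {
    generate_family(family_spec(300 + k, length = 25, n_homologs = 15,
                                mutation_rate = 0.1),
                    id = sprintf("lib%d", k))$profile
  })
  lib <- build_library(profs, b)
  expect_s3_class(lib, "omp_library")
  expect_length(lib$entries, 3)
  for (ent in lib$entries) {
    expect_length(ent$features$rsa, length(ent$profile$sequence))
    expect_length(ent$ss_ri, length(ent$profile$sequence))
  }
  expect_error(build_library(profs[c(1, 1)], b), "duplicate")
  expect_error(build_library(list(), b), "no profiles")

  dir <- withr::local_tempdir()
  save_library(lib, dir)
  lib2 <- load_library(dir)
  expect_identical(lib2$ids, lib$ids)
  for (k in 1:3) {
    expect_equal(lib2$entries[[k]]$features$rsa, lib$entries[[k]]$features$rsa,
                 tolerance = 1e-5)
    expect_identical(lib2$entries[[k]]$profile$sequence,
                     lib$entries[[k]]$profile$sequence)
  }
})

test_that("search ranks a library copy of the query first, order-invariantly", {
  b <- tiny_bundle()
  profs <- lapply(1:4, function(k) {
    generate_family(family_spec(400 + k, length = 25, n_homologs = 15,
                                mutation_rate = 0.1),
                    id = sprintf("ent%d", k))$profile
  })
  lib <- build_library(profs, b)
  query <- lib$entries[[2]]
  hits <- search_library(query, lib)
  expect_identical(hits$id[1], "ent2")
  expect_true(all(diff(hits$score) <= 0))
  # permuting the library leaves the ranking unchanged
  libp <- lib
  perm <- c(3, 1, 4, 2)
  libp$entries <- lib$entries[perm]
  libp$ids <- lib$ids[perm]
  expect_identical(search_library(query, libp), hits)
  # single-entry library yields a single hit
  lib1 <- lib
  lib1$entries <- lib$entries[1]
  lib1$ids <- lib$ids[1]
  expect_identical(nrow(search_library(query, lib1)), 1L)

  v <- query_verdict(query, lib)
  expect_identical(v$best_hit, "ent2")
  expect_identical(v$call, classify_score(v$score))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_verdicts(v, path)
  got <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(got$score, v$score, tolerance = 1e-6)
})

test_that("Q scores, MAE and Pcc match direct formulas", {
  q <- q_scores("HHEECC", "HEEECC")
  expect_equal(unname(q["Q3"]), 5 / 6)
  expect_equal(unname(q["QH"]), 1)
  expect_equal(unname(q["QE"]), 2 / 3)
  expect_equal(unname(q["QC"]), 1)
  expect_true(is.na(q_scores("HHH", "HHH")[["QE"]]))
  expect_equal(mae(c(0.2, 0.6), c(0.1, 0.9)), 0.2)
  x <- withr::with_seed(5, stats::runif(30))
  y <- 2 * x + withr::with_seed(6, stats::rnorm(30, 0, 0.1))
  expect_equal(pcc(x, y), stats::cor(x, y))
  expect_error(q_scores("HE", "H"), "lengths differ")
})
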