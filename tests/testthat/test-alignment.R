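test_that("parameter container enforces its invariants", {
  p <- alignment_params()
  expect_equal(c(p$gap_open, p$gap_extend, p$w1, p$w2, p$w3, p$w4, p$shift),
               c(-7.0, -0.54, 0.65, 1.0, 1.0, 1.0, 0.76))
  expect_identical(p$mode, "local")
  expect_error(alignment_params(gap_open = -0.1, gap_extend = -0.5), "gap_open")
  expect_error(alignment_params(gap_extend = 0.2), "gap_open")
  expect_error(alignment_params(shift = -1), "shift")
  ctrl <- control_ppa_params()
  expect_equal(c(ctrl$w2, ctrl$w3, ctrl$w4), c(0, 0, 0))
  expect_equal(ctrl$w1, 0.65)
})

test_that("scoring terms follow their stated forms", {
  q <- random_entry(6, 1)
  t <- random_entry(7, 2)
  params <- alignment_params()

  # profile term: symmetric averaged cross dot-product, loop oracle
  for (ij in list(c(1, 1), c(3, 5), c(6, 7))) {
    i <- ij[1]; j <- ij[2]
    loop <- 0
    for (k in 1:20) {
      loop <- loop + 0.5 * (q$profile$psfm[i, k] * t$profile$pssm[j, k] +
                            t$profile$psfm[j, k] * q$profile$pssm[i, k])
    }
    expect_equal(profile_score(q, t, i, j), loop, tolerance = 1e-12)
    expect_equal(profile_score(q, t, i, j), profile_score(t, q, j, i))
  }

  # one-hot frequency row reduces algebraically
  q1 <- q
  q1$profile$psfm[2, ] <- 0
  q1$profile$psfm[2, 4] <- 1
  expect_equal(profile_score(q1, t, 2, 3),
               0.5 * (t$profile$pssm[3, 4] +
                      sum(t$profile$psfm[3, ] * q1$profile$pssm[2, ])),
               tolerance = 1e-12)

  # zero log-odds rows null the term
  qz <- q; tz <- t
  qz$profile$pssm[1, ] <- 0
  tz$profile$pssm[1, ] <- 0
  expect_equal(profile_score(qz, tz, 1, 1), 0)

  # SS term: delta-gated mean reliability
  qa <- q; ta <- t
  qa$features$ss3[1] <- "H"; ta$features$ss3[1] <- "E"
  expect_identical(ss_sim(qa, ta, 1, 1), 0)
  qa$features$ss3[2] <- "E"; ta$features$ss3[2] <- "E"
  qa$ss_ri[2] <- 0.8; ta$ss_ri[2] <- 0.4
  expect_equal(ss_sim(qa, ta, 2, 2), 0.6)
  qa$ss_ri[2] <- 0; ta$ss_ri[2] <- 0
  expect_equal(ss_sim(qa, ta, 2, 2), 0)

  # property term: weighted absolute differences
  qa$features$rd[3] <- 0.5; ta$features$rd[3] <- 0.4
  qa$features$rsa[3] <- 0.1; ta$features$rsa[3] <- 0.3
  qa$features$phi_norm[3] <- 0.9; ta$features$phi_norm[3] <- 0.6
  expect_equal(property_delta(qa, ta, 3, 3, params), 0.6, tolerance = 1e-12)
  expect_equal(property_delta(qa, ta, 3, 3, params),
               property_delta(ta, qa, 3, 3, params))
  qa$features$rd[4] <- ta$features$rd[4]
  qa$features$rsa[4] <- ta$features$rsa[4]
  qa$features$phi_norm[4] <- ta$features$phi_norm[4]
  expect_equal(property_delta(qa, ta, 4, 4, params), 0)

  # composed pair score: zero profile, differing SS, identical properties
  # leaves only the shift
  qz$features$ss3[1] <- "H"; tz$features$ss3[1] <- "C"
  tz$features$rd[1] <- qz$features$rd[1]
  tz$features$rsa[1] <- qz$features$rsa[1]
  tz$features$phi_norm[1] <- qz$features$phi_norm[1]
  expect_equal(pair_score(qz, tz, 1, 1, params), -0.76, tolerance = 1e-12)

  # scalar term and vectorized matrix agree
  S <- ppaomp:::pair_score_matrix(q, t, params)
  for (i in c(1, 4, 6)) for (j in c(2, 5, 7)) {
    expect_equal(S[i, j], pair_score(q, t, i, j, params), tolerance = 1e-12)
  }
})

test_that("DP equals the brute-force pair-set oracle on 200 random instances", {
  n_fail <- 0
  for (trial in 1:200) {
    dims <- withr::with_seed(trial * 13, sample(1:6, 2, replace = TRUE))
    q <- random_entry(dims[1], trial * 2 + 1)
    t <- random_entry(dims[2], trial * 2 + 2)
    mode <- if (trial %% 2 == 0) "local" else "global"
    # vary gap penalties across trials
    gaps <- withr::with_seed(trial, sort(-stats::runif(2, 0.2, 6)))
    params <- alignment_params(gap_open = gaps[1], gap_extend = gaps[2],
                               mode = mode)
    S <- ppaomp:::pair_score_matrix(q, t, params)
    res <- align_profiles(q, t, params)
    expected <- oracle_best_score(S, mode, params)
    if (!isTRUE(all.equal(res$score, expected, tolerance = 1e-9))) {
      n_fail <- n_fail + 1
    }
    # the returned traceback itself achieves the optimal score
    rescored <- oracle_score_pairs(S, res$pairs[, 1], res$pairs[, 2],
                                   dims[1], dims[2], mode, params)
    if (!isTRUE(all.equal(rescored, expected, tolerance = 1e-9))) {
      n_fail <- n_fail + 1
    }
    # pairs strictly increasing in both coordinates
    if (nrow(res$pairs) > 1) {
      expect_true(all(diff(res$pairs[, 1]) > 0) &&
                  all(diff(res$pairs[, 2]) > 0))
    }
  }
  expect_identical(n_fail, 0)
})

test_that("local alignments have the Smith-Waterman floor", {
  # engineer entries whose every pair score is negative: disjoint one-hot
  # frequency blocks and opposite log-odds signs
  mk <- function(seed, cols) {
    withr::with_seed(seed, {
      L <- 5
      psfm <- matrix(0, L, 20)
      psfm[, cols] <- stats::runif(L * length(cols))
      pssm <- matrix(-3, L, 20)
      feats <- structural_features(
        ss3 = rep(if (cols[1] == 1) "H" else "E", L),
        rsa = stats::runif(L, 0, 0.2) + if (cols[1] == 1) 0 else 0.8,
        rd = stats::runif(L, 0, 0.1),
        phi_norm = stats::runif(L, 0, 0.1))
      aligned_entry(sequence_profile(rep("A", L), pssm, psfm), feats,
                    ss_ri = rep(0.5, L), id = paste0("m", seed))
    })
  }
  q <- mk(1, 1:5)
  t <- mk(2, 6:10)
  res <- align_profiles(q, t, alignment_params(mode = "local"))
  expect_identical(res$score, 0)
  expect_identical(nrow(res$pairs), 0L)
  expect_error(align_profiles(q, t, alignment_params(mode = "globular")),
               "arg")
})

test_that("alignment score is symmetric and self-alignment pairs the diagonal", {
  q <- random_entry(12, 31)
  t <- random_entry(15, 32)
  for (mode in c("local", "global")) {
    p <- alignment_params(mode = mode)
    expect_equal(align_profiles(q, t, p)$score,
                 align_profiles(t, q, p)$score, tolerance = 1e-9)
  }
  fam <- generate_family(family_spec(41, length = 30, n_homologs = 10))
  e <- aligned_entry(fam$profile, fam$features, id = "self")
  S <- ppaomp:::pair_score_matrix(e, e, alignment_params())
  res <- align_profiles(e, e, alignment_params(mode = "global"))
  expect_equal(res$score, sum(diag(S)), tolerance = 1e-9)
  expect_equal(res$pairs[, 1], 1:30, ignore_attr = TRUE)
  expect_equal(res$pairs[, 2], 1:30, ignore_attr = TRUE)
  # local self-score at least the best single pair when positive
  resl <- align_profiles(e, e, alignment_params(mode = "local"))
  expect_gte(resl$score, max(S))
})

test_that("zeroing the property weights reproduces the ablated configuration", {
  q <- random_entry(8, 51)
  t <- random_entry(9, 52)
  ctrl <- control_ppa_params()
  manual <- alignment_params(w2 = 0, w3 = 0, w4 = 0)
  expect_equal(align_profiles(q, t, ctrl)$score,
               align_profiles(q, t, manual)$score)
  # property-divergent pairs score differently once weights are restored
  expect_false(isTRUE(all.equal(align_profiles(q, t, ctrl)$score,
                                align_profiles(q, t, alignment_params())$score)))
})

test_that("alignments render as text and JSON", {
  q <- random_entry(8, 61)
  t <- random_entry(8, 62)
  res <- align_profiles(q, t, alignment_params(mode = "global"))
  txt <- withr::local_tempfile(fileext = ".aln")
  js <- withr::local_tempfile(fileext = ".json")
  lines <- write_alignment(res, q, t, path = txt, json_path = js)
  expect_true(file.exists(txt))
  expect_match(lines[1], "global alignment")
  got <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(got$score, res$score, tolerance = 1e-12)
  expect_equal(nrow(got$pairs), nrow(res$pairs))
})
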