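test_that("7-to-3 state reduction follows the standard mapping and is idempotent", {
  expect_identical(reduce_ss("G"), "H")
  expect_identical(reduce_ss("I"), "H")
  expect_identical(reduce_ss("B"), "E")
  expect_identical(reduce_ss("TSX-"), "CCCC")
  expect_identical(reduce_ss("HGIEBTSC"), "HHHEECCC")
  # idempotent on 3-state strings
  for (seed in 1:5) {
    s <- withr::with_seed(seed, paste(sample(c(LETTERS, "-", " "), 30, TRUE),
                               collapse = ""))
    once <- reduce_ss(s)
    expect_identical(reduce_ss(once), once)
    expect_equal(nchar(once), nchar(s))
  }
  expect_identical(reduce_ss(c("GG", "BT")), c("HH", "EC"))
})

test_that("relative accessibility is the capped ratio to the reference maximum", {
  tab <- max_asa_table()
  expect_identical(unname(relative_accessibility(tab[["A"]], "A")), 1)
  expect_identical(unname(relative_accessibility(tab[["W"]] * 2, "W")), 1)
  expect_equal(unname(relative_accessibility(tab[["V"]] / 2, "V")), 0.5)
  expect_equal(unname(relative_accessibility(c(10, 20), c("G", "G"))),
               c(10, 20) / tab[["G"]])
  expect_error(relative_accessibility(10, "X"), "max-ASA")
  expect_identical(unname(relative_accessibility(100, "X", fallback_area = 100)), 1)
  expect_error(relative_accessibility(-1, "A"), "nonnegative")
  expect_length(tab, 20)
})

test_that("residue depth normalization maps [2.8, 9.8] linearly with clamping", {
  expect_identical(normalize_rd(2.8), 0)
  expect_identical(normalize_rd(9.8), 1)
  expect_equal(normalize_rd(6.3), 0.5, tolerance = 1e-12)
  expect_identical(normalize_rd(1.0), 0)
  expect_identical(normalize_rd(12.0), 1)
  dv <- seq(2.8, 9.8, length.out = 11)
  expect_equal(normalize_rd(dv), (dv - 2.8) / 7, tolerance = 1e-12)
})

test_that("phi normalization remaps negatives by +360 then divides by 360", {
  expect_identical(normalize_phi(0), 0)
  expect_equal(normalize_phi(180), 0.5)
  expect_equal(normalize_phi(-90), 0.75)
  expect_equal(normalize_phi(-180), 0.5)  # same wrapped angle as +180
  expect_error(normalize_phi(181), "\\[-180, 180\\]")
  expect_error(normalize_phi(-200), "\\[-180, 180\\]")
  # bijection from [-180, 180) onto [0, 1): distinct angles map distinctly
  phi <- seq(-180, 179.5, by = 0.5)
  out <- normalize_phi(phi)
  expect_true(all(out >= 0 & out < 1 | out == 0.5))
  expect_equal(length(unique(out)), length(unique(c(phi[phi != -180], 180))))
})

test_that("fitness table reproduces an independent tally oracle exactly", {
  # worked toy case: A occurs 10 times, 5 H / 3 E / 2 C
  seqs <- c(paste(rep("A", 10), collapse = ""), "VVV")
  sss <- c("HHHHHEEECC", "EEE")
  fit <- suppressWarnings(compute_fitness(seqs, sss))
  expect_equal(unname(fit$ft["A", ]), c(0.5, 0.3, 0.2))
  expect_equal(unname(fit$ft["V", ]), c(0, 1, 0))

  for (seed in 1:10) {
    dat <- withr::with_seed(seed, {
      n <- sample(3:6, 1)
      lens <- sample(10:40, n, replace = TRUE)
      list(
        seqs = vapply(lens, function(L)
          paste(sample(aa_alphabet(), L, TRUE), collapse = ""), ""),
        ss = vapply(lens, function(L)
          paste(sample(c("H", "E", "C"), L, TRUE), collapse = ""), "")
      )
    })
    fit <- suppressWarnings(compute_fitness(dat$seqs, dat$ss))
    # independent scalar tally
    aa <- unlist(strsplit(paste(dat$seqs, collapse = ""), ""))
    ss <- unlist(strsplit(paste(dat$ss, collapse = ""), ""))
    for (res in aa_alphabet()) {
      na <- sum(aa == res)
      if (na == 0) {
        expect_equal(unname(fit$ft[res, ]), rep(1 / 3, 3))
      } else {
        expected <- vapply(c("H", "E", "C"),
                           function(cl) sum(aa == res & ss == cl) / na, 0)
        expect_identical(unname(fit$ft[res, ]), unname(expected))
      }
    }
    expect_equal(unname(rowSums(fit$ft)), rep(1, 20), tolerance = 1e-9)
    expect_true(all(fit$ft >= 0 & fit$ft <= 1))
  }
})

test_that("residue types absent from the dataset get a uniform row with warning", {
  expect_warning(fit <- compute_fitness("AAAA", "HHEC"), "absent")
  expect_equal(unname(fit$ft["W", ]), rep(1 / 3, 3))
  expect_equal(unname(rowSums(fit$ft)), rep(1, 20), tolerance = 1e-9)
})

test_that("fitness tables round-trip through TSV", {
  fams <- tiny_families(2)
  fit <- suppressWarnings(compute_fitness(
    vapply(fams, function(f) paste(f$profile$sequence, collapse = ""), ""),
    vapply(fams, function(f) paste(f$features$ss3, collapse = ""), "")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fitness_table(fit, path)
  back <- read_fitness_table(path)
  expect_equal(back$ft, fit$ft, tolerance = 1e-12)
})

test_that("raw annotation tables normalize into declared ranges", {
  n <- 25
  ann <- withr::with_seed(8, data.frame(
    position = 1:n,
    residue = sample(aa_alphabet(), n, TRUE),
    ss7 = sample(c("H", "G", "I", "E", "B", "T", "S", "C"), n, TRUE),
    asa = stats::runif(n, 0, 350),
    depth = stats::runif(n, 2, 11),
    phi_deg = stats::runif(n, -180, 180)
  ))
  sf <- normalize_annotations(ann)
  expect_s3_class(sf, "structural_features")
  expect_true(all(sf$rsa >= 0 & sf$rsa <= 1))
  expect_true(all(sf$rd >= 0 & sf$rd <= 1))
  expect_true(all(sf$phi_norm >= 0 & sf$phi_norm <= 1))
  expect_true(all(sf$ss3 %in% c("H", "E", "C")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_structural_features(sf, path, residues = ann$residue)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(df), n)
})
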