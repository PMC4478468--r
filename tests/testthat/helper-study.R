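# Shared study fixtures, built lazily and cached for the whole test run.
# Training the model bundle is the expensive step (~3 min); every test that
# needs trained predictors reuses the same bundle.

.study <- new.env(parent = emptyenv())

study_families <- function() {
  if (is.null(.study$train)) {
    .study$train <- generate_families(500, 30, length = 60, n_homologs = 15)
    .study$test <- generate_families(600, 10, length = 60, n_homologs = 15)
  }
  list(train = .study$train, test = .study$test)
}

study_bundle <- function() {
  if (is.null(.study$bundle)) {
    .study$bundle <- train_model_bundle(study_families()$train, seed = 11)
  }
  .study$bundle
}

# Tiny families and a mechanically trained (low-epoch) bundle for tests that
# exercise plumbing, not predictive quality.
tiny_families <- function(n = 4L, seed = 900L) {
  generate_families(seed, n, length = 30, n_homologs = 8)
}

tiny_bundle <- function() {
  if (is.null(.study$tiny_bundle)) {
    cfgs <- stats::setNames(
      lapply(c("SS", "RSA", "RD", "Phi"), predictor_config,
             epochs1 = 2L, epochs2 = 2L),
      c("SS", "RSA", "RD", "Phi"))
    # small families may lack some residue types; the uniform-fitness
    # fallback warning is expected here
    .study$tiny_bundle <- suppressWarnings(
      train_model_bundle(tiny_families(), seed = 5, configs = cfgs))
  }
  .study$tiny_bundle
}

# A random feature-annotated entry with arbitrary tracks, for scoring and
# DP tests that do not need a trained pipeline.
random_entry <- function(L, seed, id = paste0("r", seed)) {
  withr::with_seed(seed, {
    seqv <- sample(aa_alphabet(), L, replace = TRUE)
    pssm <- matrix(sample(-5:8, L * 20, replace = TRUE), L, 20)
    psfm <- matrix(stats::runif(L * 20), L, 20)
    feats <- structural_features(
      ss3 = sample(c("H", "E", "C"), L, replace = TRUE),
      rsa = stats::runif(L), rd = stats::runif(L),
      phi_norm = stats::runif(L))
    aligned_entry(sequence_profile(seqv, pssm, psfm, id = id), feats,
                  ss_ri = stats::runif(L), id = id)
  })
}
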