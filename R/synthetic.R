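# Class-conditional amino-acid propensities used by the generator. Helix
# favors the classic helix formers, strand the beta-branched/aromatic
# hydrophobics, coil the turn/loop residues (G, P, polar). 70% of the mass
# sits on the favored set, the rest is spread uniformly, so columns are
# informative but never degenerate.
ss_residue_weights <- function() {
  favored <- list(
    H = c("A", "L", "E", "M", "Q", "K", "R"),
    E = c("V", "I", "Y", "F", "W", "T"),
    C = c("G", "P", "S", "N", "D")
  )
  out <- lapply(favored, function(f) {
    w <- rep(0.3 / 20, 20)
    names(w) <- aa_alphabet()
    w[f] <- w[f] + 0.7 / length(f)
    w / sum(w)
  })
  out
}

# Kyte-Doolittle hydropathy, scaled to [-1, 1].
kd_hydropathy <- function() {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  kd[aa_alphabet()] / 4.5
}

#' Specify a synthetic homologous family
#'
#' Parameters of the seeded generator that emulates a PSI-BLAST profile:
#' an ancestor sequence is mutated into a set of homologs, and the column
#' frequencies (with pseudocounts) yield the PSFM, from which rounded
#' half-bit log-odds against a uniform background give the PSSM.
#'
#' @param seed Generator seed.
#' @param length Number of residues (>= 10).
#' @param n_homologs Number of homologous sequences (>= 2).
#' @param mutation_rate Per-site substitution probability in `[0, 0.9]`.
#' @param pseudocount Pseudocount added per amino acid per column.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(seed, length = 120L, n_homologs = 40L,
                        mutation_rate = 0.25, pseudocount = 1) {
  length <- as.integer(length)
  n_homologs <- as.integer(n_homologs)
  if (length < 10L) stop("length must be >= 10")
  if (n_homologs < 2L) stop("n_homologs must be >= 2")
  if (mutation_rate < 0 || mutation_rate > 0.9) {
    stop("mutation_rate must lie in [0, 0.9]")
  }
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  structure(list(seed = as.integer(seed), length = length,
                 n_homologs = n_homologs, mutation_rate = mutation_rate,
                 pseudocount = pseudocount),
            class = "family_spec")
}

# Sample a segmented 3-state SS string: classes alternate (no immediate
# repeats) with geometric segment lengths (means ~8 for H, ~5 for E,
# ~4 for C). Must be called inside a seeded context.
sample_ss_segments <- function(L) {
  mean_len <- c(H = 8, E = 5, C = 4)
  classes <- c("H", "E", "C")
  ss <- character(0)
  prev <- NA_character_
  while (length(ss) < L) {
    cand <- if (is.na(prev)) classes else setdiff(classes, prev)
    cl <- sample(cand, 1L)
    len <- 1L + stats::rgeom(1L, prob = 1 / mean_len[[cl]])
    ss <- c(ss, rep(cl, len))
    prev <- cl
  }
  ss[seq_len(L)]
}

# Draw one sequence position-wise from the class-conditional propensities.
sample_sequence <- function(ss) {
  w <- ss_residue_weights()
  vapply(ss, function(cl) {
    sample(aa_alphabet(), 1L, prob = w[[cl]])
  }, character(1), USE.NAMES = FALSE)
}

# Mutate an ancestor: each site substitutes with probability `rate`, the
# replacement drawn from the site's SS-class propensities (structure-
# preserving divergence, as in real families).
mutate_sequence <- function(ancestor, ss, rate) {
  w <- ss_residue_weights()
  hit <- stats::runif(length(ancestor)) < rate
  out <- ancestor
  for (i in which(hit)) {
    out[i] <- sample(aa_alphabet(), 1L, prob = w[[ss[i]]])
  }
  out
}

# PSFM/PSSM from a set of equal-length homolog sequences.
profile_from_homologs <- function(seqs, pseudocount, id) {
  L <- length(seqs[[1]])
  counts <- matrix(0, L, 20, dimnames = list(NULL, aa_alphabet()))
  for (s in seqs) {
    idx <- cbind(seq_len(L), match(s, aa_alphabet()))
    counts[idx] <- counts[idx] + 1
  }
  psfm <- (counts + pseudocount) / (length(seqs) + 20 * pseudocount)
  pssm <- round(2 * log2(psfm / 0.05))
  sequence_profile(seqs[[1]], pssm, psfm, id = id)
}

# Ground-truth structural labels conditioned on SS class and ancestor
# residue identity. RSA combines a class-dependent mean with a dominant
# hydropathy term: hydrophobic residues are buried and polar residues
# exposed, the main determinant of within-class accessibility in real
# chains (in beta-barrels the membrane-facing hydrophobics are the buried
# face). RD is a decreasing function of RSA plus noise (negative
# correlation by construction); Phi is drawn around class-typical modes
# (helix ~ -60 deg -> 0.833, strand ~ -120 deg -> 0.667, coil broader).
sample_truth <- function(ancestor, ss) {
  L <- length(ancestor)
  kd <- kd_hydropathy()[ancestor]
  rsa_mu <- c(H = 0.45, E = 0.35, C = 0.60)[ss]
  rsa <- clamp01(rsa_mu - 0.30 * kd + stats::rnorm(L, 0, 0.06))
  rd <- clamp01(0.90 - 0.75 * rsa + stats::rnorm(L, 0, 0.04))
  phi_mu <- c(H = 0.833, E = 0.667, C = 0.78)[ss]
  phi_sd <- c(H = 0.02, E = 0.02, C = 0.07)[ss]
  phi <- clamp01(phi_mu + stats::rnorm(L, 0, phi_sd))
  probs <- matrix(0, L, 3, dimnames = list(NULL, c("H", "E", "C")))
  probs[cbind(seq_len(L), match(ss, c("H", "E", "C")))] <- 1
  structural_features(ss3 = ss, rsa = rsa, rd = rd, phi_norm = phi,
                      ss_probs = probs)
}

#' Generate a synthetic family: profile plus ground-truth labels
#'
#' Deterministically (per seed) builds a segmented secondary structure,
#' an ancestor sequence drawn from class-conditional residue propensities,
#' a set of structure-preserving mutated homologs, and from them a
#' PSFM/PSSM profile. Ground-truth RSA, RD and Phi tracks follow the
#' qualitative structure of real data: RSA depends on SS class and residue
#' hydropathy, RD is negatively correlated with RSA by construction, and
#' Phi is drawn from SS-conditional modes.
#'
#' @param spec A [family_spec()].
#' @param id Profile id.
#' @return List with `profile` ([sequence_profile()]), `features`
#'   (ground-truth [structural_features()]), `ancestor` (residue vector),
#'   `ss3`, and `spec`.
#' @export
generate_family <- function(spec, id = sprintf("fam%d", spec$seed)) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    ss <- sample_ss_segments(spec$length)
    ancestor <- sample_sequence(ss)
    homologs <- c(list(ancestor),
                  lapply(seq_len(spec$n_homologs - 1L), function(k) {
                    mutate_sequence(ancestor, ss, spec$mutation_rate)
                  }))
    profile <- profile_from_homologs(homologs, spec$pseudocount, id)
    features <- sample_truth(ancestor, ss)
    list(profile = profile, features = features, ancestor = ancestor,
         ss3 = ss, spec = spec)
  })
}

#' Generate a relative of an existing family
#'
#' Builds a new profile for a diverged member of the same family: the
#' ancestor is re-mutated at `mutation_rate` into a new homolog set. The
#' underlying structure (and hence the ground-truth labels) is that of the
#' parent family.
#'
#' @param family A [generate_family()] result.
#' @param seed Seed for this relative.
#' @param mutation_rate Divergence of the relative from the ancestor.
#' @param n_homologs Homologs for the relative's own profile.
#' @param id Profile id.
#' @return List with `profile` and `features` (inherited truth).
#' @export
generate_relative <- function(family, seed, mutation_rate = 0.55,
                              n_homologs = family$spec$n_homologs,
                              id = sprintf("%s_rel%d", family$profile$id, seed)) {
  with_seed(seed, {
    base <- mutate_sequence(family$ancestor, family$ss3, mutation_rate)
    homologs <- c(list(base),
                  lapply(seq_len(n_homologs - 1L), function(k) {
                    mutate_sequence(base, family$ss3,
                                    family$spec$mutation_rate)
                  }))
    profile <- profile_from_homologs(homologs, family$spec$pseudocount, id)
    list(profile = profile, features = family$features)
  })
}

#' Generate a labeled OMP-search benchmark
#'
#' Emulates the design of an OMP identification benchmark: each of
#' `n_omp_families` families contributes one library profile and one
#' positive query (a diverged relative sharing the family ancestor, so the
#' homology is detectable but not trivial), while `n_decoys` decoy queries
#' come from independent families unrelated to the library.
#'
#' @param seed Master seed; all family seeds are derived from it.
#' @param n_omp_families Number of library families (>= 1).
#' @param n_decoys Number of unrelated decoy queries (>= 1).
#' @param length,n_homologs,mutation_rate,pseudocount Family parameters,
#'   see [family_spec()].
#' @param query_mutation_rate Divergence of positive queries from their
#'   family ancestor.
#' @return List with `library_profiles` (list of [sequence_profile()]),
#'   `queries` (list of profiles), `labels` (logical, TRUE = OMP),
#'   `query_ids`, and the ground-truth [structural_features()] of every
#'   library entry (`library_truth`) and query (`query_truth`).
#' @export
generate_benchmark <- function(seed, n_omp_families = 20L, n_decoys = 60L,
                               length = 60L, n_homologs = 15L,
                               mutation_rate = 0.35,
                               query_mutation_rate = 0.55,
                               pseudocount = 1) {
  if (n_omp_families < 1L || n_decoys < 1L) stop("counts must be >= 1")
  seeds <- derive_seeds(seed, 2L * n_omp_families + n_decoys)
  lib_profiles <- vector("list", n_omp_families)
  lib_truth <- vector("list", n_omp_families)
  pos_queries <- vector("list", n_omp_families)
  pos_truth <- vector("list", n_omp_families)
  for (f in seq_len(n_omp_families)) {
    fam <- generate_family(
      family_spec(seeds[f], length = length, n_homologs = n_homologs,
                  mutation_rate = mutation_rate, pseudocount = pseudocount),
      id = sprintf("omp%02d", f))
    lib_profiles[[f]] <- fam$profile
    lib_truth[[f]] <- fam$features
    rel <- generate_relative(fam, seed = seeds[n_omp_families + f],
                             mutation_rate = query_mutation_rate,
                             id = sprintf("pos%02d", f))
    pos_queries[[f]] <- rel$profile
    pos_truth[[f]] <- rel$features
  }
  decoy_fams <- lapply(seq_len(n_decoys), function(d) {
    generate_family(
      family_spec(seeds[2L * n_omp_families + d], length = length,
                  n_homologs = n_homologs, mutation_rate = mutation_rate,
                  pseudocount = pseudocount),
      id = sprintf("decoy%02d", d))
  })
  queries <- c(pos_queries, lapply(decoy_fams, `[[`, "profile"))
  list(
    library_profiles = lib_profiles,
    library_truth = lib_truth,
    queries = queries,
    query_truth = c(pos_truth, lapply(decoy_fams, `[[`, "features")),
    labels = c(rep(TRUE, n_omp_families), rep(FALSE, n_decoys)),
    query_ids = vapply(queries, `[[`, character(1), "id")
  )
}

#' Generate a training/evaluation set of independent families
#'
#' @param seed Master seed.
#' @param n Number of families.
#' @param ... Passed to [family_spec()] (length, n_homologs, ...).
#' @return List of [generate_family()] results.
#' @export
generate_families <- function(seed, n, ...) {
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(k) {
    generate_family(family_spec(seeds[k], ...),
                    id = sprintf("fam%03d", k))
  })
}
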