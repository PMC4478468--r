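# Internal node order of the SS output layer. The three classes are encoded
# on the output nodes as H = (0,0,1), E = (0,1,0), C = (1,0,0), i.e. node 1
# fires for coil, node 2 for strand, node 3 for helix. which.max over this
# order also realizes the deterministic argmax tie-break C > E > H.
SS_NODE_ORDER <- c("C", "E", "H")

#' Sliding-window encoding with terminus bits
#'
#' Builds the per-residue input vectors fed to the predictors: for each
#' residue, the feature rows of the `window` positions centred on it are
#' concatenated. Every window slot carries one extra terminus unit: for
#' slots extending past either chain end the feature values are set to
#' zero and the terminus bit to 1, otherwise the bit is 0. The encoded
#' width is therefore `window * (ncol(features) + 1)`.
#'
#' @param features `L x w` matrix of per-residue feature tracks.
#' @param window Odd positive window length (`2n + 1`).
#' @param terminus_bit Include the per-slot terminus unit (default TRUE).
#' @return `L x (window * (w + terminus))` encoding matrix.
#' @export
encode_windows <- function(features, window, terminus_bit = TRUE) {
  features <- as.matrix(features)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and positive")
  L <- nrow(features)
  w <- ncol(features) + as.integer(terminus_bit)
  half <- (window - 1L) %/% 2L
  pad <- matrix(0, L + 2L * half, w)
  pad[half + seq_len(L), seq_len(ncol(features))] <- features
  if (terminus_bit && half > 0L) {
    pad[c(seq_len(half), half + L + seq_len(half)), w] <- 1
  }
  out <- matrix(0, L, window * w)
  for (s in seq_len(window)) {
    out[, (s - 1L) * w + seq_len(w)] <- pad[(s - 1L) + seq_len(L), ]
  }
  out
}

# Windowed track matrix for a profile: sigmoid-normalized PSSM (20), PSFM
# (20), conservation score (1), and optionally the per-residue fitness
# triplet (3) looked up from the residue letter (X -> uniform).
profile_track_matrix <- function(profile, fitness = NULL) {
  pf <- profile_features(profile)
  tracks <- cbind(pf$pssm_sig, profile$psfm, pf$cs)
  if (!is.null(fitness)) {
    ft <- if (inherits(fitness, "fitness_table")) fitness$ft else fitness
    rows <- match(profile$sequence, rownames(ft))
    ftm <- matrix(1 / 3, length(profile$sequence), 3)
    ok <- !is.na(rows)
    ftm[ok, ] <- ft[rows[ok], ]
    tracks <- cbind(tracks, ftm)
  }
  tracks
}

#' Default architecture and training budget for a property predictor
#'
#' Window sizes and the number of networks/hidden layers per property are
#' fixed by the method (SS: window 15, two networks, two then one hidden
#' layer; RD: window 17, two single-hidden-layer networks; Phi: window 17,
#' one network; RSA: window 21, two networks, with the three SS
#' probabilities of the target residue appended un-windowed). Hidden-layer
#' widths and epoch budgets are implementation defaults and can be
#' overridden.
#'
#' @param property One of `"SS"`, `"RSA"`, `"RD"`, `"Phi"`.
#' @param hidden1,hidden2 Hidden-layer widths of the two stages.
#' @param epochs1,epochs2 Training epochs of the two stages. At the fixed
#'   learning rate of 0.001 the scalar regressions converge more slowly
#'   than the classification network, so their defaults are larger
#'   (stage 1: 120 epochs vs 60 for SS; stage 2, whose input is narrow
#'   and therefore cheap per epoch: 200 vs 60).
#' @param learning_rate,momentum Backpropagation hyperparameters.
#' @return A list of configuration fields.
#' @export
predictor_config <- function(property,
                             hidden1 = NULL, hidden2 = NULL,
                             epochs1 = NULL, epochs2 = NULL,
                             learning_rate = 0.001, momentum = 0.85) {
  property <- match.arg(property, c("SS", "RSA", "RD", "Phi"))
  cfg <- switch(property,
    SS  = list(window = 15L, stage2_window = 15L, n_stages = 2L,
               hidden1 = c(24L, 12L), hidden2 = 8L),
    RD  = list(window = 17L, stage2_window = 17L, n_stages = 2L,
               hidden1 = 16L, hidden2 = 8L),
    Phi = list(window = 17L, stage2_window = NA_integer_, n_stages = 1L,
               hidden1 = 16L, hidden2 = NULL),
    RSA = list(window = 21L, stage2_window = 21L, n_stages = 2L,
               hidden1 = 16L, hidden2 = 8L)
  )
  if (!is.null(hidden1)) cfg$hidden1 <- as.integer(hidden1)
  if (!is.null(hidden2)) cfg$hidden2 <- as.integer(hidden2)
  cfg$property <- property
  if (is.null(epochs1)) epochs1 <- if (property == "SS") 60L else 120L
  if (is.null(epochs2)) epochs2 <- if (property == "SS") 60L else 200L
  cfg$epochs1 <- as.integer(epochs1)
  cfg$epochs2 <- as.integer(epochs2)
  cfg$learning_rate <- learning_rate
  cfg$momentum <- momentum
  cfg
}

# Stage-1 input matrix for one profile under a property config.
stage1_input <- function(profile, cfg, fitness = NULL, ss_probs = NULL) {
  tracks <- profile_track_matrix(
    profile, fitness = if (cfg$property == "SS") fitness else NULL)
  X <- encode_windows(tracks, cfg$window)
  if (cfg$property == "RSA") {
    if (is.null(ss_probs)) stop("RSA prediction requires ss_probs")
    ss_probs <- as.matrix(ss_probs)
    if (nrow(ss_probs) != nrow(X) || ncol(ss_probs) != 3L) {
      stop("ss_probs must be L x 3")
    }
    X <- cbind(X, ss_probs)
  }
  X
}

#' Train one structural-property predictor
#'
#' Fits the one- or two-network predictor for a property on a set of
#' families. Stage 1 consumes the windowed profile encoding; where a second
#' network exists it refines stage-1 outputs, consuming a window of the
#' stage-1 per-residue outputs (probability triplets for SS, scalars for
#' RSA/RD) plus terminus bits. Windows never cross family boundaries.
#'
#' @param property `"SS"`, `"RSA"`, `"RD"` or `"Phi"`.
#' @param profiles List of [sequence_profile()] training inputs.
#' @param truths List of matching [structural_features()] ground truth.
#' @param fitness [compute_fitness()] result (required for SS).
#' @param ss_probs_list For RSA: list of L x 3 predicted SS probability
#'   matrices (columns H, E, C), one per family.
#' @param config A [predictor_config()].
#' @param seed Training seed.
#' @return Object of class `property_predictor`.
#' @export
train_property_predictor <- function(property, profiles, truths,
                                     fitness = NULL, ss_probs_list = NULL,
                                     config = predictor_config(property),
                                     seed = 1L) {
  property <- match.arg(property, c("SS", "RSA", "RD", "Phi"))
  stopifnot(length(profiles) == length(truths))
  if (property == "SS" && is.null(fitness)) {
    stop("SS training requires a fitness table")
  }
  if (property == "RSA" && is.null(ss_probs_list)) {
    stop("RSA training requires ss_probs_list (predicted SS probabilities)")
  }
  seeds <- derive_seeds(seed, 4L)

  Xs <- lapply(seq_along(profiles), function(i) {
    stage1_input(profiles[[i]], config, fitness = fitness,
                 ss_probs = if (property == "RSA") ss_probs_list[[i]])
  })
  Ys <- lapply(truths, function(tr) {
    if (property == "SS") {
      Y <- matrix(0, length(tr$ss3), 3)
      Y[cbind(seq_along(tr$ss3), match(tr$ss3, SS_NODE_ORDER))] <- 1
      Y
    } else {
      matrix(switch(property, RSA = tr$rsa, RD = tr$rd, Phi = tr$phi_norm),
             ncol = 1)
    }
  })
  X <- do.call(rbind, Xs)
  Y <- do.call(rbind, Ys)

  out_width <- if (property == "SS") 3L else 1L
  spec1 <- network_spec(c(ncol(X), config$hidden1, out_width),
                        seed = seeds[1],
                        learning_rate = config$learning_rate,
                        momentum = config$momentum)
  net1 <- nn_train(init_network(spec1), X, Y, epochs = config$epochs1,
                   seed = seeds[2])

  net2 <- NULL
  if (config$n_stages == 2L) {
    X2 <- do.call(rbind, lapply(Xs, function(Xi) {
      encode_windows(nn_forward(net1, Xi), config$stage2_window)
    }))
    spec2 <- network_spec(c(ncol(X2), config$hidden2, out_width),
                          seed = seeds[3],
                          learning_rate = config$learning_rate,
                          momentum = config$momentum)
    net2 <- nn_train(init_network(spec2), X2, Y, epochs = config$epochs2,
                     seed = seeds[4])
  }

  structure(
    list(property = property, config = config,
         stage1 = net1, stage2 = net2,
         fitness = if (property == "SS") fitness),
    class = "property_predictor"
  )
}

#' Reliability index of a secondary-structure prediction
#'
#' The margin between the two strongest output nodes,
#' `SS_RI = OUT_max - OUT_next`. For sigmoid outputs it lies in `[0, 1)`;
#' a residue is conventionally called confidently predicted when
#' `SS_RI > 0.35`.
#'
#' @param out 3-vector of output node values, or an L x 3 matrix.
#' @return Reliability value(s).
#' @export
ss_reliability <- function(out) {
  if (is.null(dim(out))) out <- matrix(out, 1)
  apply(out, 1, function(v) {
    s <- sort(v, decreasing = TRUE)
    s[1] - s[2]
  })
}

#' Predict 3-state secondary structure for a profile
#'
#' Runs the two-stage SS predictor: stage 1 maps the windowed profile
#' encoding to class probabilities; stage 2 re-windows those per-residue
#' probability triplets and produces the final probabilities, which are
#' renormalized to sum to 1 per residue. Labels are the class of the
#' maximal probability (ties break C, then E, then H); the reliability
#' index is the margin of the raw stage-2 output nodes.
#'
#' @param profile A [sequence_profile()].
#' @param predictor A trained SS `property_predictor` (both stages).
#' @return List with `ss_probs` (L x 3, columns H, E, C), `ss3`
#'   (character vector), `ss_ri` (length L).
#' @export
predict_ss <- function(profile, predictor) {
  stopifnot(inherits(predictor, "property_predictor"),
            predictor$property == "SS")
  if (is.null(predictor$stage2)) stop("SS predictor is missing its second stage")
  X <- stage1_input(profile, predictor$config, fitness = predictor$fitness)
  p1 <- nn_forward(predictor$stage1, X)
  X2 <- encode_windows(p1, predictor$config$stage2_window)
  out <- nn_forward(predictor$stage2, X2)
  ri <- ss_reliability(out)
  labels <- SS_NODE_ORDER[max.col(out, ties.method = "first")]
  rs <- rowSums(out)
  probs <- out / ifelse(rs > 0, rs, 1)
  probs[rs == 0, ] <- 1 / 3
  colnames(probs) <- SS_NODE_ORDER
  list(ss_probs = probs[, c("H", "E", "C"), drop = FALSE],
       ss3 = labels, ss_ri = ri)
}

#' Predict a scalar structural property (RSA, RD or Phi)
#'
#' Stage 1 consumes the windowed profile encoding; for RSA the three SS
#' probabilities of the target residue are appended once (not windowed).
#' Where a second stage exists it consumes a window of stage-1 scalar
#' outputs plus terminus bits. Outputs are clipped to `[0, 1]`.
#'
#' @param profile A [sequence_profile()].
#' @param predictor A trained RSA/RD/Phi `property_predictor`.
#' @param ss_probs L x 3 predicted SS probabilities (columns H, E, C);
#'   required for RSA, ignored otherwise.
#' @return Length-L numeric vector in `[0, 1]`.
#' @export
predict_scalar <- function(profile, predictor, ss_probs = NULL) {
  stopifnot(inherits(predictor, "property_predictor"),
            predictor$property %in% c("RSA", "RD", "Phi"))
  X <- stage1_input(profile, predictor$config, ss_probs = ss_probs)
  s1 <- nn_forward(predictor$stage1, X)
  out <- if (!is.null(predictor$stage2)) {
    X2 <- encode_windows(matrix(s1, ncol = 1), predictor$config$stage2_window)
    nn_forward(predictor$stage2, X2)
  } else {
    s1
  }
  clamp01(drop(out))
}

#' Train the full four-property model bundle
#'
#' Trains, in pipeline order: the amino-acid/SS fitness table on the
#' training labels, the two-stage SS predictor, then RSA (fed the SS
#' probabilities predicted for each training family by the just-trained SS
#' predictor, mirroring prediction time), RD and Phi.
#'
#' @param families List of `list(profile = , features = )` training
#'   families, `features` being ground-truth [structural_features()].
#' @param seed Master training seed; per-network seeds are derived from it.
#' @param configs Optional named list of [predictor_config()] overrides
#'   (names among SS, RSA, RD, Phi).
#' @return Object of class `model_bundle` with fields `ss`, `rsa`, `rd`,
#'   `phi`, `fitness`.
#' @export
train_model_bundle <- function(families, seed = 1L, configs = list()) {
  profiles <- lapply(families, `[[`, "profile")
  truths <- lapply(families, `[[`, "features")
  cfg <- function(p) configs[[p]] %||% predictor_config(p)
  seeds <- derive_seeds(seed, 4L)

  fitness <- compute_fitness(
    vapply(profiles, function(p) paste(p$sequence, collapse = ""), character(1)),
    vapply(truths, function(tr) paste(tr$ss3, collapse = ""), character(1))
  )

  ss <- train_property_predictor("SS", profiles, truths, fitness = fitness,
                                 config = cfg("SS"), seed = seeds[1])
  ss_probs_list <- lapply(profiles, function(p) predict_ss(p, ss)$ss_probs)
  rsa <- train_property_predictor("RSA", profiles, truths,
                                  ss_probs_list = ss_probs_list,
                                  config = cfg("RSA"), seed = seeds[2])
  rd <- train_property_predictor("RD", profiles, truths,
                                 config = cfg("RD"), seed = seeds[3])
  phi <- train_property_predictor("Phi", profiles, truths,
                                  config = cfg("Phi"), seed = seeds[4])

  structure(list(ss = ss, rsa = rsa, rd = rd, phi = phi, fitness = fitness),
            class = "model_bundle")
}

#' Predict all structural features for one profile
#'
#' The per-residue product of the feature-prediction pipeline: 3-state
#' secondary structure with class probabilities and reliability index,
#' relative solvent accessibility, relative residue depth and normalized
#' Phi.
#'
#' @param profile A [sequence_profile()].
#' @param bundle A trained [train_model_bundle()] result.
#' @return Data frame with columns position, residue, ss3, pH, pE, pC,
#'   ss_ri, rsa, rd, phi_norm.
#' @export
predict_features <- function(profile, bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  ss <- predict_ss(profile, bundle$ss)
  rsa <- predict_scalar(profile, bundle$rsa, ss_probs = ss$ss_probs)
  rd <- predict_scalar(profile, bundle$rd)
  phi <- predict_scalar(profile, bundle$phi)
  data.frame(
    position = seq_along(profile$sequence),
    residue = profile$sequence,
    ss3 = ss$ss3,
    pH = ss$ss_probs[, "H"],
    pE = ss$ss_probs[, "E"],
    pC = ss$ss_probs[, "C"],
    ss_ri = ss$ss_ri,
    rsa = rsa, rd = rd, phi_norm = phi,
    stringsAsFactors = FALSE
  )
}

#' Save / load a model bundle directory
#'
#' Serializes the trained networks (JSON), the encoding configuration and
#' the fitness table into a directory that [load_model_bundle()] restores.
#'
#' @param bundle A `model_bundle`.
#' @param dir Directory path (created if absent).
#' @return `dir` (save) or the restored `model_bundle` (load).
#' @export
save_model_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfgs <- list()
  for (p in c("ss", "rsa", "rd", "phi")) {
    pred <- bundle[[p]]
    save_network(pred$stage1, file.path(dir, paste0(p, "_stage1.json")))
    if (!is.null(pred$stage2)) {
      save_network(pred$stage2, file.path(dir, paste0(p, "_stage2.json")))
    }
    cfgs[[p]] <- pred$config
  }
  jsonlite::write_json(cfgs, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_fitness_table(bundle$fitness, file.path(dir, "fitness.tsv"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop("not a model bundle directory: ", dir)
  cfgs <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  fitness <- read_fitness_table(file.path(dir, "fitness.tsv"))
  load_pred <- function(p) {
    cfg <- as.list(cfgs[[p]])
    cfg$hidden1 <- as.integer(unlist(cfg$hidden1))
    if (!is.null(cfg$hidden2)) cfg$hidden2 <- as.integer(unlist(cfg$hidden2))
    s2path <- file.path(dir, paste0(p, "_stage2.json"))
    structure(
      list(property = cfg$property, config = cfg,
           stage1 = load_network(file.path(dir, paste0(p, "_stage1.json"))),
           stage2 = if (file.exists(s2path)) load_network(s2path),
           fitness = if (cfg$property == "SS") fitness),
      class = "property_predictor"
    )
  }
  structure(
    list(ss = load_pred("ss"), rsa = load_pred("rsa"),
         rd = load_pred("rd"), phi = load_pred("phi"), fitness = fitness),
    class = "model_bundle"
  )
}
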