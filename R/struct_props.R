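#' Reduce 7-state secondary structure to 3 states
#'
#' Applies the standard reduction used with DSSP/STRIDE assignments:
#' H, G and I become H (alpha-helix); E and B become E (beta-strand); every
#' other character (T, S, C, blanks, unknowns) becomes C (coil). The mapping
#' is total and length-preserving, and idempotent on 3-state input.
#'
#' @param seven_state Secondary-structure string(s), one character per
#'   residue.
#' @return String(s) of the same lengths over `{H, E, C}`.
#' @export
reduce_ss <- function(seven_state) {
  vapply(seven_state, function(s) {
    ch <- strsplit(s, "")[[1]]
    out <- rep("C", length(ch))
    out[ch %in% c("H", "G", "I")] <- "H"
    out[ch %in% c("E", "B")] <- "E"
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Maximum solvent-accessible surface areas per residue
#'
#' Returns the reference maximum accessible surface area (A^2) for each of
#' the 20 amino acids, used as the denominator when converting absolute
#' accessible areas to relative solvent accessibility. The shipped default
#' is the theoretical maximum-ASA set of Tien et al. (2013); a different
#' table can be supplied as a two-column TSV (residue, max_asa).
#'
#' @param path Optional path to a replacement TSV table.
#' @return Named numeric vector of 20 areas.
#' @export
max_asa_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "max_asa.tsv", package = "ppaomp")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tab <- stats::setNames(as.numeric(df$max_asa), df$residue)
  missing <- setdiff(aa_alphabet(), names(tab))
  if (length(missing)) stop("max-ASA table lacks residues: ",
                            paste(missing, collapse = ", "))
  tab
}

#' Relative solvent accessibility from absolute accessible area
#'
#' RSA = ASA / max_area(residue), capped at 1. Capping reflects that real
#' structures occasionally exceed the reference maxima because of unusual
#' bond angles and distorted geometry; such values are set to 100%.
#'
#' @param asa Nonnegative accessible surface area(s), A^2.
#' @param residue One-letter residue code(s), recycled against `asa`.
#' @param max_area Named area table as from [max_asa_table()].
#' @param fallback_area Optional area used for residues absent from the
#'   table (e.g. `X`); if `NULL` an unknown residue is an error.
#' @return RSA value(s) in `[0, 1]`.
#' @export
relative_accessibility <- function(asa, residue,
                                   max_area = max_asa_table(),
                                   fallback_area = NULL) {
  if (any(asa < 0)) stop("asa must be nonnegative")
  n <- max(length(asa), length(residue))
  asa <- rep_len(asa, n)
  residue <- rep_len(toupper(residue), n)
  denom <- unname(max_area[residue])
  if (anyNA(denom)) {
    if (is.null(fallback_area)) {
      stop("no max-ASA entry for residue(s): ",
           paste(unique(residue[is.na(denom)]), collapse = ", "))
    }
    denom[is.na(denom)] <- fallback_area
  }
  pmin(asa / denom, 1)
}

#' Normalize absolute residue depth to `[0, 1]`
#'
#' Residue depth measures how deeply a residue is buried below the
#' molecular surface. Absolute depth values (as computed by EDTSurf) lie in
#' `[2.8, 9.8]`; they are mapped linearly onto `[0, 1]` by
#' `(dv - 2.8) / (9.8 - 2.8)` and clamped for out-of-range inputs.
#'
#' @param dv Absolute depth value(s).
#' @return Relative depth in `[0, 1]`.
#' @export
normalize_rd <- function(dv) {
  if (any(!is.finite(dv))) stop("depth values must be finite")
  clamp01((dv - 2.8) / (9.8 - 2.8))
}

#' Normalize a backbone Phi angle to `[0, 1]`
#'
#' Angles in degrees on `(-180, 180]` are remapped to `[0, 360)` by leaving
#' angles in `[0, 180]` unchanged and adding 360 to negative angles, then
#' divided by 360. An input of exactly -180 is treated as +180 (the two
#' represent the same wrapped angle), giving 0.5.
#'
#' @param phi_deg Phi angle(s) in degrees, within `[-180, 180]`.
#' @return Normalized value(s) in `[0, 1]`.
#' @export
normalize_phi <- function(phi_deg) {
  if (any(!is.finite(phi_deg)) || any(phi_deg < -180) || any(phi_deg > 180)) {
    stop("phi must lie in [-180, 180] degrees")
  }
  phi_deg[phi_deg == -180] <- 180
  shifted <- ifelse(phi_deg >= 0, phi_deg, phi_deg + 360)
  shifted / 360
}

#' Fitness of amino acids in the three secondary-structure classes
#'
#' Tallies, over a labeled dataset, how often each amino acid occurs in
#' helix, strand and coil: `ft[i, j] = NS[j, i] / NA[i]` where `NA[i]` is
#' the count of residue type i and `NS[j, i]` the count of residue type i
#' observed in SS class j. Each row sums to 1. Residue types absent from
#' the dataset receive a uniform (1/3, 1/3, 1/3) row with a warning, so
#' small datasets remain usable. Nonstandard residues (X) are excluded
#' from the tally.
#'
#' @param sequences Character vector of amino-acid strings.
#' @param ss3 Character vector of matching 3-state SS strings over
#'   `{H, E, C}`.
#' @return Object of class `fitness_table`: `ft` (20 x 3 matrix, rows in
#'   [aa_alphabet()] order, columns H, E, C), and the raw `na`/`ns` counts.
#' @export
compute_fitness <- function(sequences, ss3) {
  if (length(sequences) != length(ss3)) {
    stop("sequences and ss3 must have the same length")
  }
  aa <- unlist(strsplit(toupper(paste(sequences, collapse = "")), ""))
  ss <- unlist(strsplit(toupper(paste(ss3, collapse = "")), ""))
  if (length(aa) != length(ss)) {
    stop("per-protein sequence and ss3 lengths differ")
  }
  if (!all(ss %in% c("H", "E", "C"))) stop("ss3 must be over {H, E, C}")
  keep <- aa %in% aa_alphabet()
  aa <- aa[keep]
  ss <- ss[keep]
  classes <- c("H", "E", "C")
  ns <- matrix(0L, 20, 3, dimnames = list(aa_alphabet(), classes))
  tab <- table(factor(aa, levels = aa_alphabet()),
               factor(ss, levels = classes))
  ns[] <- as.integer(tab)
  na <- rowSums(ns)
  ft <- ns / ifelse(na > 0, na, 1)
  absent <- na == 0
  if (any(absent)) {
    warning("residue type(s) absent from dataset, using uniform fitness: ",
            paste(aa_alphabet()[absent], collapse = ", "))
    ft[absent, ] <- 1 / 3
  }
  structure(list(ft = ft, na = na, ns = ns), class = "fitness_table")
}

#' Write / read a fitness table as TSV
#'
#' @param fitness A [compute_fitness()] result.
#' @param path File path.
#' @return `path` (write) or a `fitness_table` with counts unset (read).
#' @export
write_fitness_table <- function(fitness, path) {
  df <- data.frame(residue = rownames(fitness$ft), fitness$ft,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fitness_table
#' @export
read_fitness_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ft <- as.matrix(df[, c("H", "E", "C")])
  rownames(ft) <- df$residue
  ft <- ft[aa_alphabet(), , drop = FALSE]
  structure(list(ft = ft, na = NULL, ns = NULL), class = "fitness_table")
}

#' Bundle normalized per-residue structural features
#'
#' Container for the four target tracks on their `[0, 1]` training scales:
#' 3-state secondary structure (with optional class probabilities), relative
#' solvent accessibility, relative residue depth and normalized Phi.
#'
#' @param ss3 Character vector (one letter per residue) or single string
#'   over `{H, E, C}`.
#' @param rsa,rd,phi_norm Numeric vectors in `[0, 1]`, same length.
#' @param ss_probs Optional L x 3 matrix (columns H, E, C) of class
#'   probabilities; rows are renormalized to sum to 1.
#' @return Object of class `structural_features`.
#' @export
structural_features <- function(ss3, rsa, rd, phi_norm, ss_probs = NULL) {
  if (length(ss3) == 1L && nchar(ss3) > 1L) ss3 <- strsplit(ss3, "")[[1]]
  L <- length(ss3)
  if (!all(ss3 %in% c("H", "E", "C"))) stop("ss3 must be over {H, E, C}")
  for (v in list(rsa = rsa, rd = rd, phi_norm = phi_norm)) {
    if (length(v) != L) stop("all feature tracks must share length L")
    if (any(v < 0 | v > 1)) stop("rsa, rd and phi_norm must lie in [0, 1]")
  }
  if (!is.null(ss_probs)) {
    ss_probs <- as.matrix(ss_probs)
    if (!all(dim(ss_probs) == c(L, 3L))) stop("ss_probs must be L x 3")
    ss_probs <- ss_probs / rowSums(ss_probs)
    colnames(ss_probs) <- c("H", "E", "C")
  }
  structure(
    list(ss3 = ss3, ss_probs = ss_probs, rsa = rsa, rd = rd,
         phi_norm = phi_norm),
    class = "structural_features"
  )
}

#' Normalize a raw per-residue annotation table
#'
#' Converts the output of external structure-annotation programs (7-state
#' secondary structure, absolute accessible areas, absolute depth values,
#' Phi angles in degrees) into the normalized [structural_features()] used
#' for training. The table must have columns `position`, `residue`, `ss7`,
#' `asa`, `depth`, `phi_deg`.
#'
#' @param annotation Data frame or path to a TSV with the columns above.
#' @param max_area Max-ASA table, see [max_asa_table()].
#' @return A [structural_features()].
#' @export
normalize_annotations <- function(annotation, max_area = max_asa_table()) {
  if (is.character(annotation)) {
    annotation <- utils::read.table(annotation, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  }
  need <- c("position", "residue", "ss7", "asa", "depth", "phi_deg")
  if (!all(need %in% names(annotation))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  annotation <- annotation[order(annotation$position), ]
  structural_features(
    ss3 = strsplit(reduce_ss(paste(annotation$ss7, collapse = "")), "")[[1]],
    rsa = relative_accessibility(annotation$asa, annotation$residue,
                                 max_area = max_area, fallback_area = mean(max_area)),
    rd = normalize_rd(annotation$depth),
    phi_norm = normalize_phi(annotation$phi_deg)
  )
}

#' Write normalized structural features as TSV
#'
#' @param features A [structural_features()].
#' @param path Output path.
#' @param residues Optional residue letters column.
#' @return `path`, invisibly.
#' @export
write_structural_features <- function(features, path, residues = NULL) {
  L <- length(features$ss3)
  df <- data.frame(position = seq_len(L))
  if (!is.null(residues)) df$residue <- residues
  df$ss3 <- features$ss3
  if (!is.null(features$ss_probs)) {
    df$pH <- features$ss_probs[, "H"]
    df$pE <- features$ss_probs[, "E"]
    df$pC <- features$ss_probs[, "C"]
  }
  df$rsa <- features$rsa
  df$rd <- features$rd
  df$phi_norm <- features$phi_norm
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
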