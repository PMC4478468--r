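# Independent brute-force alignment oracle: enumerates every monotone set
# of aligned position pairs and scores it directly (pair scores plus
# affine gap runs, each costing open + (len - 1) * extend; global mode
# additionally charges terminal runs). Kept free of any DP machinery.

oracle_gap_cost <- function(g, params) {
  if (g <= 0) 0 else params$gap_open + (g - 1) * params$gap_extend
}

oracle_score_pairs <- function(S, is, js, n, m, mode, params) {
  is <- unname(as.integer(is))
  js <- unname(as.integer(js))
  k <- length(is)
  if (k == 0L) {
    if (mode == "local") return(0)
    return(oracle_gap_cost(n, params) + oracle_gap_cost(m, params))
  }
  sc <- sum(S[cbind(is, js)])
  if (k > 1L) {
    sc <- sc + sum(vapply(diff(is) - 1L, oracle_gap_cost, 0, params = params)) +
      sum(vapply(diff(js) - 1L, oracle_gap_cost, 0, params = params))
  }
  if (mode == "global") {
    sc <- sc + oracle_gap_cost(is[1] - 1L, params) +
      oracle_gap_cost(js[1] - 1L, params) +
      oracle_gap_cost(n - is[k], params) +
      oracle_gap_cost(m - js[k], params)
  }
  sc
}

oracle_best_score <- function(S, mode, params) {
  n <- nrow(S)
  m <- ncol(S)
  best <- oracle_score_pairs(S, integer(0), integer(0), n, m, mode, params)
  for (k in seq_len(min(n, m))) {
    ri <- utils::combn(n, k)
    ci <- utils::combn(m, k)
    for (a in seq_len(ncol(ri))) {
      for (b in seq_len(ncol(ci))) {
        sc <- oracle_score_pairs(S, ri[, a], ci[, b], n, m, mode, params)
        if (sc > best) best <- sc
      }
    }
  }
  best
}
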