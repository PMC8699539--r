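# small builders and independent oracles shared across test files

toy_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  storage.mode(m) <- "integer"
  m
}

toy_design <- function(samples, conditions) {
  data.frame(sample_id = samples,
             cell_line = "SYN",
             condition = conditions,
             replicate = stats::ave(seq_along(samples), conditions,
                                    FUN = seq_along),
             stringsAsFactors = FALSE)
}

# brute-force BH step-up, written from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# closed-form two-sided Welch t p-value
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(abs(tt), df, lower.tail = FALSE)
}

# exhaustive hypergeometric upper tail by enumerating draws
hyper_enum <- function(overlap, set_size, universe, list_size) {
  ks <- max(0, list_size - (universe - set_size)):min(set_size, list_size)
  probs <- choose(set_size, ks) * choose(universe - set_size, list_size - ks) /
    choose(universe, list_size)
  sum(probs[ks >= overlap])
}

# literal running-sum walk for the enrichment score
es_hand <- function(in_set, scores, weight = 1) {
  w <- abs(scores)^weight
  rs <- 0
  best <- 0
  n_miss <- sum(!in_set)
  for (i in seq_along(in_set)) {
    rs <- rs + if (in_set[i]) w[i] / sum(w[in_set]) else -1 / n_miss
    if (abs(rs) > abs(best)) best <- rs
  }
  as.numeric(best)
}
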