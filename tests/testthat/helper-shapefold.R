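# Shared helpers: pair-level accuracy and small random instances.

pair_key <- function(s) {
  pr <- shapefold:::structure_pairs(s)
  if (!nrow(pr)) character(0) else paste(pr[, 1], pr[, 2])
}

# fraction of ground-truth pairs recovered by a prediction
pair_sensitivity <- function(truth, pred) {
  tk <- pair_key(truth)
  if (!length(tk)) return(NA_real_)
  mean(tk %in% pair_key(pred))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# Boltzmann pair-probability matrix from an exhaustive enumeration
enumeration_pair_probs <- function(enum, n, RT) {
  w <- exp(-enum$energy / RT)
  Z <- sum(w)
  P <- matrix(0, n, n)
  for (s in seq_len(nrow(enum))) {
    pr <- shapefold:::structure_pairs(enum$structure[[s]])
    if (nrow(pr)) for (r in seq_len(nrow(pr)))
      P[pr[r, 1], pr[r, 2]] <- P[pr[r, 1], pr[r, 2]] + w[s] / Z
  }
  P + t(P)
}
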