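# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, direct definitions) and never call the code paths they check.

# Build a peptide observation table from parallel vectors.
make_peptides <- function(peptide_id, protein_id, replicate_id, design,
                          log2_hl, probability = 1, correct = TRUE) {
  data.frame(peptide_id = peptide_id, protein_id = protein_id,
             replicate_id = replicate_id, design = design,
             log2_hl = log2_hl,
             probability = rep_len(probability, length(peptide_id)),
             correct = rep_len(correct, length(peptide_id)),
             stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Hochberg step-up straight from the definition:
# adj_(i) = min over k >= i of p_(k) * m / k, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (k in i:m) best <- min(best, ps[k] * m / k)
    adj[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force codon counting via regmatches (independent of substring
# arithmetic used in the implementation).
codon_count_oracle <- function(seq) {
  codons <- regmatches(seq, gregexpr("...", seq))[[1]]
  codons <- codons[-length(codons)] # drop terminal stop
  table(codons)
}

# A small simulated dataset shared by several files.
small_sim <- function(seed = 11, n = 150, ...) {
  cfg <- generator_config(n_proteins = n, seed = seed, ...)
  simulate_dataset(cfg)
}
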