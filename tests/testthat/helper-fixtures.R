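# small deterministic fixtures used across test files

random_expression <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean = 8),
         nrow = n_genes,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# a well-powered planted cohort for workflow tests (effects large enough
# that the BH screen recovers the planted genes essentially always)
strong_cohort <- function(seed, n_samples = 170) {
  simulate_cohort(cohort_config(n_samples = n_samples,
                                de_log2fc = c(1.6, 1.2, 1.0),
                                seed = seed))
}

# brute-force AUC by pair counting (independent oracle)
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# brute-force two-sided Fisher p: sum hypergeometric probabilities of all
# tables with the observed margins that are no more probable than the
# observed one (with the conventional 1 + 1e-7 relative tolerance for
# floating-point ties)
fisher_enumerate <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  lo <- max(0, k - m2)
  hi <- min(k, m1)
  probs <- dhyper(lo:hi, m1, m2, k)
  obs <- dhyper(a, m1, m2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
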