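# Independent brute-force oracles for the empirical FDR estimators.
# Deliberately O(N^2): direct counting over all SNP pairs, no shared code
# with the package implementation.

oracle_marginal_fdr <- function(p, pi0 = 1) {
  vapply(seq_along(p), function(i)
    min(1, pi0 * p[i] * length(p) / sum(p <= p[i])), numeric(1))
}

oracle_cond_fdr <- function(p1, p2, pi0 = 1) {
  vapply(seq_along(p1), function(i) {
    strat <- p2 <= p2[i]
    min(1, pi0 * p1[i] * sum(strat) / sum(strat & p1 <= p1[i]))
  }, numeric(1))
}

oracle_conj_fdr <- function(p1, p2, pi0 = 1)
  pmax(oracle_cond_fdr(p1, p2, pi0), oracle_cond_fdr(p2, p1, pi0))

# The worked 5-SNP example used across the FDR tests
example5 <- function() list(p1 = c(0.01, 0.2, 0.3, 0.05, 0.5),
                            p2 = c(0.04, 0.03, 0.5, 0.02, 0.9))
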