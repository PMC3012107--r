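# Brute-force binomial oracles (pmf summation), independent of the
# pbinom/qbinom survival-function path used by the package.

oracle_tail <- function(S, gamma, K) {
  if (K <= 0) return(1)
  if (K > S) return(0)
  sum(dbinom(K:S, S, gamma))
}

# smallest b with P(Bin(S, gamma) >= b) <= alpha, scanning b = 0 .. S + 1;
# the same 1e-9 relative boundary guard as the implementation, so both sides
# treat P = alpha identically
oracle_critical_value <- function(S, gamma, alpha) {
  for (b in 0:(S + 1)) {
    if (oracle_tail(S, gamma, b) <= alpha * (1 + 1e-9)) return(b)
  }
}

# classical BH step-up written from the definition (sorted comparison), as an
# independent check of bh_procedure
oracle_bh <- function(p, q) {
  S <- length(p)
  ord <- order(p)
  ok <- which(p[ord] <= seq_len(S) / S * q)
  if (!length(ok)) return(integer(0))
  sort(ord[seq_len(max(ok))])
}

# one mixture trial at the simulation study's conditions
make_mixture <- function(S = 1000, effect_proportion = 0.1, w = 2) {
  generate_pvalues(S, effect_proportion, w)
}
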