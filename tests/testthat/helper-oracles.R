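# Brute-force two-sided Fisher p-value: enumerate the hypergeometric
# support of the 2x2 table and sum the probabilities not exceeding the
# observed one (with R's documented relative tie tolerance).
fisher_oracle <- function(a, b, cc, d) {
  m <- a + cc; n_ <- b + d; k <- a + b
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
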