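# Independent oracles and small fixture builders shared across tests.

# Brute-force two-sided Fisher P: enumerate every achievable table with the
# same margins and sum the hypergeometric probabilities that do not exceed
# the observed table's probability (with the usual relative-error guard).
fisher_oracle <- function(a, m, k, N) {
  support <- max(0L, k - (N - m)):min(m, k)
  probs <- stats::dhyper(support, m, N - m, k)
  p_obs <- stats::dhyper(a, m, N - m, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random valid contingency counts with N <= n_max.
random_contingency <- function(n_max = 60) {
  N <- sample(4:n_max, 1L)
  m <- sample(1:(N - 1L), 1L)
  k <- sample(1:(N - 1L), 1L)
  lo <- max(0L, k - (N - m))
  a <- sample(lo:min(m, k), 1L)
  contingency(a, m, k, N)
}

# Tiny expression fixture: a values matrix with explicit group labels.
make_expr <- function(values, group) {
  list(values = values, group = factor(group))
}

# Minimal profiles table for survival tests.
make_profiles <- function(n, kras = TRUE, tp53 = FALSE, smad4 = FALSE,
                          cdkn2a = FALSE, time = NULL, event = NULL) {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    kras_mut = rep_len(kras, n), tp53_mut = rep_len(tp53, n),
    smad4_mut = rep_len(smad4, n), cdkn2a_mut = rep_len(cdkn2a, n),
    n_driver_mut = rep_len(kras, n) + rep_len(tp53, n) +
      rep_len(smad4, n) + rep_len(cdkn2a, n),
    time = if (is.null(time)) rexp(n, 0.05) else time,
    event = if (is.null(event)) rbinom(n, 1, 0.8) else event,
    stringsAsFactors = FALSE
  )
}
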