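# shared fixtures and oracles

# principal angles (degrees) between the column spaces of A and B
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  acos(pmin(1, svd(crossprod(qa, qb))$d)) * 180 / pi
}

# a small cohort configuration used across tests
small_cfg <- function(...) {
  defaults <- list(n_subjects = 2, n_positions = 2, n_repetitions = 3, seed = 123L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# single synthetic trial, preprocessed
fixture_trial <- function(seed = 42L, ...) {
  cfg <- small_cfg(n_subjects = 1, n_positions = 1, n_repetitions = 1, seed = seed, ...)
  coh <- generate_cohort(cfg)
  coh$subjects[[1]]$recordings[[1]]
}

# Gaussian burst on a zero baseline (constructed detector input)
burst_envelope <- function(n = 600, center = 300, width = 40, amp = 1) {
  amp * exp(-0.5 * ((seq_len(n) - center) / width)^2)
}
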