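## Small shared generator configurations for fast tests.

tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 1, n_channels = 8, sfreq = 50,
         epoch_window = c(0, 200), n_repetitions = 4, seed = 42),
    list(...)
  )
  do.call(generator_params, args)
}

tiny_design <- function(n_identities = 2, n_variations = 5, n_repetitions = 4) {
  make_design(5, n_identities, n_variations, n_repetitions = n_repetitions)
}

## Independent Spearman oracle: classic rank-difference formula (no ties).
spearman_oracle <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  n <- length(a)
  1 - 6 * sum((ra - rb)^2) / (n * (n^2 - 1))
}

## Exhaustive signed-rank null: p = P(V >= v_obs) over all 2^n sign patterns.
signed_rank_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_null <- as.matrix(signs) %*% r
  mean(v_null >= v_obs)
}
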