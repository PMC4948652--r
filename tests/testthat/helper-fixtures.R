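# Shared fixtures, built once per test run.

fluid_fixture <- local({
  cache <- NULL
  function(n = 2e4) {
    if (is.null(cache) || nrow(cache) < n) {
      cache <<- sample_posterior(posterior_spec(), n, seed = 4242)
    }
    cache[seq_len(n), ] -> out
    attr(out, "spec") <- attr(cache, "spec")
    out
  }
})

# independent draws for oracle comparisons
random_draws <- function(n, seed) sample_posterior(posterior_spec(), n, seed)

expect_within_se <- function(est, target, se, k = 3) {
  expect_lt(abs(est - target), k * se + 1e-12)
}
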