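# Fitted posteriors are reused across test files; chains are fitted once
# per test run and cached. Unit tests use moderate chains; the acceptance
# tests use full-length chains.
.fit_cache <- new.env(parent = emptyenv())

test_posteriors <- function() {
  if (is.null(.fit_cache$post)) {
    .fit_cache$post <- fit_all_posteriors(seed = 1, n_iter = 20000,
                                          burn_in = 2000)
  }
  .fit_cache$post
}

acceptance_posteriors <- function() {
  if (is.null(.fit_cache$post_full)) {
    .fit_cache$post_full <- fit_all_posteriors(seed = 1)
  }
  .fit_cache$post_full
}
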