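# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# A small, fully separable configuration: polar tweets draw ONLY from their
# loaded lexicon (mix_weight = 1), so the latent label is recoverable.
separable_config <- function(n = 500, seed = 11L,
                             props = c(0.3, 0.3, 0.4)) {
  corpus_config(
    n_tweets = n, modality = "pap_smear", true_proportions = props,
    mix_weight = 1, seed = seed,
    arrival_rates = c(positive = n / 3, negative = n / 3, neutral = n / 3)
  )
}

# The default mixed (classifiable-but-imperfect) configuration.
mixed_config <- function(n = 600, seed = 21L,
                         props = c(0.25, 0.25, 0.5)) {
  corpus_config(
    n_tweets = n, modality = "colonoscopy", true_proportions = props,
    mix_weight = 0.4, seed = seed,
    arrival_rates = c(positive = n / 6, negative = n / 6, neutral = n / 6)
  )
}

# Identity correction kernel.
identity_kernel <- function() {
  k <- diag(3)
  dimnames(k) <- list(true = c("positive", "negative", "neutral"),
                      classified = c("positive", "negative", "neutral"))
  k
}

# Random small token corpus for classifier cross-checks: documents over a
# small vocabulary with binary labels.
random_token_corpus <- function(seed, n_docs = 8, vocab_size = 6,
                                max_len = 6) {
  set.seed(seed)
  vocab <- paste0("w", seq_len(vocab_size))
  repeat {
    labels <- sample(c("aa", "bb"), n_docs, replace = TRUE)
    if (length(unique(labels)) == 2L) break
  }
  docs <- lapply(seq_len(n_docs), function(i) {
    sample(vocab, sample.int(max_len, 1L), replace = TRUE)
  })
  test_docs <- lapply(1:5, function(i) {
    sample(c(vocab, "oov1", "oov2"), sample.int(max_len, 1L), replace = TRUE)
  })
  list(docs = docs, labels = labels, test_docs = test_docs, vocab = vocab)
}

# Independent negative-binomial log-PMF written directly from the gamma
# representation (oracle; deliberately avoids dnbinom).
ref_negbin_logpmf <- function(x, mu, k) {
  lgamma(x + k) - lgamma(k) - lgamma(x + 1) +
    k * (log(k) - log(k + mu)) + x * (log(mu) - log(mu + k))
}
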