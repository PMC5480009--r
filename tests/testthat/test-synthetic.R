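test_that("degenerate corpus sizes and proportions behave as specified", {
  empty <- generate_corpus(corpus_config(0, "colonoscopy", c(0.3, 0.3, 0.4)))
  expect_identical(nrow(empty), 0L)
  all_pos <- generate_corpus(
    corpus_config(50, "colonoscopy", c(1, 0, 0), seed = 3L))
  expect_identical(nrow(all_pos), 50L)
  expect_true(all(all_pos$true_sentiment == "positive"))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(corpus_config(10, "colonoscopy", c(0.5, 0.4, 0.2)),
               "true_proportions")
  expect_error(corpus_config(10, "colonoscopy", c(0.7, 0.4, -0.1)),
               "true_proportions")
  lex <- default_lexicons()
  lex$neutral <- c(lex$neutral, "painful")
  expect_error(corpus_config(10, "colonoscopy", c(0.3, 0.3, 0.4),
                             lexicons = lex), "disjoint")
  expect_error(
    corpus_config(10, "colonoscopy", c(0.3, 0.3, 0.4),
                  retweet_params = list(positive = list(mu = 1, k = 0),
                                        negative = list(mu = 1, k = 1),
                                        neutral = list(mu = 1, k = 1))),
    "k")
})

test_that("identical config and seed reproduce a byte-identical corpus", {
  cfg <- mixed_config(n = 200, seed = 33L)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  f1 <- tempfile(fileext = ".jsonl")
  f2 <- tempfile(fileext = ".jsonl")
  on.exit(unlink(c(f1, f2)))
  write_corpus_jsonl(c1, f1)
  write_corpus_jsonl(c2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed changes the corpus
  cfg2 <- mixed_config(n = 200, seed = 34L)
  expect_false(identical(generate_corpus(cfg2), c1))
})

test_that("empirical sentiment fractions recover the configured proportions", {
  # oracle: exact central 99% binomial interval for n = 10000, p = 0.3
  n <- 10000
  p <- 0.3
  lo <- qbinom(0.005, n, p)
  hi <- qbinom(0.995, n, p)
  cfg <- corpus_config(n, "mammography", c(p, 0.2, 0.5), seed = 91L)
  corpus <- generate_corpus(cfg)
  n_pos <- sum(corpus$true_sentiment == "positive")
  expect_gte(n_pos, lo)
  expect_lte(n_pos, hi)
})

test_that("generated text is non-empty and contains the query prefix", {
  corpus <- generate_corpus(mixed_config(n = 100, seed = 8L))
  expect_true(all(nchar(corpus$text) > 0))
  expect_true(all(startsWith(corpus$text, "colonoscopy ")))
  expect_true(all(lengths(tokenize(corpus$text)) >= 4L))
  expect_true(all(corpus$retweet_count >= 0))
  expect_true(all(corpus$retweet_count == round(corpus$retweet_count)))
  expect_identical(anyDuplicated(corpus$id), 0L)
})

test_that("retweet sampler matches the negative-binomial moments", {
  expect_identical(sample_retweet_counts(0, 1, 10, seed = 1L), integer(10))
  expect_error(sample_retweet_counts(2, 0, 10), "k")
  # Poisson limit: variance within 5% of the mean
  x <- sample_retweet_counts(2, 1e6, 50000, seed = 5L)
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
  # overdispersed: variance within 10% of mu + mu^2/k = 10
  y <- sample_retweet_counts(2, 0.5, 50000, seed = 6L)
  expect_lt(abs(var(y) - 10) / 10, 0.10)
  expect_lt(abs(mean(y) - 2) / 2, 0.05)
  # determinism under a fixed seed
  expect_identical(sample_retweet_counts(2, 0.5, 100, seed = 9L),
                   sample_retweet_counts(2, 0.5, 100, seed = 9L))
})

test_that("small-k samples are overdispersed (variance exceeds mean)", {
  for (k in c(0.3, 1, 5)) {
    x <- sample_retweet_counts(3, k, 20000, seed = 100L + k * 10)
    expect_gt(var(x), mean(x))
  }
})

test_that("corpus JSONL and truth CSV round-trip", {
  corpus <- generate_corpus(mixed_config(n = 40, seed = 12L))
  f <- tempfile(fileext = ".jsonl")
  g <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f, g)))
  write_corpus_jsonl(corpus, f)
  back <- read_corpus_jsonl(f)
  expect_identical(back$id, corpus$id)
  expect_identical(back$text, corpus$text)
  expect_identical(as.integer(back$retweet_count), corpus$retweet_count)
  expect_identical(back$is_original, corpus$is_original)
  expect_identical(back$true_sentiment, corpus$true_sentiment)
  write_truth_csv(corpus, g)
  truth <- read.csv(g, stringsAsFactors = FALSE)
  expect_identical(truth$true_sentiment, corpus$true_sentiment)
})

test_that("original-tweet arrivals follow the configured Poisson rates", {
  n <- 6000
  cfg <- corpus_config(
    n, "pap_smear", c(0.3, 0.3, 0.4), seed = 55L,
    arrival_rates = c(positive = 300, negative = 600, neutral = 0))
  corpus <- generate_corpus(cfg)
  orig <- table(factor(corpus$true_sentiment[corpus$is_original],
                       levels = c("positive", "negative", "neutral")))
  expect_identical(unname(orig[["neutral"]]), 0L)
  # each count within the exact central 99.9% Poisson interval of its rate
  expect_gte(orig[["positive"]], qpois(5e-4, 300))
  expect_lte(orig[["positive"]], qpois(1 - 5e-4, 300))
  expect_gte(orig[["negative"]], qpois(5e-4, 600))
  expect_lte(orig[["negative"]], qpois(1 - 5e-4, 600))
})
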