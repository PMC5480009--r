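toy_classified <- function() {
  data.frame(
    id = as.character(1:4),
    text = c("pap saves lives", "pap saves", "pap painful prep",
             "pap saves lives again"),
    is_original = c(TRUE, TRUE, TRUE, FALSE),
    label = c("positive", "positive", "negative", "positive"),
    stringsAsFactors = FALSE)
}

test_that("word frequencies count original tweets under the stated rules", {
  tw <- toy_classified()
  tab <- word_frequencies(tw, "positive", stopwords = character(),
                          exclude = "pap", top_k = 10)
  expect_identical(tab$token, c("saves", "lives"))
  expect_identical(tab$count, c(2L, 1L))
  expect_identical(tab$rank, 1:2)
  expect_identical(attr(tab, "n_docs"), 2L)  # retweet record excluded
  # top_k larger than the vocabulary returns the whole vocabulary
  expect_identical(nrow(word_frequencies(tw, "positive",
                                         stopwords = character(),
                                         top_k = 100)), 3L)
  # no matching tweets -> empty table, not an error
  none <- word_frequencies(tw, "neutral")
  expect_identical(nrow(none), 0L)
  expect_identical(attr(none, "n_docs"), 0L)
})

test_that("ranking is by descending count with lexicographic tie-break", {
  tw <- data.frame(
    id = "1", text = "zebra apple zebra apple mango",
    is_original = TRUE, label = "negative", stringsAsFactors = FALSE)
  tab <- word_frequencies(tw, "negative", stopwords = character(), top_k = 3)
  expect_identical(tab$token, c("apple", "zebra", "mango"))
  expect_true(all(diff(tab$count) <= 0))
  expect_identical(tab$rank, 1:3)
})

test_that("frequency counts conserve the retained token total", {
  corpus <- generate_corpus(mixed_config(n = 300, seed = 71L))
  corpus$label <- corpus$true_sentiment
  stop_set <- builtin_stopwords()
  query <- modality_query_terms("colonoscopy")
  tab <- word_frequencies(corpus, "negative", stopwords = stop_set,
                          exclude = query, top_k = 10000)
  toks <- unlist(tokenize(
    corpus$text[corpus$label == "negative" & corpus$is_original]))
  toks <- toks[!(toks %in% stop_set) & !(toks %in% query)]
  expect_identical(sum(tab$count), length(toks))
  expect_true(all(grepl("^[a-z0-9]+$", tab$token)))
})

test_that("strongly loaded lexicons surface as top-ranked tokens", {
  lex <- default_lexicons()
  lex$positive <- c("awareness", "detection")
  cfg <- corpus_config(400, "pap_smear", c(0.5, 0.2, 0.3), lexicons = lex,
                       mix_weight = 0.8, seed = 77L,
                       arrival_rates = c(positive = 200, negative = 80,
                                         neutral = 120))
  corpus <- generate_corpus(cfg)
  corpus$label <- corpus$true_sentiment
  tab <- word_frequencies(corpus, "positive", stopwords = character(),
                          exclude = modality_query_terms("pap_smear"),
                          top_k = 2)
  expect_setequal(tab$token, c("awareness", "detection"))
})

test_that("reports serialize deterministically and round-trip", {
  report <- run_study(configs = default_study_configs(n_tweets = 600,
                                                      seed = 19L),
                      seed = 19L, n_labeled = 300, n_boot = 300, top_k = 5)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(f1, f2)))
  write_report_json(report, f1)
  parsed <- jsonlite::read_json(f1, simplifyVector = FALSE)
  write_report_json(parsed, f2)
  # round-trip: serializing the parsed report preserves every value
  expect_identical(jsonlite::read_json(f2, simplifyVector = FALSE), parsed)
  expect_identical(names(parsed$modalities),
                   c("colonoscopy", "mammography", "pap_smear"))
  expect_identical(parsed$software$package, "screensent")
})

test_that("reports mark absent stages instead of failing", {
  rep <- build_report(list(colonoscopy = list(accuracy = 0.8)), seed = 1L)
  m <- rep$modalities$colonoscopy
  expect_identical(m$accuracy, 0.8)
  expect_false(m$ratio_estimate$available)
  expect_false(m$propagation$available)
  expect_error(build_report(list(), seed = 1L))
  one <- build_report(list(pap_smear = list(accuracy = 1)), seed = 2L)
  expect_length(one$modalities, 1L)
})
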